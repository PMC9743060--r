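test_that("percent change is exact on constructed series", {
  d <- c(2, 2, 1)
  const <- bold_from_array(array(1000, dim = c(d, 6)), n_baseline = 3)
  pc <- percent_change_series(const)
  expect_equal(as.numeric(pc$pc), rep(0, prod(d) * 6))

  arr <- array(1000, dim = c(d, 6))
  arr[1, 1, 1, 4:6] <- 1050
  b <- bold_from_array(arr, n_baseline = 3)
  pc <- percent_change_series(b)
  expect_equal(pc$pc[1, 1, 1, 4], 5)
  expect_equal(pc$baseline_mean[1, 1, 1], 1000)

  # zero/negative baseline flagged invalid
  arr[2, 1, 1, ] <- 0
  pc <- percent_change_series(bold_from_array(arr, n_baseline = 3))
  expect_false(pc$valid[2, 1, 1])
  expect_true(all(is.na(pc$pc[2, 1, 1, ])))
})

test_that("zero-noise step effects give exactly the specified percent change", {
  a <- small_atlas()
  eff <- effect_spec(region = 1, group = "mg1", amplitude = 5)
  b <- simulate_bold(a, identity_transform(), eff, noise_sd = 0, seed = 1,
                     group = "mg1", n_baseline = 10, n_stim = 20)
  st <- voxel_ttest(b)
  resp <- st$voxel %in% which(b$truth$positive)
  expect_equal(st$pc_mean[resp], rep(5, sum(resp)), tolerance = 1e-12)
  expect_equal(st$pc_mean[!resp], rep(0, sum(!resp)), tolerance = 1e-12)
})

test_that("voxelwise Welch t-tests match stats::t.test to 1e-10", {
  set.seed(42)
  arr <- array(1000 + rnorm(4 * 4 * 2 * 30, sd = 10), dim = c(4, 4, 2, 30))
  b <- bold_from_array(arr, n_baseline = 12)
  st <- voxel_ttest(b)
  pcs <- percent_change_series(b)
  pc <- matrix(pcs$pc, nrow = 32)
  for (i in sample(nrow(st), 25)) {
    v <- st$voxel[i]
    ref <- t.test(pc[v, 13:30], pc[v, 1:12], var.equal = FALSE)
    expect_equal(st$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(st$pc_mean[i], mean(pc[v, 13:30]), tolerance = 1e-10)
  }
})

test_that("t-test conventions hold for degenerate and separated inputs", {
  # symmetric identical data in both windows: p should not be small
  arr <- array(rep(c(990, 1010), 18), dim = c(1, 1, 1, 36))
  st <- voxel_ttest(bold_from_array(arr, n_baseline = 18))
  expect_gte(st$p, 0.5)

  # near-complete separation
  arr <- array(c(rep(1000, 4), 1050 + c(0.01, -0.01, 0.02, -0.02)),
               dim = c(1, 1, 1, 8))
  st <- voxel_ttest(bold_from_array(arr, n_baseline = 4))
  expect_lt(st$p, 1e-6)

  # zero variance in both windows
  arr_eq <- array(1000, dim = c(1, 1, 1, 8))
  expect_equal(voxel_ttest(bold_from_array(arr_eq, n_baseline = 4))$p, 1)
  arr_ne <- array(c(rep(1000, 4), rep(1100, 4)), dim = c(1, 1, 1, 8))
  expect_equal(voxel_ttest(bold_from_array(arr_ne, n_baseline = 4))$p, 0)
})

test_that("the step-up filter reproduces hand-evaluated cases", {
  # thresholds i/V * q: 0.05, 0.10, 0.15, 0.20
  keep <- fdr_filter(c(0.001, 0.002, 0.9, 0.95), q = 0.2, cV = 1)
  expect_identical(keep, c(TRUE, TRUE, FALSE, FALSE))

  expect_identical(fdr_filter(rep(1, 10)), rep(FALSE, 10))
  expect_identical(fdr_filter(numeric(0)), logical(0))
  expect_error(fdr_filter(c(0.5, 1.5)), "0, 1")

  # the rank-54-of-134 threshold is (54/134)*0.2
  p134 <- c(seq_len(54) / 134 * 0.2 - 1e-9, seq(0.5, 0.99, length.out = 80))
  keep <- fdr_filter(p134, q = 0.2, cV = 1)
  expect_equal(sum(keep), 54)
  expect_equal(max(p134[keep]), 54 / 134 * 0.2 - 1e-9)
})

test_that("the step-up filter matches rank-by-rank evaluation on random instances", {
  set.seed(7)
  for (rep in 1:60) {
    V <- sample(1:20, 1)
    p <- round(runif(V), sample(c(1, 2, 6), 1))  # rounding creates ties
    q <- sample(c(0.05, 0.2, 1), 1)
    expect_identical(fdr_filter(p, q = q, cV = 1), stepup_oracle(p, q, 1),
                     info = sprintf("rep %d", rep))
  }
})

test_that("the step-up filter is monotone in the p-values", {
  set.seed(8)
  for (rep in 1:20) {
    p <- runif(30)
    base <- fdr_filter(p, q = 0.2)
    i <- sample(30, 1)
    p2 <- p
    p2[i] <- p[i] * runif(1)
    lowered <- fdr_filter(p2, q = 0.2)
    expect_true(all(lowered[base]), info = "lowering a p-value never shrinks the retained set")
  }
})

test_that("activation maps respect the 2% threshold and sign partition", {
  # build stats directly: 3 voxels with tiny p, PC +1.5, +5, -4
  st <- structure(
    data.frame(voxel = 1:3, pc_mean = c(1.5, 5, -4), p = c(0.001, 0.001, 0.001)),
    class = c("phbold_voxstats", "data.frame"),
    V = 3, grid_dim = c(3, 1, 1), n_baseline = 5, n_stim = 5)
  m <- build_activation_map(st, retained = rep(TRUE, 3), threshold_pct = 2)
  expect_equal(m$positive[1], 0)  # +1.5% is below the magnitude threshold
  expect_equal(m$positive[2], 5)
  expect_equal(m$negative[3], -4)
  expect_equal(m$n_pos, 1)
  expect_equal(m$n_neg, 1)
  expect_false(any(m$positive != 0 & m$negative != 0))

  # p above alpha is dropped even when retained by the filter
  st$p <- c(0.001, 0.2, 0.001)
  m2 <- build_activation_map(st, retained = rep(TRUE, 3))
  expect_equal(m2$n_pos, 0)
})
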