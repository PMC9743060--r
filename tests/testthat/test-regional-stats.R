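test_that("Kruskal-Wallis handles identical data and matches the rank formula", {
  expect_equal(kruskal_wallis(list(c(3, 3), c(3, 3), c(3, 3))),
               list(H = 0, df = 2L, p = 1))

  kw <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(kw$H, kw_oracle(list(c(1, 2), c(3, 4), c(5, 6))), tolerance = 1e-10)
  expect_equal(kw$p, pchisq(kw$H, 2, lower.tail = FALSE), tolerance = 1e-12)

  set.seed(11)
  for (rep in 1:50) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(i) {
      sample(0:5, sample(2:6, 1), replace = TRUE)  # heavy ties, like voxel counts
    })
    if (length(unique(unlist(groups))) == 1) next
    kw <- kruskal_wallis(groups)
    expect_equal(kw$H, kw_oracle(groups), tolerance = 1e-8,
                 info = sprintf("rep %d", rep))
    expect_equal(kw$p, pchisq(kw$H, k - 1, lower.tail = FALSE), tolerance = 1e-8)
  }
})

test_that("Kruskal-Wallis is invariant under monotone transforms", {
  set.seed(12)
  g <- list(rnorm(5), rnorm(6) + 1, rnorm(4))
  h1 <- kruskal_wallis(g)$H
  h2 <- kruskal_wallis(lapply(g, function(v) exp(v)))$H
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("Wilcoxon rank-sum matches exact enumeration on small untied samples", {
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(10, 11, 12)), 0.1)  # 2 / choose(6, 3)

  set.seed(13)
  for (rep in 1:50) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    vals <- sample(1:100, na + nb)  # distinct -> no ties
    a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
    expect_equal(wilcoxon_ranksum(a, b), ranksum_exact_oracle(a, b),
                 tolerance = 1e-10, info = sprintf("rep %d", rep))
  }
})

test_that("effect size formula, clipping and errors", {
  expect_equal(effect_size(0, 29, 4), 0)
  expect_equal(effect_size(3, 29, 4), 0)  # H = k - 1 is the null expectation
  expect_equal(effect_size(14.8, 29, 4), (14.8 - 3) / 25)
  expect_equal(effect_size(14.8, 29, 4, variant = "simple"), 14.8 / 28)
  expect_equal(effect_size(200, 29, 4), 1)  # clipped
  expect_error(effect_size(5, 4, 4), "exceed")
})

test_that("the region-list cutoff reproduces the published significance levels", {
  # 54 of 134 regions retained at q = 0.2 -> printed level .08
  p54 <- c(seq_len(54) / 134 * 0.2 - 1e-9, seq(0.4, 0.99, length.out = 80))
  tab <- rank_and_cut(data.frame(region = seq_len(134), p = p54), q = 0.2, cV = 1)
  expect_equal(sum(tab$pass), 54)
  expect_equal(attr(tab, "cutoff"), 54 / 134 * 0.2)
  expect_equal(round(attr(tab, "cutoff"), 2), 0.08)

  # 52 retained -> printed level .077
  p52 <- c(seq_len(52) / 134 * 0.2 - 1e-9, seq(0.4, 0.99, length.out = 82))
  tab <- rank_and_cut(data.frame(region = seq_len(134), p = p52), q = 0.2, cV = 1)
  expect_equal(sum(tab$pass), 52)
  expect_equal(floor(attr(tab, "cutoff") * 1000) / 1000, 0.077)

  none <- rank_and_cut(data.frame(region = 1:5, p = rep(1, 5)))
  expect_equal(sum(none$pass), 0)
  expect_true(is.na(attr(none, "cutoff")))
})

test_that("dose-response profiles are classified by the documented rules", {
  # published regional medians with known shapes
  expect_equal(classify_profile(c(0, 164, 136, 8))$label, "descending")
  expect_equal(classify_profile(c(1, 16, 4, 37))$label, "U-shaped")
  expect_equal(classify_profile(c(0, 0, 0, 0))$label, "comparable")
  expect_equal(classify_profile(c(0, 2, 5, 9))$label, "ascending")
  expect_equal(classify_profile(c(0, 30, 0, 0))$label, "single-dose-max")
  expect_equal(classify_profile(c(0, 30, 0, 0))$max_dose, "1.0")
  expect_equal(classify_profile(c(0, 5, 5, 5))$label, "comparable")
  # tolerance folds near-equal medians into "comparable"
  expect_equal(classify_profile(c(6, 46, 44, 52), tol = 10)$label, "comparable")
  expect_equal(classify_profile(c(6, 46, 44, 52))$label, "U-shaped")
})

test_that("the strict dose-maximum tally over the published negative table gives 15 at 3.3 mg", {
  tab <- published_voa("negative")
  expect_equal(nrow(tab), 52)
  max_dose <- apply(tab[, c("mg1", "mg3.3", "mg10")], 1, function(d) {
    if (sum(d == max(d)) > 1) NA_character_ else c("1.0", "3.3", "10")[which.max(d)]
  })
  expect_equal(sum(max_dose == "3.3", na.rm = TRUE), 15)
})

test_that("regional_table assembles medians, omnibus p and the cutoff", {
  set.seed(14)
  groups <- c("vehicle", "mg1", "mg3.3", "mg10")
  counts <- expand.grid(subject_id = sprintf("s%02d", 1:24),
                        region = 1:5, stringsAsFactors = FALSE)
  counts$group <- rep(rep(groups, each = 6), times = 5)
  counts$name <- sprintf("region_%03d", counts$region)
  counts$n_pos <- rpois(nrow(counts), 2)
  counts$n_neg <- 0L
  # region 2 responds strongly at mg1 only
  sel <- counts$region == 2 & counts$group == "mg1"
  counts$n_pos[sel] <- counts$n_pos[sel] + 40
  tab <- regional_table(counts, groups = groups, sign = "n_pos")
  top <- tab[1, ]
  expect_equal(top$region, 2)
  expect_true(top$pass)
  expect_equal(top$max_dose, "mg1")
  expect_gt(top$median_mg1, top$median_vehicle)
  expect_true(all(diff(tab$p) >= 0))
  expect_equal(tab$omega_sq[tab$region == 2],
               effect_size(tab$H[tab$region == 2], 24, 4))
})
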