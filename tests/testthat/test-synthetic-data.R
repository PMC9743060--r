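test_that("make_atlas produces labelled, connected, reproducible parcellations", {
  a1 <- make_atlas(1, c(8, 8, 4), voxel_size = c(1, 1, 1), seed = 1)
  expect_setequal(unique(as.vector(a1$labels)), c(0L, 1L))
  expect_gt(sum(a1$labels == 1), 0)

  a <- small_atlas()
  expect_setequal(sort(unique(a$labels[a$labels > 0])), 1:10)
  expect_true(all(region_sizes(a) > 0))
  for (id in 1:10) expect_true(region_connected(a$labels, id))

  a_again <- make_atlas(10, reduced_shape, reduced_vs, seed = 3)
  expect_identical(a$labels, a_again$labels)

  expect_error(make_atlas(10000, c(8, 8, 4)), "capacity")
})

test_that("full-scale atlas has 134 nonempty regions and ~15,000 brain voxels", {
  a <- make_atlas(134, c(96, 96, 18), seed = 1)
  sizes <- region_sizes(a)
  expect_length(sizes, 134)
  expect_true(all(sizes > 0))
  n_mask <- sum(a$labels > 0)
  expect_gt(n_mask, 15000 * 0.8)
  expect_lt(n_mask, 15000 * 1.2)
})

test_that("subject transforms are invertible, reproducible, and reject degenerate scales", {
  id <- make_subject_transform(0, 0, 0, seed = 1)
  expect_equal(id$matrix, diag(4), tolerance = 1e-12)

  tr <- make_subject_transform(seed = 7, center = c(5, 5, 5))
  expect_lt(max(abs(tr$matrix %*% tr$inverse - diag(4))), 1e-10)
  tr2 <- make_subject_transform(seed = 7, center = c(5, 5, 5))
  expect_identical(tr$matrix, tr2$matrix)

  expect_error(affine_transform(scale = c(0, 1, 1)), "degenerate")

  # parameter -> matrix -> apply round trip: mapping the centre gives
  # centre + translation regardless of rotation/scale
  p <- affine_apply(tr, tr$center)
  expect_equal(as.numeric(p), tr$center + tr$parameters$translation,
               tolerance = 1e-12)
})

test_that("simulate_bold builds exact signals under zero noise", {
  a <- small_atlas()
  tr <- identity_transform()
  b0 <- simulate_bold(a, tr, NULL, noise_sd = 0, seed = 1, n_baseline = 5,
                      n_stim = 10)
  m <- matrix(b0$data, ncol = 15)
  expect_equal(apply(m, 1, function(v) max(v) - min(v)), rep(0, nrow(m)))
  expect_true(all(b0$data > 0))

  eff <- effect_spec(region = 2, group = "mg1", amplitude = 5, fraction = 1)
  b <- simulate_bold(a, tr, eff, noise_sd = 0, seed = 1, group = "mg1",
                     n_baseline = 5, n_stim = 10)
  m <- matrix(b$data, ncol = 15)
  base_mean <- rowMeans(m[, 1:5])
  post_mean <- rowMeans(m[, 6:15])
  ratio <- post_mean / base_mean
  in_region <- as.vector(b$labels == 2)
  expect_equal(ratio[in_region], rep(1.05, sum(in_region)), tolerance = 1e-12)
  expect_equal(ratio[!in_region], rep(1, sum(!in_region)), tolerance = 1e-12)
  expect_identical(b$truth$positive, array(b$labels == 2, dim = dim(b$labels)))
})

test_that("simulate_bold validates effect regions and onsets", {
  a <- small_atlas()
  tr <- identity_transform()
  eff_bad <- effect_spec(region = 99, group = "mg1", amplitude = 5)
  expect_error(simulate_bold(a, tr, eff_bad, group = "mg1",
                             n_baseline = 5, n_stim = 5), "99")
  eff_early <- effect_spec(region = 1, group = "mg1", amplitude = 5, onset = 2)
  expect_error(simulate_bold(a, tr, eff_early, group = "mg1",
                             n_baseline = 5, n_stim = 5), "onset")
})

test_that("positive and negative truth masks are disjoint and complete", {
  a <- small_atlas()
  tr <- identity_transform()
  eff <- effect_spec(region = c(1, 2), group = "mg1", amplitude = c(5, -4),
                     fraction = 0.5)
  b <- simulate_bold(a, tr, eff, noise_sd = 0.5, seed = 9, group = "mg1",
                     n_baseline = 5, n_stim = 10)
  expect_false(any(b$truth$positive & b$truth$negative))
  expect_equal(sum(b$truth$positive), round(0.5 * sum(b$labels == 1)))
  expect_equal(sum(b$truth$negative), round(0.5 * sum(b$labels == 2)))
})

test_that("the activation pipeline recovers >=90% of responding voxels at 1% noise", {
  a <- small_atlas()
  eff <- effect_spec(region = 3, group = "mg1", amplitude = 5, fraction = 0.5)
  tpl <- small_template()
  center <- grid_center_mm(reduced_shape, reduced_vs)
  hits <- 0; total <- 0
  for (s in 1:8) {
    tr <- make_subject_transform(seed = 100 + s, center = center)
    b <- simulate_bold(a, tr, eff, noise_sd = 1, seed = 200 + s,
                       group = "mg1", template = tpl)
    am <- activation_map(b)
    hits <- hits + sum(am$positive != 0 & b$truth$positive)
    total <- total + sum(b$truth$positive)
  }
  expect_gte(hits / total, 0.90)
})

test_that("make_cohort writes a complete, reproducible on-disk dataset", {
  cfg <- list(groups = c(vehicle = 2L, mg1 = 2L, mg3.3 = 0L, mg10 = 1L),
              seed = 11, n_regions = 4L, shape = c(16L, 16L, 6L),
              voxel_size = c(1, 1, 2), n_baseline = 4L, n_stim = 6L)
  d1 <- file.path(tempdir(), "cohort_a")
  d2 <- file.path(tempdir(), "cohort_b")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_cohort(cfg, d1)
  m2 <- make_cohort(cfg, d2)

  expect_length(m1$subjects, 5)
  expect_equal(m1$groups$mg3.3, 0)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))
  for (f in c("sub01_func.nii", "sub03_anat.nii")) {
    v1 <- read_volume(file.path(d1, f))
    v2 <- read_volume(file.path(d2, f))
    expect_identical(as.numeric(v1), as.numeric(v2))
  }

  co <- read_cohort(d1)
  expect_length(co$subjects, 5)
  expect_equal(co$subjects$sub01$group, "vehicle")
  expect_equal(dim(co$subjects$sub01$data), c(16, 16, 6, 10))
  # transforms survive the JSON round trip exactly enough to reuse
  tr_disk <- co$subjects$sub05$transform
  expect_lt(max(abs(tr_disk$matrix %*% tr_disk$inverse - diag(4))), 1e-10)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("cohort generation fails cleanly on an unwritable directory", {
  cfg <- list(groups = c(vehicle = 1L), seed = 1, n_regions = 2L,
              shape = c(8L, 8L, 4L), n_baseline = 3L, n_stim = 3L)
  # /proc rejects directory creation for every user
  expect_error(make_cohort(cfg, "/proc/no_such_dir/x"))
})
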