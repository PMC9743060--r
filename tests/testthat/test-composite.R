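actmap_from <- function(pos, neg = NULL) {
  d <- dim(pos)
  if (is.null(neg)) neg <- array(0, dim = d)
  structure(list(positive = pos, negative = neg,
                 n_pos = sum(pos != 0), n_neg = sum(neg != 0), V = prod(d)),
            class = "phbold_actmap")
}

test_that("composite of one subject under the identity equals its map", {
  a <- small_atlas()
  id <- identity_transform()
  pos <- array(0, dim = reduced_shape)
  pos[a$labels == 2] <- 5
  comp <- build_composite(list(s1 = actmap_from(pos)), list(s1 = id), a, "g")
  expect_equal(comp$positive, pos, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(max(comp$n_contrib), 1)
})

test_that("zeros count in the composite average by default", {
  a <- small_atlas()
  id <- identity_transform()
  m <- array(0, dim = reduced_shape)
  m[a$labels == 2] <- 4
  maps <- list(s1 = actmap_from(m), s2 = actmap_from(array(0, reduced_shape), -m))
  comp <- build_composite(maps, list(s1 = id, s2 = id), a, "g")
  sel <- a$labels == 2
  expect_equal(comp$positive[sel], rep(2, sum(sel)))   # (4 + 0) / 2
  expect_equal(comp$negative[sel], rep(-2, sum(sel)))  # (0 + -4) / 2

  comp_nz <- build_composite(maps, list(s1 = id, s2 = id), a, "g",
                             nonzero_only = TRUE)
  expect_equal(comp_nz$positive[sel], rep(4, sum(sel)))
})

test_that("composite of N identical subjects equals any one of them", {
  a <- small_atlas()
  id <- identity_transform()
  m <- array(0, dim = reduced_shape)
  m[a$labels == 3] <- 2.5
  maps <- list(s1 = actmap_from(m), s2 = actmap_from(m), s3 = actmap_from(m))
  comp <- build_composite(maps, list(s1 = id, s2 = id, s3 = id), a, "g")
  expect_equal(comp$positive, m, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("known subject displacements put the composite peak at the atlas centroid", {
  a <- small_atlas()
  tpl <- small_template()
  center <- grid_center_mm(reduced_shape, reduced_vs)
  eff <- effect_spec(region = 3, group = "mg1", amplitude = 6, fraction = 1)
  maps <- list(); trs <- list()
  for (s in 1:3) {
    tr <- affine_transform(translation = c(s - 2, 2 - s, 0) * 0.75,
                           center = center)
    b <- simulate_bold(a, tr, eff, noise_sd = 0.5, seed = 400 + s,
                       group = "mg1", template = tpl)
    sid <- paste0("s", s)
    maps[[sid]] <- activation_map(b)
    trs[[sid]] <- tr
  }
  comp <- build_composite(maps, trs, a, "mg1")
  vals <- comp$positive
  vals[is.na(vals)] <- 0
  peak <- arrayInd(which.max(vals), reduced_shape)
  truth_centroid <- colMeans(arrayInd(which(a$labels == 3), reduced_shape))
  expect_lt(sqrt(sum((peak - truth_centroid)^2 * c(1, 1, 1))),
            max(dist(arrayInd(which(a$labels == 3), reduced_shape))))
  # stronger: composite mass concentrates inside the true region
  inside <- sum(vals[a$labels == 3]) / sum(vals)
  expect_gt(inside, 0.8)
})

test_that("a missing transform is an error naming the subject", {
  a <- small_atlas()
  m <- actmap_from(array(0, reduced_shape))
  expect_error(
    build_composite(list(subA = m), list(subA = NULL), a, "g"), "subA")
})

test_that("count_activated counts nonzero voxels per region and sign", {
  a <- small_atlas()
  empty <- actmap_from(array(0, reduced_shape))
  cc <- count_activated(empty, a)
  expect_equal(sum(cc$n_pos) + sum(cc$n_neg), 0)

  full <- array(0, dim = reduced_shape)
  full[a$labels == 4] <- 5
  cc <- count_activated(actmap_from(full), a)
  expect_equal(cc$n_pos[cc$region == 4], sum(a$labels == 4))

  set.seed(6)
  vox <- which(a$labels == 5)
  chosen <- sample(vox, round(0.1 * length(vox)))
  sparse <- array(0, dim = reduced_shape)
  sparse[chosen] <- -3
  cc <- count_activated(actmap_from(array(0, reduced_shape), sparse), a)
  expect_equal(cc$n_neg[cc$region == 5], length(chosen))

  small <- list(positive = array(0, c(4, 4, 2)), negative = array(0, c(4, 4, 2)))
  expect_error(count_activated(small, a), "grid")
})
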