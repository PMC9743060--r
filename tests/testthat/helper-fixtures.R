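# Shared small synthetic fixtures, built once per test run.

reduced_vs <- c(0.375, 0.375, 1.5)
reduced_shape <- c(48L, 48L, 9L)

.fixture_env <- new.env()

small_atlas <- function() {
  if (is.null(.fixture_env$atlas)) {
    .fixture_env$atlas <- make_atlas(10, reduced_shape, reduced_vs, seed = 3)
  }
  .fixture_env$atlas
}

small_template <- function() {
  if (is.null(.fixture_env$template)) {
    .fixture_env$template <- make_template(small_atlas(), seed = 3)
  }
  .fixture_env$template
}

identity_transform <- function(shape = reduced_shape, vs = reduced_vs) {
  affine_transform(center = grid_center_mm(shape, vs))
}

# bold object with explicit 4D data
bold_from_array <- function(data4d, n_baseline, labels = NULL,
                            group = "vehicle", subject_id = "s") {
  structure(list(data = data4d, n_baseline = as.integer(n_baseline),
                 n_stim = dim(data4d)[4] - as.integer(n_baseline),
                 voxel_size = c(1, 1, 1), subject_id = subject_id,
                 group = group, labels = labels, truth = NULL,
                 transform = NULL),
            class = "phbold_bold")
}

# independent step-up oracle: evaluate the rule rank by rank
stepup_oracle <- function(p, q, cV) {
  V <- length(p)
  ord <- order(p)
  istar <- 0
  for (i in seq_len(V)) {
    if (p[ord[i]] <= i / V * (q / cV)) istar <- i
  }
  keep <- rep(FALSE, V)
  if (istar > 0) keep[ord[seq_len(istar)]] <- TRUE
  keep
}

# exact two-sided rank-sum p by enumeration of all C(m+n, m) splits
ranksum_exact_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ws <- apply(combs, 2, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# textbook Kruskal-Wallis H with tie correction
kw_oracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# two-factor fixed-effects ANOVA from explicit sums of squares (balanced)
anova2_oracle <- function(value, f1, f2) {
  f1 <- factor(f1); f2 <- factor(f2)
  gm <- mean(value)
  ss_a <- sum(tapply(value, f1, length) * (tapply(value, f1, mean) - gm)^2)
  ss_b <- sum(tapply(value, f2, length) * (tapply(value, f2, mean) - gm)^2)
  cell_mean <- tapply(value, list(f1, f2), mean)
  cell_n <- tapply(value, list(f1, f2), length)
  ss_cells <- sum(cell_n * (cell_mean - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_tot <- sum((value - gm)^2)
  ss_res <- ss_tot - ss_cells
  df_a <- nlevels(f1) - 1
  df_res <- length(value) - nlevels(f1) * nlevels(f2)
  ms_a <- ss_a / df_a
  ms_res <- ss_res / df_res
  list(F = ms_a / ms_res, df1 = df_a, df2 = df_res,
       p = stats::pf(ms_a / ms_res, df_a, df_res, lower.tail = FALSE),
       ss = c(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res, tot = ss_tot))
}

# 26-connectivity check for one labelled region
region_connected <- function(labels, id) {
  vox <- which(labels == id)
  if (length(vox) <= 1) return(TRUE)
  co <- arrayInd(vox, dim(labels))
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  remaining <- stats::setNames(seq_len(nrow(co)), key(co))
  frontier <- 1
  seen <- rep(FALSE, nrow(co))
  seen[1] <- TRUE
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        k <- paste(co[i, 1] + dx, co[i, 2] + dy, co[i, 3] + dz)
        j <- remaining[k]
        if (!is.na(j) && !seen[j]) { seen[j] <- TRUE; nxt <- c(nxt, j) }
      }
    }
    frontier <- nxt
  }
  all(seen)
}
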