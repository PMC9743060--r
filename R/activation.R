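#' Percent signal change relative to the baseline window
#'
#' Expresses every voxel's time series as percent change from its mean
#' over the control (pre-injection) window: PC(v, t) = 100 (S(v, t) -
#' B(v)) / B(v). Voxels whose baseline mean is non-positive cannot be
#' expressed as percent change and are flagged invalid.
#'
#' @param bold a `phbold_bold`.
#' @return list with `pc` (4D array of percent change), `baseline_mean`
#'   (3D) and `valid` (3D logical).
#' @export
percent_change_series <- function(bold) {
  stopifnot(inherits(bold, "phbold_bold"), bold$n_baseline >= 1)
  d <- dim(bold$data)
  n_vox <- prod(d[1:3])
  mat <- matrix(bold$data, nrow = n_vox)
  b <- rowMeans(mat[, seq_len(bold$n_baseline), drop = FALSE])
  valid <- b > 0
  pc <- matrix(NA_real_, nrow = n_vox, ncol = d[4])
  pc[valid, ] <- 100 * (mat[valid, , drop = FALSE] - b[valid]) / b[valid]
  list(pc = array(pc, dim = d),
       baseline_mean = array(b, dim = d[1:3]),
       valid = array(valid, dim = d[1:3]))
}

#' Per-voxel Welch t-tests of stim window against baseline
#'
#' For every in-mask voxel, compares the post-injection acquisitions to
#' the baseline acquisitions with a two-tailed unequal-variance (Welch)
#' t-test, treating acquisitions as independent samples, and records the
#' mean percent change over the stim window. Degenerate voxels (zero
#' variance in both windows) get p = 1 when the means agree and p = 0
#' when they differ.
#'
#' @param bold a `phbold_bold`.
#' @param mask 3D logical; defaults to the subject's brain (labels > 0)
#'   when labels are present, else all valid voxels.
#' @return A `phbold_voxstats`: data.frame with `voxel` (linear index),
#'   `pc_mean` (%), `p`; attributes `V` (number of in-mask valid voxels),
#'   `dim`, `n_baseline`, `n_stim`.
#' @export
voxel_ttest <- function(bold, mask = NULL) {
  stopifnot(bold$n_baseline >= 2, bold$n_stim >= 2)
  pcs <- percent_change_series(bold)
  d <- dim(bold$data)
  if (is.null(mask)) {
    mask <- if (!is.null(bold$labels)) bold$labels > 0 else pcs$valid
  }
  mask <- mask & pcs$valid
  vox <- which(mask)
  n_vox <- prod(d[1:3])
  pc <- matrix(pcs$pc, nrow = n_vox)[vox, , drop = FALSE]
  ib <- seq_len(bold$n_baseline)
  is <- bold$n_baseline + seq_len(bold$n_stim)
  res <- welch_rows(pc[, ib, drop = FALSE], pc[, is, drop = FALSE])
  # the baseline-window mean of PC is identically 0, so the stim-window
  # mean PC equals the baseline-vs-stim mean difference
  out <- data.frame(voxel = vox, pc_mean = res$mean_y, p = res$p)
  structure(out, class = c("phbold_voxstats", "data.frame"),
            V = length(vox), grid_dim = d[1:3],
            n_baseline = bold$n_baseline, n_stim = bold$n_stim)
}

# vectorized Welch t-test, rows of x vs rows of y (two-tailed)
welch_rows <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- (my - mx) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero_se <- se2 == 0
  if (any(zero_se)) {
    p[zero_se] <- ifelse(mx[zero_se] == my[zero_se], 1, 0)
  }
  p[is.na(p)] <- 1
  list(t = t, df = df, p = p, mean_x = mx, mean_y = my, mean_diff = my - mx)
}

#' Rank-based false-positive (step-up FDR) filter
#'
#' Implements the step-up rule P(i) <= (i / V) (q / cV) over the ranked
#' p-values of a region of interest containing V voxels: ranks are
#' assigned ascending, the largest rank i* satisfying the inequality is
#' found, and every voxel with p at or below P(i*) is retained (tie
#' invariant). With q = 0.2 and cV = 1 this is the configuration that
#' keeps the expected false-positive rate of the activation maps below
#' 0.05. Returns an all-FALSE mask when no rank satisfies the rule.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @param q false-positive filter value, in (0, 1\].
#' @param cV predetermined constant, >= 1 (unity for conservative
#'   estimates under arbitrary dependence would be sum(1/i); here the
#'   published analysis sets it to 1).
#' @return logical retention mask aligned with `pvalues`.
#' @export
fdr_filter <- function(pvalues, q = 0.2, cV = 1) {
  stopifnot(q > 0, q <= 1, cV >= 1)
  V <- length(pvalues)
  if (V == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  sp <- sort(pvalues)
  ok <- sp <= seq_len(V) / V * (q / cV)
  if (!any(ok)) return(rep(FALSE, V))
  pvalues <= sp[max(which(ok))]
}

#' Threshold retained voxels into a sign-split activation map
#'
#' A voxel enters the positive component when it was retained by the
#' false-positive filter, its t-test is significant at `alpha`
#' (two-tailed 95% confidence by default), and its stim-window mean
#' percent change is at least `+threshold_pct`; the negative component
#' mirrors this at `-threshold_pct`. The magnitude threshold (2% by
#' default) absorbs normal BOLD fluctuations of the awake rodent brain.
#' Retained voxels keep their percent-change values; all others are 0.
#'
#' @param stats a `phbold_voxstats`.
#' @param retained logical retention mask from [fdr_filter()], aligned
#'   with the rows of `stats`.
#' @param threshold_pct magnitude threshold, percent.
#' @param alpha per-voxel significance level for the t-test.
#' @return A `phbold_actmap`: list with `positive` and `negative` 3D
#'   arrays of retained percent-change values, voxel counts `n_pos`,
#'   `n_neg`, and `V`.
#' @export
build_activation_map <- function(stats, retained, threshold_pct = 2, alpha = 0.05) {
  stopifnot(inherits(stats, "phbold_voxstats"),
            length(retained) == nrow(stats), threshold_pct >= 0)
  d <- attr(stats, "grid_dim")
  pos <- array(0, dim = d)
  neg <- array(0, dim = d)
  keep <- retained & stats$p <= alpha
  up <- keep & stats$pc_mean >= threshold_pct
  dn <- keep & stats$pc_mean <= -threshold_pct
  pos[stats$voxel[up]] <- stats$pc_mean[up]
  neg[stats$voxel[dn]] <- stats$pc_mean[dn]
  structure(list(positive = pos, negative = neg,
                 n_pos = sum(up), n_neg = sum(dn), V = attr(stats, "V")),
            class = "phbold_actmap")
}

#' @export
print.phbold_actmap <- function(x, ...) {
  cat(sprintf("Activation map: %d positive, %d negative of %d in-mask voxels\n",
              x$n_pos, x$n_neg, x$V))
  invisible(x)
}

#' One-call activation mapping for a subject
#'
#' Runs percent change, per-voxel Welch t-tests, the step-up
#' false-positive filter and the magnitude threshold.
#'
#' @param bold a `phbold_bold`.
#' @param q,cV filter parameters, see [fdr_filter()].
#' @param threshold_pct,alpha see [build_activation_map()].
#' @param mask optional 3D logical analysis mask.
#' @return a `phbold_actmap`.
#' @export
activation_map <- function(bold, q = 0.2, cV = 1, threshold_pct = 2,
                           alpha = 0.05, mask = NULL) {
  stats <- voxel_ttest(bold, mask = mask)
  retained <- fdr_filter(stats$p, q = q, cV = cV)
  build_activation_map(stats, retained, threshold_pct = threshold_pct,
                       alpha = alpha)
}
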