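#' Mean percent-change time course of a region set
#'
#' Averages the percent-change series over a population of voxels
#' belonging to a set of atlas regions in the subject's own space. By
#' default only voxels retained in the subject's activation map of the
#' requested sign enter the average; `use = "all"` averages every voxel
#' of the set instead.
#'
#' @param bold a `phbold_bold` (with subject-space `labels`).
#' @param region_set integer vector of region ids (e.g. the four
#'   hippocampal areas).
#' @param sign "positive" or "negative".
#' @param map the subject's `phbold_actmap`; required for
#'   `use = "retained"`.
#' @param use "retained" or "all".
#' @return data.frame with `acquisition` (1-based) and `value` (mean
#'   percent change, %); attribute `n_voxels`.
#' @export
region_timecourse <- function(bold, region_set, sign = c("positive", "negative"),
                              map = NULL, use = c("retained", "all")) {
  sign <- match.arg(sign)
  use <- match.arg(use)
  stopifnot(length(region_set) >= 1)
  in_set <- bold$labels %in% region_set
  dim(in_set) <- dim(bold$labels)
  if (use == "retained") {
    if (is.null(map)) stop("use = 'retained' requires the subject's activation map")
    in_set <- in_set & map[[sign]] != 0
  }
  vox <- which(in_set)
  if (length(vox) == 0) {
    stop(sprintf("empty voxel population for region set {%s} (%s, %s voxels)",
                 paste(region_set, collapse = ", "), sign, use))
  }
  pcs <- percent_change_series(bold)
  d <- dim(bold$data)
  pc <- matrix(pcs$pc, nrow = prod(d[1:3]))[vox, , drop = FALSE]
  structure(data.frame(acquisition = seq_len(d[4]), value = colMeans(pc)),
            n_voxels = length(vox))
}

#' Two-way (treatment x time) ANOVA on post-injection time courses
#'
#' Fixed-effects two-factor analysis of variance on subject x time-bin
#' percent-change values over the post-injection window only, comparing
#' two treatment levels. Time is binned into `n_bins` equal windows
#' (averaging within bins) before fitting `value ~ treatment * time`.
#' Reports the treatment main effect and the direction of the marginal
#' treatment means.
#'
#' @param timecourses data.frame with columns `subject_id`, `treatment`
#'   (exactly 2 levels, each with >= 2 subjects), `acquisition`,
#'   `value`.
#' @param n_baseline acquisitions to drop as the baseline window.
#' @param n_bins number of post-injection time bins (NULL keeps every
#'   acquisition as its own level).
#' @return list with `F`, `df1`, `df2`, `p`, `direction` (label of the
#'   larger treatment), and the full `anova` table.
#' @export
two_way_anova <- function(timecourses, n_baseline = 50L, n_bins = NULL) {
  df <- timecourses[timecourses$acquisition > n_baseline, , drop = FALSE]
  df$treatment <- factor(df$treatment)
  if (nlevels(df$treatment) != 2) stop("exactly two treatment levels required")
  n_per <- tapply(df$subject_id, df$treatment, function(s) length(unique(s)))
  if (any(n_per < 2)) stop("each treatment group needs at least two subjects")
  if (!is.null(n_bins)) {
    post <- sort(unique(df$acquisition))
    df$time <- cut(match(df$acquisition, post), breaks = n_bins, labels = FALSE)
    df <- stats::aggregate(value ~ subject_id + treatment + time, df, mean)
  } else {
    df$time <- df$acquisition
  }
  df$time <- factor(df$time)
  fit <- stats::aov(value ~ treatment * time, data = df)
  tab <- summary(fit)[[1]]
  rn <- trimws(rownames(tab))
  trt <- tab[match("treatment", rn), ]
  means <- tapply(df$value, df$treatment, mean)
  Fv <- trt[["F value"]]
  # a treatment sum of squares at rounding-noise level is a null effect,
  # not a 0/0 ratio
  null_trt <- is.na(Fv) ||
    trt[["Sum Sq"]] <= 1e-10 * max(sum(tab[["Sum Sq"]]), 1e-300)
  list(F = if (null_trt) 0 else Fv,
       df1 = trt[["Df"]],
       df2 = tab[match("Residuals", rn), "Df"],
       p = if (null_trt || is.na(trt[["Pr(>F)"]])) 1 else trt[["Pr(>F)"]],
       direction = names(means)[which.max(means)],
       anova = tab)
}

#' Stack region time courses for a set of subjects
#'
#' @param subjects named list of `phbold_bold`.
#' @param maps named list of `phbold_actmap`, parallel to `subjects`.
#' @param region_set,sign,use see [region_timecourse()].
#' @return long data.frame (subject_id, treatment, acquisition, value);
#'   subjects with an empty voxel population are dropped with a message.
#' @export
cohort_timecourses <- function(subjects, maps, region_set,
                               sign = "positive", use = "retained") {
  rows <- lapply(names(subjects), function(sid) {
    tc <- tryCatch(
      region_timecourse(subjects[[sid]], region_set, sign = sign,
                        map = maps[[sid]], use = use),
      error = function(e) NULL)
    if (is.null(tc)) return(NULL)
    data.frame(subject_id = sid, treatment = subjects[[sid]]$group,
               acquisition = tc$acquisition, value = tc$value,
               stringsAsFactors = FALSE)
  })
  kept <- !vapply(rows, is.null, logical(1))
  if (!all(kept)) {
    message(sum(!kept), " subject(s) had no voxels in the region set and were dropped")
  }
  do.call(rbind, rows[kept])
}
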