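#' Summarize a motion trace
#'
#' Axis-wise mean, SD (population formula) and maximum absolute
#' displacement over all acquisitions, measured from the reference
#' (first-acquisition) position. These are the quantities reported in
#' awake-imaging motion summaries.
#'
#' @param trace data.frame with columns `x_um`, `y_um`, `z_um` (and
#'   optionally `acquisition`), displacements in micrometres.
#' @return one-row data.frame with `<axis>_mean`, `<axis>_sd`,
#'   `<axis>_max` for x, y, z plus `excluded` (FALSE until
#'   [apply_exclusion()] is run) and `reason`.
#' @export
summarize_motion <- function(trace) {
  stopifnot(is.data.frame(trace))
  if (nrow(trace) == 0) stop("empty motion trace")
  cols <- c("x_um", "y_um", "z_um")
  stopifnot(all(cols %in% names(trace)))
  out <- list()
  for (ax in c("x", "y", "z")) {
    v <- trace[[paste0(ax, "_um")]]
    if (any(!is.finite(v))) stop("non-finite displacement in motion trace")
    out[[paste0(ax, "_mean")]] <- mean(v)
    out[[paste0(ax, "_sd")]] <- sqrt(mean((v - mean(v))^2))
    out[[paste0(ax, "_max")]] <- max(abs(v))
  }
  out$excluded <- FALSE
  out$reason <- NA_character_
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Apply the half-voxel motion exclusion rule
#'
#' A subject is excluded when its maximum absolute in-plane (X or Y)
#' displacement strictly exceeds half of one in-plane voxel. The default
#' of 93.75 um is half the 187.5 um in-plane resolution; through-plane
#' (Z) motion is reported but does not exclude.
#'
#' @param summary a row from [summarize_motion()] (multi-row input is
#'   processed rowwise).
#' @param half_voxel_um exclusion threshold, um; must be positive.
#' @return the summary with `excluded` and `reason` filled in.
#' @export
apply_exclusion <- function(summary, half_voxel_um = 93.75) {
  stopifnot(half_voxel_um > 0)
  for (i in seq_len(nrow(summary))) {
    worst_ax <- NA_character_
    worst <- -Inf
    for (ax in c("x", "y")) {
      m <- summary[[paste0(ax, "_max")]][i]
      if (m > worst) { worst <- m; worst_ax <- ax }
    }
    if (worst > half_voxel_um) {
      summary$excluded[i] <- TRUE
      summary$reason[i] <- sprintf("max in-plane displacement %.2f um on %s axis exceeds %.2f um",
                                   worst, toupper(worst_ax), half_voxel_um)
    } else {
      summary$excluded[i] <- FALSE
      summary$reason[i] <- NA_character_
    }
  }
  summary
}

#' Motion QC for a whole cohort
#'
#' @param subjects list of `phbold_bold` objects carrying `$motion`
#'   traces (as loaded by [read_cohort()]), or a named list of traces.
#' @param half_voxel_um exclusion threshold, um.
#' @return data.frame, one row per subject, with subject_id, group,
#'   per-axis summaries, `excluded` and `reason`.
#' @export
motion_qc_table <- function(subjects, half_voxel_um = 93.75) {
  rows <- lapply(names(subjects), function(sid) {
    s <- subjects[[sid]]
    trace <- if (is.data.frame(s)) s else s$motion
    grp <- if (is.data.frame(s)) NA_character_ else s$group
    cbind(data.frame(subject_id = sid, group = grp, stringsAsFactors = FALSE),
          apply_exclusion(summarize_motion(trace), half_voxel_um))
  })
  do.call(rbind, rows)
}
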