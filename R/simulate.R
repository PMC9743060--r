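#' Specify regional dose-dependent BOLD effects
#'
#' One row per (region, group) combination: the signed percent-change
#' amplitude injected into that region for subjects of that group, the
#' fraction of the region's voxels that respond, the onset acquisition
#' (0-based; the injection occurs after the baseline window, so onsets
#' are at or after `n_baseline`), and the response shape.
#'
#' @param region integer region ids.
#' @param group group labels (recycled), e.g. "vehicle", "mg1", "mg3.3", "mg10".
#' @param amplitude signed percent change (positive = activation,
#'   negative = deactivation). Must be nonzero.
#' @param fraction fraction of region voxels responding, in \[0, 1\].
#' @param onset 0-based acquisition index at which the response starts.
#' @param shape "step" (full amplitude from onset) or "ramp" (linear
#'   rise over `ramp` acquisitions, emulating drug levels peaking within
#'   minutes of injection).
#' @param ramp ramp length, acquisitions.
#' @return data.frame of class `phbold_effects`.
#' @export
effect_spec <- function(region, group, amplitude, fraction = 1,
                        onset = NA_integer_, shape = "step", ramp = 5L) {
  df <- data.frame(region = as.integer(region), group = as.character(group),
                   amplitude = as.numeric(amplitude),
                   fraction = as.numeric(fraction),
                   onset = as.integer(onset), shape = as.character(shape),
                   ramp = as.integer(ramp), stringsAsFactors = FALSE)
  stopifnot(all(df$fraction >= 0 & df$fraction <= 1),
            all(df$amplitude != 0),
            all(df$shape %in% c("step", "ramp")))
  class(df) <- c("phbold_effects", "data.frame")
  df
}

#' Simulate one subject's 4D BOLD acquisition
#'
#' Generates a functional series on the subject grid: the subject's
#' anatomy is the atlas template resampled through the subject's
#' ground-truth transform, baseline intensity equals that anatomy, and
#' each effect multiplies responding voxels by (1 + amplitude/100) from
#' its onset. Noise is independent Gaussian per voxel and acquisition,
#' scaled as a percentage of each voxel's baseline; an optional linear
#' drift is centred on the baseline window so baseline means stay at
#' their nominal values in expectation.
#'
#' @param atlas a `phbold_atlas`.
#' @param transform the subject's `phbold_affine` (subject -> atlas, mm).
#' @param effects a `phbold_effects` (rows for other groups are ignored)
#'   or NULL for no injected response.
#' @param noise_sd Gaussian noise SD as percent of baseline intensity.
#' @param drift_slope linear drift in percent of baseline per acquisition.
#' @param seed integer seed (noise and responder selection).
#' @param n_baseline,n_stim control-window and post-injection acquisition
#'   counts (50 and 100 at full scale: 150 scans over 15 min, the first
#'   50 forming the 5 min baseline).
#' @param group subject's treatment group label.
#' @param subject_id identifier string.
#' @param template atlas-space intensity template; defaults to
#'   `make_template(atlas)` (shared across subjects so registration has a
#'   common target).
#' @return A `phbold_bold`: list with `data` (4D array x,y,z,t),
#'   `n_baseline`, `n_stim`, `voxel_size`, `subject_id`, `group`,
#'   subject-space `anat` and `labels`, ground-truth responder masks
#'   `truth` (`$positive`, `$negative`, logical 3D), and `transform`.
#' @export
simulate_bold <- function(atlas, transform, effects = NULL,
                          noise_sd = 1, drift_slope = 0, seed = 1L,
                          n_baseline = 50L, n_stim = 100L,
                          group = "vehicle", subject_id = "s01",
                          template = NULL) {
  stopifnot(noise_sd >= 0, n_baseline >= 1, n_stim >= 1)
  if (is.null(template)) template <- make_template(atlas)
  shape <- dim(atlas$labels)
  vs <- atlas$voxel_size
  n_t <- n_baseline + n_stim

  anat <- resample_volume(template, transform$matrix, shape, vs,
                          src_voxel_size = vs, fill = 100)
  labels <- resample_volume(atlas$labels, transform$matrix, shape, vs,
                            src_voxel_size = vs, method = "nearest", fill = 0)
  labels <- array(as.integer(labels), dim = shape)

  rng <- local_rng(seed)
  truth_pos <- array(FALSE, dim = shape)
  truth_neg <- array(FALSE, dim = shape)
  n_vox <- prod(shape)
  # per-voxel multiplicative gain over time, built effect by effect
  gain <- NULL
  if (!is.null(effects)) {
    eff <- effects[effects$group == group, , drop = FALSE]
    if (nrow(eff) > 0) {
      known <- as.integer(names(atlas$names))
      bad <- setdiff(eff$region, known)
      if (length(bad) > 0) {
        stop(sprintf("effect references unknown region id(s): %s",
                     paste(bad, collapse = ", ")))
      }
      gain <- matrix(0, nrow = 0, ncol = n_t)
      gain_vox <- integer(0)
      for (i in seq_len(nrow(eff))) {
        vox <- which(labels == eff$region[i])
        if (length(vox) == 0) next
        n_resp <- round(eff$fraction[i] * length(vox))
        if (n_resp == 0) next
        vox <- sort(vox[rng$sample_int(length(vox), n_resp)])
        onset <- if (is.na(eff$onset[i])) n_baseline else eff$onset[i]
        if (onset < n_baseline) {
          stop("effect onset precedes the end of the baseline window")
        }
        g <- time_profile(n_t, onset, eff$shape[i], eff$ramp[i])
        gain <- rbind(gain, matrix(rep(eff$amplitude[i] * g, each = length(vox)),
                                   nrow = length(vox)))
        gain_vox <- c(gain_vox, vox)
        if (eff$amplitude[i] > 0) truth_pos[vox] <- TRUE else truth_neg[vox] <- TRUE
      }
      if (length(gain_vox) > 0) {
        gain <- list(vox = gain_vox, pct = gain)
      } else {
        gain <- NULL
      }
    }
  }

  base <- as.numeric(anat)
  data <- matrix(rep(base, n_t), nrow = n_vox)
  if (!is.null(gain)) {
    data[gain$vox, ] <- data[gain$vox, ] * (1 + gain$pct / 100)
  }
  if (drift_slope != 0) {
    t_idx <- seq_len(n_t)
    drift <- 1 + drift_slope / 100 * (t_idx - mean(seq_len(n_baseline)))
    data <- data * rep(drift, each = n_vox)
  }
  if (noise_sd > 0) {
    data <- data + base * noise_sd / 100 *
      matrix(rng$rnorm(n_vox * n_t), nrow = n_vox)
  }
  data <- pmax(data, 1e-6)
  dim(data) <- c(shape, n_t)

  structure(list(data = data, n_baseline = as.integer(n_baseline),
                 n_stim = as.integer(n_stim), voxel_size = vs,
                 subject_id = subject_id, group = group,
                 anat = anat, labels = labels,
                 truth = list(positive = truth_pos, negative = truth_neg),
                 transform = transform),
            class = "phbold_bold")
}

# 0/1 response profile over acquisitions (1-based t; onset 0-based)
time_profile <- function(n_t, onset, shape, ramp) {
  t0 <- onset + 1  # first responding acquisition, 1-based
  g <- numeric(n_t)
  if (t0 > n_t) return(g)
  if (shape == "step") {
    g[t0:n_t] <- 1
  } else {
    rise <- pmin(seq_len(n_t) - t0 + 1, ramp) / ramp
    g[t0:n_t] <- rise[t0:n_t]
  }
  g
}

#' @export
print.phbold_bold <- function(x, ...) {
  cat(sprintf("BOLD series %s (%s): grid %s, %d baseline + %d stim acquisitions\n",
              x$subject_id, x$group, paste(dim(x$data)[1:3], collapse = "x"),
              x$n_baseline, x$n_stim))
  invisible(x)
}

#' Simulate a head-motion trace
#'
#' Mean-reverting random walk per axis with a configurable stationary
#' SD (default 10 um, the magnitude seen in well-restrained awake mice,
#' whose largest in-plane excursions are a few tens of um). An optional
#' spike can be injected to exercise the exclusion rule.
#'
#' @param n_acq number of acquisitions.
#' @param sd_um stationary displacement SD, um.
#' @param seed integer seed.
#' @param spike optional list(axis = "x"|"y"|"z", index, magnitude_um).
#' @return data.frame (acquisition, x_um, y_um, z_um).
#' @export
simulate_motion_trace <- function(n_acq = 150L, sd_um = 10, seed = 1L, spike = NULL) {
  rng <- local_rng(seed)
  phi <- 0.9
  step_sd <- sd_um * sqrt(1 - phi^2)
  one_axis <- function() {
    x <- numeric(n_acq)
    e <- rng$rnorm(n_acq, 0, step_sd)
    x[1] <- rng$rnorm(1, 0, sd_um)
    for (t in seq_len(n_acq - 1)) x[t + 1] <- phi * x[t] + e[t + 1]
    x
  }
  tr <- data.frame(acquisition = seq_len(n_acq),
                   x_um = one_axis(), y_um = one_axis(), z_um = one_axis())
  if (!is.null(spike)) {
    col <- paste0(spike$axis, "_um")
    tr[[col]][spike$index] <- spike$magnitude_um
  }
  tr
}

#' Write a synthetic cohort to disk
#'
#' Generates and writes a full multi-group cohort: a shared atlas and
#' template, one anatomical and one functional NIfTI per subject,
#' per-subject motion traces (TSV), ground-truth transforms (JSON) and
#' responder masks (NIfTI), and a JSON manifest with group assignments.
#'
#' @param config list with elements `groups` (named integer vector of
#'   group sizes, e.g. c(vehicle = 7, mg1 = 8, mg3.3 = 6, mg10 = 8)),
#'   `effects` (a `phbold_effects` or NULL), `seed`, and optionally
#'   `n_regions`, `shape`, `voxel_size`, `noise_sd`, `drift_slope`,
#'   `n_baseline`, `n_stim`, `motion_sd_um`, `motion_spikes` (named list
#'   subject_id -> spike), `scale_jitter`, `rotation_jitter`,
#'   `translation_jitter`.
#' @param out_dir output directory (created).
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
make_cohort <- function(config, out_dir) {
  config <- cohort_config(config)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  atlas <- make_atlas(config$n_regions, config$shape, config$voxel_size,
                      seed = config$seed)
  template <- make_template(atlas, seed = config$seed)
  write_atlas(atlas, file.path(out_dir, "atlas"))
  write_volume(template, file.path(out_dir, "template.nii"))

  seeds <- subject_seeds(config$seed, sum(config$groups) + 1)
  center <- grid_center_mm(config$shape, config$voxel_size)
  subjects <- list()
  si <- 0
  for (g in names(config$groups)) {
    n_g <- config$groups[[g]]
    if (n_g == 0) next
    for (k in seq_len(n_g)) {
      si <- si + 1
      sid <- sprintf("sub%02d", si)
      s_seed <- seeds[si]
      tr <- make_subject_transform(config$scale_jitter, config$rotation_jitter,
                                   config$translation_jitter,
                                   seed = s_seed, center = center)
      bold <- simulate_bold(atlas, tr, config$effects,
                            noise_sd = config$noise_sd,
                            drift_slope = config$drift_slope,
                            seed = s_seed + 1L,
                            n_baseline = config$n_baseline,
                            n_stim = config$n_stim,
                            group = g, subject_id = sid,
                            template = template)
      spike <- config$motion_spikes[[sid]]
      motion <- simulate_motion_trace(config$n_baseline + config$n_stim,
                                      sd_um = config$motion_sd_um,
                                      seed = s_seed + 2L, spike = spike)
      paths <- list(
        anat = file.path(out_dir, paste0(sid, "_anat.nii")),
        func = file.path(out_dir, paste0(sid, "_func.nii")),
        motion = file.path(out_dir, paste0(sid, "_motion.tsv")),
        transform = file.path(out_dir, paste0(sid, "_transform.json")),
        truth_pos = file.path(out_dir, paste0(sid, "_truth_pos.nii")),
        truth_neg = file.path(out_dir, paste0(sid, "_truth_neg.nii"))
      )
      write_volume(bold$anat, paths$anat)
      write_volume(bold$data, paths$func, voxel_size = bold$voxel_size)
      utils::write.table(motion, paths$motion, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      write_transform(bold$transform, paths$transform)
      write_volume(bold$truth$positive + 0, paths$truth_pos,
                   voxel_size = bold$voxel_size)
      write_volume(bold$truth$negative + 0, paths$truth_neg,
                   voxel_size = bold$voxel_size)
      subjects[[sid]] <- c(list(subject_id = sid, group = g, seed = s_seed),
                           lapply(paths, basename))
    }
  }
  manifest <- list(
    seed = config$seed,
    groups = as.list(config$groups),
    n_baseline = config$n_baseline, n_stim = config$n_stim,
    shape = config$shape, voxel_size = config$voxel_size,
    n_regions = config$n_regions,
    atlas = "atlas_labels.nii", atlas_names = "atlas_names.tsv",
    template = "template.nii",
    subjects = unname(subjects)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# fill cohort config defaults
cohort_config <- function(config) {
  defaults <- list(
    groups = c(vehicle = 8L, mg1 = 8L, mg3.3 = 8L, mg10 = 8L),
    effects = NULL, seed = 1L,
    n_regions = 134L, shape = c(96L, 96L, 18L),
    voxel_size = c(0.1875, 0.1875, 0.75),
    noise_sd = 1, drift_slope = 0,
    n_baseline = 50L, n_stim = 100L,
    motion_sd_um = 10, motion_spikes = list(),
    scale_jitter = 0.03, rotation_jitter = 0.05, translation_jitter = 0.4
  )
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  stopifnot(!is.null(names(config$groups)), all(config$groups >= 0))
  config
}

# deterministic per-subject seed expansion from one root seed
subject_seeds <- function(root_seed, n) {
  rng <- local_rng(root_seed)
  rng$sample_int(2^30, n) * 2L
}
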