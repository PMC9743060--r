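#' Pipeline configuration
#'
#' Assembles and validates the parameter set of a full analysis run.
#' Defaults follow the awake-mouse study conditions: 50 baseline + 100
#' post-injection acquisitions, q = 0.2 with cV = 1 and a 2% magnitude
#' threshold, SPM-style registration settings (quality 0.97, smoothing
#' 0.35 mm, separation 0.50 mm) with 0.8 mm FWHM map smoothing, and a
#' 93.75 um half-voxel motion exclusion.
#'
#' @param groups named integer vector of group sizes (vehicle first).
#' @param effects a `phbold_effects` or NULL.
#' @param seed root seed; per-subject seeds are expanded from it.
#' @param shape,n_regions,voxel_size synthetic grid and atlas scale.
#' @param n_baseline,n_stim acquisition windows.
#' @param q,cV,threshold_pct,alpha activation filter parameters.
#' @param quality,smoothing_mm,separation_mm,fwhm_mm registration and
#'   map-smoothing parameters.
#' @param reg_search_mm,reg_maxit translation search half-width and
#'   optimizer iteration cap for per-subject registration.
#' @param half_voxel_um motion exclusion threshold.
#' @param registration "estimate" runs intensity-based registration;
#'   "truth" uses the simulator's ground-truth transforms.
#' @param smooth_maps smooth subject percent-change maps with `fwhm_mm`
#'   before compositing.
#' @param noise_sd,drift_slope,motion_sd_um,motion_spikes simulator
#'   settings, see [make_cohort()].
#' @param region_sets named list of integer region-id vectors for
#'   time-course analyses.
#' @param timecourse_use average "all" region voxels (default, so
#'   vehicle subjects contribute a trace) or only "retained" voxels of
#'   the requested sign.
#' @param ... further overrides stored verbatim.
#' @return list of class `phbold_config`.
#' @export
pipeline_config <- function(groups = c(vehicle = 8L, mg1 = 8L, mg3.3 = 8L, mg10 = 8L),
                            effects = NULL, seed = 1L,
                            shape = c(48L, 48L, 9L), n_regions = 20L,
                            voxel_size = c(0.375, 0.375, 1.5),
                            n_baseline = 50L, n_stim = 100L,
                            q = 0.2, cV = 1, threshold_pct = 2, alpha = 0.05,
                            quality = 0.97, smoothing_mm = 0.35,
                            separation_mm = 0.50, fwhm_mm = 0.8,
                            reg_search_mm = 1.5, reg_maxit = 400L,
                            half_voxel_um = 93.75,
                            registration = c("estimate", "truth"),
                            smooth_maps = FALSE,
                            noise_sd = 1, drift_slope = 0,
                            motion_sd_um = 10, motion_spikes = list(),
                            region_sets = list(),
                            timecourse_use = c("all", "retained"), ...) {
  registration <- match.arg(registration)
  timecourse_use <- match.arg(timecourse_use)
  cfg <- c(as.list(environment()), list(...))
  stopifnot(cfg$q > 0, cfg$q <= 1, cfg$cV >= 1, cfg$threshold_pct >= 0,
            cfg$n_baseline >= 2, cfg$n_stim >= 2,
            cfg$half_voxel_um > 0, cfg$noise_sd >= 0)
  class(cfg) <- c("phbold_config", "list")
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes, in order: cohort simulation, motion QC with the half-voxel
#' exclusion, per-subject voxelwise activation mapping, subject-to-atlas
#' registration, group composite maps, regional volume-of-activation
#' tables for both signs, and (when region sets are configured)
#' time-course extraction with the treatment-by-time ANOVA against
#' vehicle. Excluded subjects take no part in any downstream statistic.
#'
#' @param config a `phbold_config`.
#' @param out_dir optional directory; when given, tables, composites and
#'   a provenance record (config hash + seed) are written there.
#' @param cohort optional pre-built cohort (as from [read_cohort()]);
#'   when NULL the cohort is simulated in memory from `config`.
#' @return list with `qc`, `maps`, `transforms`, `composites`,
#'   `tables` (`$positive`, `$negative`), `timecourses`, `anova`,
#'   `atlas`, `subjects_used`, `provenance`.
#' @export
run_pipeline <- function(config, out_dir = NULL, cohort = NULL) {
  stopifnot(inherits(config, "phbold_config"))
  if (is.null(cohort)) {
    atlas <- make_atlas(config$n_regions, config$shape, config$voxel_size,
                        seed = config$seed)
    template <- make_template(atlas, seed = config$seed)
    seeds <- subject_seeds(config$seed, sum(config$groups))
    center <- grid_center_mm(config$shape, config$voxel_size)
    subjects <- list()
    si <- 0
    for (g in names(config$groups)) {
      ng <- config$groups[[g]]
      if (ng == 0) next
      for (k in seq_len(ng)) {
        si <- si + 1
        sid <- sprintf("sub%02d", si)
        tr <- make_subject_transform(seed = seeds[si], center = center)
        b <- simulate_bold(atlas, tr, config$effects,
                           noise_sd = config$noise_sd,
                           drift_slope = config$drift_slope,
                           seed = seeds[si] + 1L,
                           n_baseline = config$n_baseline,
                           n_stim = config$n_stim,
                           group = g, subject_id = sid, template = template)
        b$motion <- simulate_motion_trace(config$n_baseline + config$n_stim,
                                          sd_um = config$motion_sd_um,
                                          seed = seeds[si] + 2L,
                                          spike = config$motion_spikes[[sid]])
        subjects[[sid]] <- b
      }
    }
  } else {
    atlas <- cohort$atlas
    template <- cohort$template
    subjects <- cohort$subjects
  }

  qc <- motion_qc_table(subjects, half_voxel_um = config$half_voxel_um)
  used <- qc$subject_id[!qc$excluded]
  subjects_used <- subjects[used]

  maps <- lapply(subjects_used, function(b) {
    activation_map(b, q = config$q, cV = config$cV,
                   threshold_pct = config$threshold_pct, alpha = config$alpha)
  })
  if (isTRUE(config$smooth_maps)) {
    maps <- lapply(maps, function(m) {
      m$positive <- smooth_gaussian(m$positive, config$fwhm_mm, config$voxel_size)
      m$negative <- smooth_gaussian(m$negative, config$fwhm_mm, config$voxel_size)
      m
    })
  }

  transforms <- lapply(subjects_used, function(b) {
    if (config$registration == "truth") {
      b$transform
    } else {
      register_affine(b$anat, template, voxel_size = config$voxel_size,
                      quality = config$quality,
                      smoothing_mm = config$smoothing_mm,
                      separation_mm = config$separation_mm,
                      search_mm = config$reg_search_mm,
                      maxit = config$reg_maxit)
    }
  })

  groups_present <- unique(vapply(subjects_used, function(b) b$group, character(1)))
  composites <- lapply(groups_present, function(g) {
    sel <- vapply(subjects_used, function(b) b$group == g, logical(1))
    build_composite(maps[sel], transforms[sel], atlas, group = g)
  })
  names(composites) <- groups_present

  counts <- do.call(rbind, lapply(used, function(sid) {
    am <- maps[[sid]]
    atlas_map <- list(
      positive = map_to_atlas(am$positive, transforms[[sid]], atlas, method = "nearest"),
      negative = map_to_atlas(am$negative, transforms[[sid]], atlas, method = "nearest"))
    cbind(data.frame(subject_id = sid, group = subjects_used[[sid]]$group,
                     stringsAsFactors = FALSE),
          count_activated(atlas_map, atlas))
  }))

  group_order <- names(config$groups)
  tables <- list(
    positive = regional_table(counts, groups = group_order, sign = "n_pos",
                              q = config$q, cV = config$cV),
    negative = regional_table(counts, groups = group_order, sign = "n_neg",
                              q = config$q, cV = config$cV))

  timecourses <- list()
  anova <- list()
  for (set_name in names(config$region_sets)) {
    for (sgn in c("positive", "negative")) {
      tc <- cohort_timecourses(subjects_used, maps,
                               config$region_sets[[set_name]], sign = sgn,
                               use = config$timecourse_use)
      key <- paste(set_name, sgn, sep = "_")
      timecourses[[key]] <- tc
      if (!is.null(tc)) {
        sel <- tc$treatment %in% c(group_order[1], group_order[2])
        two <- tc[sel, , drop = FALSE]
        if (length(unique(two$treatment)) == 2) {
          anova[[key]] <- tryCatch(
            two_way_anova(two, n_baseline = config$n_baseline, n_bins = 10),
            error = function(e) NULL)
        }
      }
    }
  }

  provenance <- list(seed = config$seed, config_hash = config_hash(config),
                     n_subjects = length(subjects), n_used = length(used),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  result <- list(qc = qc, maps = maps, transforms = transforms,
                 composites = composites, counts = counts, tables = tables,
                 timecourses = timecourses, anova = anova, atlas = atlas,
                 subjects_used = used, provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(result, config, out_dir)
  result
}

# stable hash of the configuration (md5 of its serialized JSON)
config_hash <- function(config) {
  cfg <- config
  cfg$effects <- if (!is.null(cfg$effects)) as.data.frame(cfg$effects) else NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- result$provenance
  hdr <- sprintf("# config_hash=%s seed=%d", stamp$config_hash, stamp$seed)
  write_tsv <- function(df, name) {
    path <- file.path(out_dir, name)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", row.names = FALSE,
                                        quote = FALSE, append = TRUE))
  }
  write_tsv(result$qc, "motion_qc.tsv")
  write_tsv(result$counts, "regional_counts.tsv")
  for (sgn in names(result$tables)) {
    tab <- result$tables[[sgn]]
    tab$cutoff <- attr(tab, "cutoff")
    write_tsv(tab, sprintf("regional_table_%s.tsv", sgn))
  }
  for (g in names(result$composites)) {
    comp <- result$composites[[g]]
    for (sgn in c("positive", "negative")) {
      v <- comp[[sgn]]
      v[is.na(v)] <- 0
      write_volume(v, file.path(out_dir, sprintf("composite_%s_%s.nii", g, sgn)),
                   voxel_size = config$voxel_size)
    }
  }
  jsonlite::write_json(stamp, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Published regional volume-of-activation tables
#'
#' Loads the packaged transcription of the published ranked regional
#' median volume-of-activation tables (one per BOLD sign) from the
#' awake-mouse esketamine study: per region, the median activated voxel
#' count under vehicle and the 1.0, 3.3 and 10 mg/kg doses, the printed
#' omnibus p-value and effect size.
#'
#' @param sign "positive" (54 rows) or "negative" (52 rows).
#' @return data.frame with columns `name`, `veh`, `mg1`, `mg3.3`,
#'   `mg10`, `p`, `omega_sq`.
#' @export
published_voa <- function(sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  path <- system.file("extdata", sprintf("esketamine_%s_voa.tsv", sign),
                      package = "phbold", mustWork = TRUE)
  utils::read.delim(path, check.names = FALSE)
}
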