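#' Affine registration of a subject volume to a template
#'
#' Estimates the 9-parameter transform (translation, rotation, per-axis
#' scaling) mapping a subject anatomical volume onto a template by
#' maximizing normalized cross-correlation. Both volumes are pre-smoothed
#' with a small Gaussian, the template is sampled on a grid with the
#' stated point separation, and a coarse-to-fine pair of derivative-free
#' (Nelder-Mead) refinements is run from the identity (or a supplied
#' initialization). The `quality` setting thins the sample-point set:
#' a fraction 1 - quality of candidate points is dropped in a regular
#' pattern, trading speed against precision.
#'
#' @param subject 3D subject array (mm `voxel_size` attribute or same
#'   grid as template).
#' @param template 3D template array in atlas space.
#' @param voxel_size mm voxel size shared by the two grids (defaults to
#'   the template's attribute).
#' @param quality sampling quality in (0, 1]; default 0.97.
#' @param smoothing_mm FWHM of the registration pre-smoothing, mm.
#' @param separation_mm spacing of template sample points, mm.
#' @param init optional `phbold_affine` initialization.
#' @param search_mm half-width of the coarse translation search run
#'   before local refinement (skipped when `init` is given), mm.
#' @param maxit Nelder-Mead iteration cap per stage.
#' @return a `phbold_affine` (subject -> atlas, mm) with an extra
#'   `objective` element: list(ncc, evaluations).
#' @export
register_affine <- function(subject, template,
                            voxel_size = attr(template, "voxel_size"),
                            quality = 0.97, smoothing_mm = 0.35,
                            separation_mm = 0.50, init = NULL,
                            search_mm = 3, maxit = 2000L) {
  stopifnot(quality > 0, quality <= 1, separation_mm > 0)
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  d_t <- dim(template)
  center <- grid_center_mm(d_t, voxel_size)

  p0 <- if (is.null(init)) rep(0, 9) else with(init$parameters, c(translation, rotation, log(scale)))
  evals <- 0L

  stage <- function(p_start, sep_mm, maxit_stage, smooth_mm = smoothing_mm,
                    translation_search = FALSE) {
    sub_s <- smooth_gaussian(subject, smooth_mm, voxel_size)
    tpl_s <- smooth_gaussian(template, smooth_mm, voxel_size)
    stride <- pmax(1L, round(sep_mm / voxel_size))
    pts_idx <- as.matrix(expand.grid(
      x = seq(1, d_t[1], by = stride[1]),
      y = seq(1, d_t[2], by = stride[2]),
      z = seq(1, d_t[3], by = stride[3])))
    tpl_vals <- tpl_s[pts_idx]
    keep <- tpl_vals > stats::quantile(tpl_vals, 0.25)  # favour brain over background
    if (quality < 1) {
      # drop every k-th candidate so a fraction ~quality remains
      k <- max(2L, round(1 / (1 - quality)))
      keep[seq(1, length(keep), by = k)] <- FALSE
    }
    pts_idx <- pts_idx[keep, , drop = FALSE]
    tpl_vals <- tpl_s[pts_idx]
    pts_mm <- sweep(pts_idx - 1, 2, voxel_size, "*")
    obj <- function(p) {
      evals <<- evals + 1L
      tr <- affine_transform(p[1:3], p[4:6], exp(p[7:9]), center = center)
      sub_mm <- affine_apply(tr$inverse, pts_mm)
      vals <- trilinear_sample(sub_s, sweep(sub_mm, 2, voxel_size, "/"))
      ok <- is.finite(vals)
      if (sum(ok) < 20) return(2)  # essentially no overlap
      1 - suppressWarnings(stats::cor(vals[ok], tpl_vals[ok]))
    }
    if (!is.finite(obj(p_start)) || obj(p_start) >= 2) {
      stop("registration failed: subject and template do not overlap at initialization")
    }
    if (translation_search) {
      # coarse exhaustive search over translations to escape the
      # identity basin before the local refinements
      steps <- lapply(1:3, function(ax) {
        span <- min(search_mm, 0.25 * d_t[ax] * voxel_size[ax])
        seq(-span, span, by = max(voxel_size[ax], span / 4))
      })
      grid <- as.matrix(expand.grid(steps[[1]], steps[[2]], steps[[3]]))
      costs <- apply(grid, 1, function(tr) obj(c(tr, p_start[4:9])))
      return(c(grid[which.min(costs), ], p_start[4:9]))
    }
    # translations are O(mm); rotations and log-scales O(1e-2)
    parscale <- c(rep(0.5, 3), rep(0.01, 3), rep(0.01, 3))
    fit <- stats::optim(p_start, obj, method = "Nelder-Mead",
                        control = list(maxit = maxit_stage, reltol = 1e-12,
                                       parscale = parscale))
    fit <- stats::optim(fit$par, obj, method = "BFGS",
                        control = list(maxit = 60, reltol = 1e-12,
                                       parscale = parscale, ndeps = rep(1e-5, 9)))
    fit$par
  }

  if (is.null(init)) {
    p0 <- stage(p0, sep_mm = 3 * separation_mm, maxit_stage = 0,
                smooth_mm = max(2 * smoothing_mm, 1.0), translation_search = TRUE)
  }
  p <- stage(p0, sep_mm = 2 * separation_mm, maxit_stage = maxit,
             smooth_mm = max(2 * smoothing_mm, 0.7))
  p <- stage(p, sep_mm = separation_mm, maxit_stage = maxit)
  p <- stage(p, sep_mm = separation_mm, maxit_stage = maxit)

  out <- affine_transform(p[1:3], p[4:6], exp(p[7:9]), center = center)
  # final objective at the solution
  tr_ncc <- {
    sub_s <- smooth_gaussian(subject, smoothing_mm, voxel_size)
    tpl_s <- smooth_gaussian(template, smoothing_mm, voxel_size)
    pts_mm <- grid_mm(d_t, voxel_size)
    sub_mm <- affine_apply(out$inverse, pts_mm)
    vals <- trilinear_sample(sub_s, sweep(sub_mm, 2, voxel_size, "/"))
    ok <- is.finite(vals)
    suppressWarnings(stats::cor(vals[ok], as.numeric(tpl_s)[ok]))
  }
  out$objective <- list(ncc = tr_ncc, evaluations = evals)
  out
}
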