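#' Build a synthetic labeled brain atlas
#'
#' Creates a 3D integer label volume emulating a segmented mouse-brain
#' atlas: an ellipsoidal brain mask partitioned into `n_regions`
#' connected parcels by seeded Voronoi growth in voxel-index space. At
#' the full acquisition grid (96 x 96 x 18) the mask holds roughly
#' 15,000 voxels, the per-subject in-brain voxel count of awake-mouse
#' BOLD studies at 187.5 um in-plane resolution.
#'
#' @param n_regions number of parcels (134 at full atlas scale).
#' @param shape integer length 3, grid dimensions.
#' @param voxel_size numeric length 3, mm per voxel edge. Default matches
#'   187.5 um in-plane resolution with 0.75 mm slices.
#' @param seed integer seed; the parcellation is deterministic in it.
#' @return A `phbold_atlas`: list with `labels` (3D integer array,
#'   0 = background), `names` (named character vector, region id ->
#'   name) and `voxel_size`.
#' @export
make_atlas <- function(n_regions,
                       shape = c(96, 96, 18),
                       voxel_size = c(0.1875, 0.1875, 0.75),
                       seed = 1L) {
  stopifnot(n_regions >= 1, length(shape) == 3, all(shape >= 2))
  mask <- ellipsoid_mask(shape)
  n_mask <- sum(mask)
  if (n_regions > n_mask) {
    stop(sprintf("atlas capacity exceeded: %d regions requested but the brain mask holds only %d voxels",
                 n_regions, n_mask))
  }
  rng <- local_rng(seed)
  idx <- which(mask)
  coords <- arrayInd(idx, shape)
  seeds <- coords[rng$sample_int(n_mask, n_regions), , drop = FALSE]
  # nearest-seed assignment (squared Euclidean in index space); ties to
  # the lowest region id, which keeps parcels convex-intersect-ellipsoid
  # and therefore connected
  best_d <- rep(Inf, n_mask)
  lab <- integer(n_mask)
  for (r in seq_len(n_regions)) {
    d <- (coords[, 1] - seeds[r, 1])^2 +
         (coords[, 2] - seeds[r, 2])^2 +
         (coords[, 3] - seeds[r, 3])^2
    better <- d < best_d
    lab[better] <- r
    best_d[better] <- d[better]
  }
  labels <- array(0L, dim = shape)
  labels[idx] <- lab
  names <- sprintf("region_%03d", seq_len(n_regions))
  names(names) <- as.character(seq_len(n_regions))
  structure(list(labels = labels, names = names,
                 voxel_size = as.numeric(voxel_size)),
            class = "phbold_atlas")
}

# Ellipsoid with semi-axes a fixed fraction of the half-dimensions,
# chosen so the full 96x96x18 grid yields ~15,000 in-mask voxels.
ellipsoid_mask <- function(shape, fractions = c(0.48, 0.58, 0.62)) {
  half <- (shape - 1) / 2
  ax <- pmax(fractions * shape / 2, 1)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]), z = seq_len(shape[3]))
  d <- ((g$x - 1 - half[1]) / ax[1])^2 +
       ((g$y - 1 - half[2]) / ax[2])^2 +
       ((g$z - 1 - half[3]) / ax[3])^2
  array(d <= 1, dim = shape)
}

#' @export
print.phbold_atlas <- function(x, ...) {
  cat(sprintf("Labeled atlas: %d regions, grid %s, %d brain voxels\n",
              length(x$names), paste(dim(x$labels), collapse = "x"),
              sum(x$labels > 0)))
  invisible(x)
}

#' Sizes of atlas regions
#'
#' @param atlas a `phbold_atlas`.
#' @return named integer vector of voxel counts per region id.
#' @export
region_sizes <- function(atlas) {
  tab <- tabulate(atlas$labels[atlas$labels > 0], nbins = length(atlas$names))
  names(tab) <- names(atlas$names)
  tab
}

#' Template intensity volume for an atlas
#'
#' Builds the smooth anatomical "phantom" used both as the registration
#' template and as the source of every synthetic subject's anatomy:
#' per-region mean intensities plus a smoothed within-region texture, on
#' a dim background. Contrast between regions is what makes affine
#' registration well posed.
#'
#' @param atlas a `phbold_atlas`.
#' @param seed integer seed for region means and texture.
#' @param background background (out-of-brain) intensity.
#' @param texture_sd SD of the smoothed texture component, intensity units.
#' @return 3D numeric array with a `voxel_size` attribute.
#' @export
make_template <- function(atlas, seed = 0L, background = 100, texture_sd = 40) {
  rng <- local_rng(seed)
  n <- length(atlas$names)
  means <- 700 + 500 * rng$runif(n)
  vol <- array(background, dim = dim(atlas$labels))
  inb <- atlas$labels > 0
  vol[inb] <- means[atlas$labels[inb]]
  if (texture_sd > 0) {
    tex <- array(rng$rnorm(length(vol), 0, texture_sd), dim = dim(vol))
    # texture correlation length set in voxels (isotropic in index
    # space) so through-plane contrast is as smooth as in-plane
    tex <- smooth_gaussian(tex, fwhm_mm = 2.5, voxel_size = c(1, 1, 1))
    vol <- vol + tex
  }
  # soften region boundaries so intensity gradients are resolvable at
  # sub-voxel registration accuracy
  vol <- smooth_gaussian(vol, fwhm_mm = 1.5, voxel_size = c(1, 1, 1))
  vol[vol <= 1] <- 1
  attr(vol, "voxel_size") <- atlas$voxel_size
  vol
}
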