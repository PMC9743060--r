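#' Trilinear interpolation at continuous voxel coordinates
#'
#' Samples a 3D volume at arbitrary continuous positions using the
#' weighted average of the eight surrounding voxels. Coordinates are
#' 0-based voxel indices (voxel centres at integers), the convention
#' used throughout for mapping between mm and grid positions.
#'
#' @param volume 3D numeric array.
#' @param points n x 3 matrix of continuous 0-based voxel coordinates
#'   (a length-3 vector is one point).
#' @param method "trilinear" or "nearest" (nearest-neighbour, used for
#'   label volumes and for count-preserving map transfer).
#' @return numeric vector of length n; `NA` for points outside the grid
#'   (out-of-bounds samples are excluded from composite averaging, not
#'   zero-filled).
#' @export
trilinear_sample <- function(volume, points, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  d <- dim(volume)
  x <- points[, 1]; y <- points[, 2]; z <- points[, 3]
  inb <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  out <- rep(NA_real_, nrow(points))
  if (!any(inb)) return(out)
  x <- x[inb]; y <- y[inb]; z <- z[inb]
  if (method == "nearest") {
    i <- pmin(pmax(round(x), 0), d[1] - 1) + 1
    j <- pmin(pmax(round(y), 0), d[2] - 1) + 1
    k <- pmin(pmax(round(z), 0), d[3] - 1) + 1
    out[inb] <- volume[cbind(i, j, k)]
    return(out)
  }
  x0 <- pmin(floor(x), d[1] - 2); x0[d[1] == 1] <- 0
  y0 <- pmin(floor(y), d[2] - 2); y0[d[2] == 1] <- 0
  z0 <- pmin(floor(z), d[3] - 2); z0[d[3] == 1] <- 0
  x0 <- pmax(x0, 0); y0 <- pmax(y0, 0); z0 <- pmax(z0, 0)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1); z1 <- pmin(z0 + 1, d[3] - 1)
  v <- function(i, j, k) volume[cbind(i + 1, j + 1, k + 1)]
  val <-
    v(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz) +
    v(x1, y0, z0) * fx       * (1 - fy) * (1 - fz) +
    v(x0, y1, z0) * (1 - fx) * fy       * (1 - fz) +
    v(x1, y1, z0) * fx       * fy       * (1 - fz) +
    v(x0, y0, z1) * (1 - fx) * (1 - fy) * fz +
    v(x1, y0, z1) * fx       * (1 - fy) * fz +
    v(x0, y1, z1) * (1 - fx) * fy       * fz +
    v(x1, y1, z1) * fx       * fy       * fz
  out[inb] <- val
  out
}

#' Resample a volume through an mm-space mapping
#'
#' For every voxel of the output grid, maps its mm coordinate through
#' `mm_map` and samples the source volume there. This is the primitive
#' behind both synthetic-subject generation (atlas template -> subject
#' grid through the subject transform) and composite building (subject
#' maps -> atlas grid through the inverse transform).
#'
#' @param src 3D source array.
#' @param mm_map 4x4 matrix mapping output mm coordinates to source mm
#'   coordinates.
#' @param out_dim integer length 3, output grid.
#' @param out_voxel_size,src_voxel_size mm voxel sizes of the two grids.
#' @param method interpolation method, see [trilinear_sample()].
#' @param fill value for out-of-bounds samples (`NA` keeps them missing).
#' @return 3D array of dim `out_dim` with `voxel_size` attribute.
#' @export
resample_volume <- function(src, mm_map, out_dim, out_voxel_size,
                            src_voxel_size = attr(src, "voxel_size"),
                            method = "trilinear", fill = NA_real_) {
  if (is.null(src_voxel_size)) src_voxel_size <- c(1, 1, 1)
  pts <- grid_mm(out_dim, out_voxel_size)
  src_mm <- affine_apply(mm_map, pts)
  src_vox <- sweep(src_mm, 2, src_voxel_size, "/")
  vals <- trilinear_sample(src, src_vox, method = method)
  if (!is.na(fill)) vals[is.na(vals)] <- fill
  out <- array(vals, dim = out_dim)
  attr(out, "voxel_size") <- as.numeric(out_voxel_size)
  out
}

# mm coordinates of all voxel centres of a grid (0-based index * voxel size)
grid_mm <- function(dim, voxel_size) {
  g <- expand.grid(x = seq_len(dim[1]) - 1,
                   y = seq_len(dim[2]) - 1,
                   z = seq_len(dim[3]) - 1)
  cbind(g$x * voxel_size[1], g$y * voxel_size[2], g$z * voxel_size[3])
}

#' Physical centre of a voxel grid
#'
#' The mm coordinate of the grid centre, used throughout as the
#' rotation/scaling centre of subject transforms.
#'
#' @param dim integer length 3 grid dimensions.
#' @param voxel_size mm voxel edge lengths.
#' @return numeric length 3, mm.
#' @export
grid_center_mm <- function(dim, voxel_size) {
  (dim - 1) / 2 * voxel_size
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Smooths with a Gaussian kernel specified by its full width at half
#' maximum in mm, converted per axis to voxel units via the voxel size
#' (sigma = FWHM / (2 sqrt(2 ln 2))). The kernel is normalized, so image
#' sum is conserved away from the boundary; boundaries are zero-padded.
#'
#' @param volume 3D numeric array.
#' @param fwhm_mm full width at half maximum, mm (0 returns the input).
#' @param voxel_size mm voxel edge lengths (defaults to the volume's
#'   `voxel_size` attribute, else 1).
#' @return smoothed array of the same dimensions.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size = attr(volume, "voxel_size")) {
  stopifnot(fwhm_mm >= 0)
  if (fwhm_mm == 0) return(volume)
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size
  out <- volume
  d <- dim(volume)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-3) next
    r <- max(1L, ceiling(3.5 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    acc <- array(0, dim = d)
    for (o in seq(-r, r)) {
      w <- k[o + r + 1]
      n <- d[ax]
      src_idx <- seq_len(n) + o
      keep <- src_idx >= 1 & src_idx <= n
      if (!any(keep)) next
      dst <- which(keep)
      src <- src_idx[keep]
      if (ax == 1) acc[dst, , ] <- acc[dst, , ] + w * out[src, , ]
      else if (ax == 2) acc[, dst, ] <- acc[, dst, ] + w * out[, src, ]
      else acc[, , dst] <- acc[, , dst] + w * out[, , src]
    }
    out <- acc
  }
  attributes(out) <- attributes(volume)
  out
}
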