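#' Affine transforms between subject and atlas space
#'
#' Transforms are 4x4 homogeneous matrices acting on physical (mm)
#' coordinates, mapping subject space to atlas space. Only the nine
#' parameters used for atlas registration are supported: per-axis
#' translation (mm), rotation (rad, applied as Rz Ry Rx) and per-axis
#' scaling. Rotation and scaling are applied about a stated centre so
#' that parameters remain interpretable for volumes whose origin is a
#' corner voxel.
#'
#' @param translation numeric length 3, mm.
#' @param rotation numeric length 3, radians about x, y, z.
#' @param scale numeric length 3, unitless; must be nonzero.
#' @param center numeric length 3, mm point about which rotation and
#'   scaling act (typically the volume centre).
#' @return An object of class `phbold_affine` with elements `matrix`,
#'   `inverse` (both 4x4), `parameters` (named list) and `center`.
#' @export
affine_transform <- function(translation = c(0, 0, 0),
                             rotation = c(0, 0, 0),
                             scale = c(1, 1, 1),
                             center = c(0, 0, 0)) {
  stopifnot(length(translation) == 3, length(rotation) == 3,
            length(scale) == 3, length(center) == 3)
  if (any(abs(scale) < 1e-8)) {
    stop("degenerate transform: scale factors must be nonzero")
  }
  rx <- rotation[1]; ry <- rotation[2]; rz <- rotation[3]
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(rx), -sin(rx)),
              c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)),
              c(0, 1, 0),
              c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0),
              c(sin(rz), cos(rz), 0),
              c(0, 0, 1))
  A <- (Rz %*% Ry %*% Rx) %*% diag(scale)
  m <- diag(4)
  m[1:3, 1:3] <- A
  # x' = A (x - c) + c + t
  m[1:3, 4] <- center - A %*% center + translation
  obj <- list(
    matrix = m,
    inverse = solve(m),
    parameters = list(translation = as.numeric(translation),
                      rotation = as.numeric(rotation),
                      scale = as.numeric(scale)),
    center = as.numeric(center)
  )
  class(obj) <- "phbold_affine"
  obj
}

#' @export
print.phbold_affine <- function(x, ...) {
  p <- x$parameters
  cat("Affine transform (subject -> atlas, mm)\n")
  cat(sprintf("  translation: %s mm\n", paste(signif(p$translation, 4), collapse = ", ")))
  cat(sprintf("  rotation:    %s rad\n", paste(signif(p$rotation, 4), collapse = ", ")))
  cat(sprintf("  scale:       %s\n", paste(signif(p$scale, 4), collapse = ", ")))
  invisible(x)
}

#' Apply an affine transform to points
#'
#' @param transform a `phbold_affine` or a 4x4 matrix.
#' @param points numeric matrix, n x 3, mm coordinates (a length-3 vector
#'   is treated as a single point).
#' @param inverse apply the inverse mapping instead.
#' @return n x 3 matrix of mapped mm coordinates.
#' @export
affine_apply <- function(transform, points, inverse = FALSE) {
  m <- if (inherits(transform, "phbold_affine")) {
    if (inverse) transform$inverse else transform$matrix
  } else {
    if (inverse) solve(transform) else transform
  }
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3)
  out <- cbind(points, 1) %*% t(m)
  out[, 1:3, drop = FALSE]
}

#' Invert an affine transform
#'
#' @param transform a `phbold_affine`.
#' @return a `phbold_affine` representing the inverse mapping. Parameter
#'   fields are inverted elementwise only for pure-translation/scale
#'   transforms; the matrix and its inverse are always exact.
#' @export
affine_invert <- function(transform) {
  stopifnot(inherits(transform, "phbold_affine"))
  obj <- list(
    matrix = transform$inverse,
    inverse = transform$matrix,
    parameters = list(translation = -transform$parameters$translation,
                      rotation = -transform$parameters$rotation,
                      scale = 1 / transform$parameters$scale),
    center = transform$center
  )
  class(obj) <- "phbold_affine"
  obj
}

#' Draw a random subject-to-atlas transform
#'
#' Generates a small random rigid-plus-scaling transform of the kind used
#' to emulate between-subject positioning differences. Jitters are the
#' half-widths of uniform distributions; ground-truth parameters are kept
#' on the object so registration recovery can be scored.
#'
#' @param scale_jitter max deviation of each scale factor from 1.
#' @param rotation_jitter max rotation per axis, radians.
#' @param translation_jitter max translation per axis, mm.
#' @param seed integer seed; draws are reproducible.
#' @param center rotation/scaling centre, mm.
#' @return a `phbold_affine`.
#' @export
make_subject_transform <- function(scale_jitter = 0.03,
                                   rotation_jitter = 0.05,
                                   translation_jitter = 0.4,
                                   seed = 1L,
                                   center = c(0, 0, 0)) {
  stopifnot(scale_jitter >= 0, rotation_jitter >= 0, translation_jitter >= 0)
  if (scale_jitter >= 1) stop("degenerate transform: scale_jitter must be < 1")
  rng <- local_rng(seed)
  translation <- rng$runif(3, -translation_jitter, translation_jitter)
  rotation <- rng$runif(3, -rotation_jitter, rotation_jitter)
  scale <- 1 + rng$runif(3, -scale_jitter, scale_jitter)
  affine_transform(translation, rotation, scale, center = center)
}

# Seeded RNG helper that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      })
      f(...)
    }
  }
  list(
    runif = with_state(stats::runif),
    rnorm = with_state(stats::rnorm),
    sample_int = with_state(function(n, size, replace = FALSE) sample.int(n, size, replace = replace))
  )
}
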