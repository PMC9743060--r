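#' Map a subject-space volume into atlas space
#'
#' Samples the subject volume at every atlas voxel through the inverse
#' transform Tj^-1, so the full atlas grid is populated wherever the
#' mapped point falls inside the subject field of view. Use
#' `method = "nearest"` for label volumes or when voxel counts must be
#' preserved exactly.
#'
#' @param volume 3D subject-space array.
#' @param transform the subject's `phbold_affine` (subject -> atlas).
#' @param atlas a `phbold_atlas` defining the output grid.
#' @param method interpolation method, see [trilinear_sample()].
#' @return 3D array on the atlas grid; `NA` where the inverse-mapped
#'   point leaves the subject volume.
#' @export
map_to_atlas <- function(volume, transform, atlas, method = "trilinear") {
  resample_volume(volume, transform$inverse, dim(atlas$labels),
                  atlas$voxel_size,
                  src_voxel_size = atlas$voxel_size, method = method)
}

#' Build a group composite percent-change map
#'
#' For each atlas voxel, maps its location into every subject via the
#' inverse transform, trilinearly samples that subject's retained
#' percent-change map, and assigns the average of the contributions.
#' Positive and negative components are composited separately and never
#' mixed. By default the average runs over all contributing subjects,
#' counting non-retained (zero) voxels as zeros; set
#' `nonzero_only = TRUE` to average over nonzero contributors instead.
#' Out-of-bounds samples are missing, not zero, and are excluded from
#' the average.
#'
#' @param maps list of `phbold_actmap`, one per subject.
#' @param transforms list of `phbold_affine`, parallel to `maps` (a
#'   missing or NULL entry is an error naming the subject).
#' @param atlas a `phbold_atlas`.
#' @param group group label stored on the result.
#' @param nonzero_only average over nonzero contributions only.
#' @return A `phbold_composite`: list with `group`, `positive`,
#'   `negative` (3D atlas-grid arrays, NA where no subject contributes)
#'   and `n_contrib` (3D count of contributing subjects).
#' @export
build_composite <- function(maps, transforms, atlas, group = "group",
                            nonzero_only = FALSE) {
  stopifnot(length(maps) == length(transforms))
  ids <- names(maps)
  if (is.null(ids)) ids <- as.character(seq_along(maps))
  d <- dim(atlas$labels)
  acc <- list(positive = array(0, d), negative = array(0, d))
  cnt <- list(positive = array(0L, d), negative = array(0L, d))
  n_any <- array(0L, d)
  for (i in seq_along(maps)) {
    tr <- transforms[[i]]
    if (is.null(tr)) stop("missing transform for subject ", ids[i])
    contributed <- NULL
    for (sign in c("positive", "negative")) {
      w <- map_to_atlas(maps[[i]][[sign]], tr, atlas, method = "trilinear")
      ok <- !is.na(w)
      use <- if (nonzero_only) ok & w != 0 else ok
      acc[[sign]][use] <- acc[[sign]][use] + w[use]
      cnt[[sign]][use] <- cnt[[sign]][use] + 1L
      if (is.null(contributed)) contributed <- ok
    }
    n_any <- n_any + contributed
  }
  out <- lapply(c(positive = "positive", negative = "negative"), function(sign) {
    v <- acc[[sign]] / cnt[[sign]]
    v[cnt[[sign]] == 0] <- NA_real_
    v
  })
  structure(list(group = group, positive = out$positive,
                 negative = out$negative, n_contrib = n_any),
            class = "phbold_composite")
}

#' @export
print.phbold_composite <- function(x, ...) {
  cat(sprintf("Composite map, group %s: grid %s, max contributors %d\n",
              x$group, paste(dim(x$n_contrib), collapse = "x"),
              max(x$n_contrib)))
  invisible(x)
}
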