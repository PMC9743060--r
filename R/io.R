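#' Write a volume as NIfTI-1
#'
#' Stores 3D or 4D arrays with the voxel size in the pixdim header
#' fields (RAS+, origin at the first voxel).
#'
#' @param volume 3D/4D numeric array; `voxel_size` attribute used unless
#'   given explicitly.
#' @param path output file path (".nii").
#' @param voxel_size mm voxel edge lengths.
#' @export
write_volume <- function(volume, path, voxel_size = attr(volume, "voxel_size")) {
  if (is.null(voxel_size)) voxel_size <- c(1, 1, 1)
  img <- RNifti::asNifti(unclass(volume))
  RNifti::pixdim(img) <- rep_len(as.numeric(voxel_size), length(dim(volume)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume
#'
#' @param path file path.
#' @return numeric array with a `voxel_size` attribute (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size") <- as.numeric(vs)
  out
}

#' Write / read a labeled atlas
#'
#' The label volume goes to `<prefix>_labels.nii` and the region-name
#' lookup table to `<prefix>_names.tsv` (columns region_id, name).
#'
#' @param atlas a `phbold_atlas`.
#' @param prefix path prefix.
#' @export
write_atlas <- function(atlas, prefix) {
  write_volume(atlas$labels, paste0(prefix, "_labels.nii"),
               voxel_size = atlas$voxel_size)
  utils::write.table(
    data.frame(region_id = as.integer(names(atlas$names)), name = unname(atlas$names)),
    paste0(prefix, "_names.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(prefix) {
  vol <- read_volume(paste0(prefix, "_labels.nii"))
  tab <- utils::read.delim(paste0(prefix, "_names.tsv"))
  names <- tab$name
  names(names) <- as.character(tab$region_id)
  structure(list(labels = array(as.integer(round(vol)), dim = dim(vol)),
                 names = names, voxel_size = attr(vol, "voxel_size")),
            class = "phbold_atlas")
}

#' Serialize an affine transform as JSON
#'
#' Written as a 4x4 row-major matrix in mm units, plus the parameter
#' decomposition and centre when available.
#'
#' @param transform a `phbold_affine`.
#' @param path output file.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = apply(transform$matrix, 1, function(r) r, simplify = FALSE),
         parameters = transform$parameters,
         center = transform$center),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- do.call(rbind, lapply(seq_len(4), function(i) as.numeric(x$matrix[i, ])))
  if (is.matrix(x$matrix)) m <- x$matrix
  p <- x$parameters
  affine_transform(p$translation, p$rotation, p$scale, center = x$center)
}

#' Load a cohort written by [make_cohort()]
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return list with `atlas`, `template`, `manifest`, and a `subjects`
#'   list of `phbold_bold` objects (with motion traces attached as
#'   `$motion` and ground-truth masks in `$truth`).
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  atlas <- read_atlas(file.path(dir, "atlas"))
  template <- read_volume(file.path(dir, "template.nii"))
  subs <- lapply(seq_len(nrow(manifest$subjects)), function(i) {
    s <- manifest$subjects[i, ]
    func <- read_volume(file.path(dir, s$func))
    anat <- read_volume(file.path(dir, s$anat))
    tr <- read_transform(file.path(dir, s$transform))
    labels <- resample_volume(atlas$labels, tr$matrix, dim(anat),
                              attr(anat, "voxel_size"),
                              src_voxel_size = atlas$voxel_size,
                              method = "nearest", fill = 0)
    structure(list(
      data = func, n_baseline = manifest$n_baseline, n_stim = manifest$n_stim,
      voxel_size = attr(func, "voxel_size"),
      subject_id = s$subject_id, group = s$group,
      anat = anat, labels = array(as.integer(labels), dim = dim(anat)),
      truth = list(
        positive = read_volume(file.path(dir, s$truth_pos)) > 0.5,
        negative = read_volume(file.path(dir, s$truth_neg)) > 0.5),
      transform = tr,
      motion = utils::read.delim(file.path(dir, s$motion))
    ), class = "phbold_bold")
  })
  names(subs) <- manifest$subjects$subject_id
  list(atlas = atlas, template = template, manifest = manifest, subjects = subs)
}
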