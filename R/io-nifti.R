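#' Read and write volumes as NIfTI
#'
#' HU voxels round-trip losslessly; spacing and origin are carried in the
#' NIfTI sform (a diagonal affine: world = origin + index * spacing, with
#' world axes x = left-right, y = anterior-posterior, z = cranio-caudal).
#'
#' @param vol a [voxel_volume()].
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_volume` returns
#'   a [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  vol <- as_voxel_volume(vol)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("unsupported volume format '%s' (use .nii or .nii.gz)", path)
  img <- RNifti::asNifti(vol$voxels)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path))
    stopf("unsupported volume format '%s' (use .nii or .nii.gz)", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stopf("expected a 3-D volume in '%s'", path)
  aff <- RNifti::xform(img)
  voxel_volume(arr, spacing = diag(aff)[1:3], origin = aff[1:3, 4])
}

#' Write a label volume with its label map
#'
#' @param labels the `labels` element of a [rasterize()] result.
#' @param spacing,origin geometry of the label grid.
#' @param path NIfTI output path; the label map is written alongside as
#'   `<path>.labels.json`.
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(labels, spacing, path,
                               origin = NULL) {
  vol <- voxel_volume(labels$volume + 0, spacing, origin)
  write_volume(vol, path)
  jsonlite::write_json(labels$map, paste0(path, ".labels.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
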