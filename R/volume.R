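#' CT voxel volume
#'
#' A `voxel_volume` is the unit every analysis stage consumes: a 3-D array of
#' Hounsfield Units with its physical geometry.  Axis order is fixed:
#' x = left-right, y = anterior-posterior, z = cranio-caudal.  World
#' coordinates are millimetres at voxel centres; voxel `[1, 1, 1]` has world
#' position `origin`.
#'
#' @param voxels numeric 3-D array of HU values (finite).
#' @param spacing numeric length-3, voxel spacing in mm (x, y, z), all > 0.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.  Defaults to centring the grid on the world origin.
#' @return An object of class `voxel_volume` with fields `voxels`, `spacing`
#'   and `origin`.
#' @examples
#' v <- voxel_volume(array(0, c(4, 4, 2)), spacing = c(0.51, 0.51, 0.5))
#' dim(v$voxels)
#' @export
voxel_volume <- function(voxels, spacing, origin = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stopf("voxels must be a 3-D array")
  d <- dim(voxels)
  if (d[3] < 1L) stopf("volume must have at least one slice")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive finite values (mm)")
  if (!all(is.finite(voxels)))
    stopf("voxel values must be finite HU")
  if (is.null(origin)) origin <- -(d - 1) / 2 * spacing
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stopf("origin must be three finite values (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<voxel_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.1f, %.1f, %.1f) mm, HU range [%.0f, %.0f]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

as_voxel_volume <- function(x) {
  if (inherits(x, "voxel_volume")) return(x)
  stopf("expected a voxel_volume")
}

#' Region-of-interest mask
#'
#' A labelled set of voxel indices into a specific grid.  Masks of distinct
#' inserts are disjoint by construction when produced by
#' [segment_inserts()].
#'
#' @param label character ROI label.
#' @param indices integer vector of linear indices into the volume array.
#' @param dim integer length-3 grid dimensions the indices refer to.
#' @param erosion_margin erosion margin (mm) that was applied, if any.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(label, indices, dim, erosion_margin = 0) {
  indices <- as.integer(indices)
  if (length(indices) == 0L) stopf("mask '%s' is empty", label)
  if (any(indices < 1L) || any(indices > prod(dim)))
    stopf("mask '%s' has indices outside the volume", label)
  structure(list(label = as.character(label), indices = indices,
                 dim = as.integer(dim), erosion_margin = erosion_margin),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d voxels (erosion margin %.2g mm)\n",
              x$label, length(x$indices), x$erosion_margin))
  invisible(x)
}

mask_values <- function(vol, mask) {
  if (!identical(as.integer(dim(vol$voxels)), mask$dim))
    stopf("mask '%s' does not match the volume grid", mask$label)
  vol$voxels[mask$indices]
}

mask_to_array <- function(mask) {
  a <- array(FALSE, mask$dim)
  a[mask$indices] <- TRUE
  a
}
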