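## ---- geometry painting ------------------------------------------------
## All shapes are evaluated at voxel centres over their bounding box only;
## linear indices are then assigned into the full arrays.

## linear indices of voxels inside a z-aligned cylinder
cylinder_indices <- function(coords, dims, center, r, len) {
  xi <- which(abs(coords$x - center[1]) <= r)
  yi <- which(abs(coords$y - center[2]) <= r)
  zi <- which(abs(coords$z - center[3]) <= len / 2)
  if (!length(xi) || !length(yi) || !length(zi)) return(integer(0))
  d2 <- outer((coords$x[xi] - center[1])^2, (coords$y[yi] - center[2])^2, "+")
  in2 <- which(d2 <= r^2)
  if (!length(in2)) return(integer(0))
  off <- (xi[(in2 - 1) %% length(xi) + 1]) +
         (yi[(in2 - 1) %/% length(xi) + 1] - 1) * dims[1]
  as.integer(outer(off, (zi - 1) * dims[1] * dims[2], "+"))
}

## linear indices inside a (possibly tilted) cube
cube_indices <- function(coords, dims, center, half, tilt) {
  pad <- half * 1.8
  xi <- which(abs(coords$x - center[1]) <= pad)
  yi <- which(abs(coords$y - center[2]) <= pad)
  zi <- which(abs(coords$z - center[3]) <= pad)
  if (!length(xi) || !length(yi) || !length(zi)) return(integer(0))
  nx <- length(xi); ny <- length(yi); nz <- length(zi)
  X <- array(coords$x[xi] - center[1], c(nx, ny, nz))
  Y <- array(rep(coords$y[yi] - center[2], each = nx), c(nx, ny, nz))
  Z <- array(rep(coords$z[zi] - center[3], each = nx * ny), c(nx, ny, nz))
  cz <- cos(tilt[1]); sz <- sin(tilt[1]); cx <- cos(tilt[2]); sx <- sin(tilt[2])
  X1 <-  cz * X + sz * Y; Y1 <- -sz * X + cz * Y
  Y2 <-  cx * Y1 + sx * Z; Z2 <- -sx * Y1 + cx * Z
  sel <- which(abs(X1) <= half & abs(Y2) <= half & abs(Z2) <= half)
  if (!length(sel)) return(integer(0))
  ai <- arrayInd(sel, c(nx, ny, nz))
  as.integer(xi[ai[, 1]] + (yi[ai[, 2]] - 1) * dims[1] +
             (zi[ai[, 3]] - 1) * dims[1] * dims[2])
}

## elliptic cylinder spanning the full z extent
ellipse_indices <- function(coords, dims, center, semi) {
  xi <- which(abs(coords$x - center[1]) <= semi[1])
  yi <- which(abs(coords$y - center[2]) <= semi[2])
  if (!length(xi) || !length(yi)) return(integer(0))
  q <- outer(((coords$x[xi] - center[1]) / semi[1])^2,
             ((coords$y[yi] - center[2]) / semi[2])^2, "+")
  in2 <- which(q <= 1)
  if (!length(in2)) return(integer(0))
  off <- (xi[(in2 - 1) %% length(xi) + 1]) +
         (yi[(in2 - 1) %/% length(xi) + 1] - 1) * dims[1]
  as.integer(outer(off, (seq_len(dims[3]) - 1) * dims[1] * dims[2], "+"))
}

shape_indices <- function(s, coords, dims) {
  if (s$shape == "cube")
    cube_indices(coords, dims, s$center, s$radius_or_halfedge, s$tilt)
  else
    cylinder_indices(coords, dims, s$center, s$radius_or_halfedge, s$length)
}

## seeded, smoothed, exactly zero-mean unit-SD texture over given indices
texture_field <- function(indices, dims, spacing, seed) {
  ai <- arrayInd(indices, dims)
  rng <- apply(ai, 2, range)
  sub <- rng[2, ] - rng[1, ] + 1L
  field <- with_seed(seed, array(rnorm(prod(sub)), sub))
  field <- separable_gaussian_blur(field, spacing, rep(1, 3))  # 1 mm kernel
  v <- field[cbind(ai[, 1] - rng[1, 1] + 1L, ai[, 2] - rng[1, 2] + 1L,
                   ai[, 3] - rng[1, 3] + 1L)]
  (v - mean(v)) / sd(v)
}

#' Rasterize a phantom layout into ground-truth volumes
#'
#' Produces the noiseless HU volume in which every voxel takes its
#' material's nominal CT number (textured materials additionally receive a
#' seeded, smoothed heterogeneity field scaled to the material's
#' `texture_sd`), together with an integer label volume identifying each
#' labelled insert, the lung foam, the body and background air.  The label
#' volume is the segmentation ground truth used throughout the test-bench.
#'
#' @param layout a [build_layout()] result.
#' @param spacing voxel spacing in mm (x, y, z); the physical acquisitions
#'   this emulates reconstruct at 0.51 x 0.51 mm in-plane with 0.5 mm slice
#'   spacing, but any desk-scale geometry is accepted.
#' @param grid_shape integer length-3 grid dimensions.
#' @param origin optional world position (mm) of the first voxel centre;
#'   defaults to centring the grid on the phantom.
#' @param texture_seed seed for the heterogeneity fields of textured
#'   materials; rasterization is fully deterministic given this seed and
#'   seed-independent for untextured materials.
#' @param require_all error when a labelled insert does not fit inside the
#'   grid; set to `FALSE` to rasterize a sub-region of the phantom (e.g. a
#'   fine grid around a single tube).
#' @return A list with `volume` (a [voxel_volume()]) and `labels`, itself a
#'   list of `volume` (integer array) and `map` (data.frame of id, label).
#' @export
rasterize <- function(layout, spacing, grid_shape, origin = NULL,
                      texture_seed = 42L, require_all = TRUE) {
  spacing <- as.numeric(spacing); grid_shape <- as.integer(grid_shape)
  if (any(spacing <= 0)) stopf("spacing must be positive")
  if (is.null(origin)) origin <- -(grid_shape - 1) / 2 * spacing
  dims <- grid_shape
  coords <- grid_coords(dims, spacing, origin)
  world_lo <- origin; world_hi <- origin + (dims - 1) * spacing

  ins <- layout$inserts
  payload <- ins[vapply(ins, `[[`, "", "role") == "insert"]
  if (require_all) for (s in payload) {
    half <- if (s$shape == "cube") rep(s$radius_or_halfedge, 3) else
      c(s$radius_or_halfedge, s$radius_or_halfedge, s$length / 2)
    if (any(s$center - half < world_lo - spacing / 2) ||
        any(s$center + half > world_hi + spacing / 2))
      stopf("grid too small: insert '%s' does not fit inside the volume",
            s$label)
  }

  vol <- array(-1000, dims)     # background air
  lab <- array(0L, dims)
  geom <- layout$geometry

  body <- ellipse_indices(coords, dims, c(0, 0), geom$body_semi)
  vol[body] <- layout$body_hu; lab[body] <- 1L
  for (side in c("right", "left")) {
    li <- ellipse_indices(coords, dims, geom$lung_center[[side]], geom$lung_semi)
    vol[li] <- layout$lung_foam_hu; lab[li] <- 2L
  }
  tubes <- c(list(geom$large_tube), unname(geom$small_tubes))
  for (tb in tubes) {
    wall <- setdiff(
      cylinder_indices(coords, dims, c(tb$center, 0), tb$outer_r, 1e9),
      cylinder_indices(coords, dims, c(tb$center, 0), tb$inner_r, 1e9))
    vol[wall] <- layout$tube_wall_hu; lab[wall] <- 3L
    bore <- cylinder_indices(coords, dims, c(tb$center, 0), tb$inner_r, 1e9)
    vol[bore] <- -1000; lab[bore] <- 0L
  }

  map <- data.frame(id = c(1L, 2L, 3L), label = c("body", "lung_foam", "tube_wall"),
                    stringsAsFactors = FALSE)
  next_id <- 10L
  for (s in ins) {        # carriers first by construction order
    idx <- shape_indices(s, coords, dims)
    if (s$role != "insert") {
      vol[idx] <- s$material$nominal_hu
      next
    }
    if (!length(idx)) {
      if (require_all)
        stopf("grid too small: insert '%s' rasterized empty", s$label)
      next
    }
    vol[idx] <- s$material$nominal_hu
    if (s$material$texture_sd > 0) {
      tx <- texture_field(idx, dims, spacing,
                          texture_seed + next_id)
      vol[idx] <- vol[idx] + s$material$texture_sd * tx
    }
    lab[idx] <- next_id
    map <- rbind(map, data.frame(id = next_id, label = s$label,
                                 stringsAsFactors = FALSE))
    next_id <- next_id + 1L
  }
  list(volume = voxel_volume(vol, spacing, origin),
       labels = list(volume = lab, map = map))
}

#' Ground-truth mask for one label of a rasterized phantom
#'
#' @param labels the `labels` element returned by [rasterize()].
#' @param label label name from the label map.
#' @return An [roi_mask()].
#' @export
label_mask <- function(labels, label) {
  id <- labels$map$id[match(label, labels$map$label)]
  if (is.na(id)) stopf("label '%s' not present in label map", label)
  roi_mask(label, which(labels$volume == id), dim(labels$volume))
}
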