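## ---- connected components and morphology ------------------------------

## 3-D connected components: 2-D labelling per slice (EBImage) merged
## across adjacent slices with union-find
connected_components_3d <- function(mask) {
  d <- dim(mask)
  lab <- EBImage::bwlabel(mask * 1)          # labels restart on every slice
  m2 <- matrix(as.integer(lab), ncol = d[3])
  nlab <- apply(m2, 2, max)
  offs <- as.integer(cumsum(c(0, nlab[-d[3]])))
  m2 <- m2 + rep(offs, each = d[1] * d[2]) * (m2 > 0L)
  lab <- array(m2, d)
  total <- as.integer(sum(nlab))
  if (total == 0L) return(list(labels = lab, n = 0L))
  parent <- seq_len(total)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(d[3] - 1L)) {
    a <- lab[, , k]; b <- lab[, , k + 1L]
    sel <- a > 0L & b > 0L
    if (!any(sel)) next
    key <- unique(as.numeric(a[sel]) * (total + 1) + b[sel])
    pa <- as.integer(key %/% (total + 1)); pb <- as.integer(key %% (total + 1))
    for (r in seq_along(key)) {
      ra <- find(pa[r]); rb <- find(pb[r])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(total), find, 0L)
  compact <- match(roots, sort(unique(roots)))
  nz <- lab > 0L
  lab[nz] <- compact[lab[nz]]
  list(labels = lab, n = max(compact))
}

## zero-padded logical shift
shift_logical <- function(m, s) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    if (s[a] >= 0) { dst[[a]] <- (1 + s[a]):d[a]; src[[a]] <- 1:(d[a] - s[a]) }
    else { dst[[a]] <- 1:(d[a] + s[a]); src[[a]] <- (1 - s[a]):d[a] }
    if (d[a] <= abs(s[a])) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

## erode a voxel-index set by a spherical margin in mm
erode_indices <- function(indices, dims, spacing, margin) {
  if (margin <= 0) return(indices)
  m <- array(FALSE, dims); m[indices] <- TRUE
  r <- floor(margin / spacing)
  out <- m
  for (dx in -r[1]:r[1]) for (dy in -r[2]:r[2]) for (dz in -r[3]:r[3]) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (sum((c(dx, dy, dz) * spacing)^2) > margin^2) next
    out <- out & shift_logical(m, c(dx, dy, dz))
  }
  which(out)
}

## ---- lung segmentation -------------------------------------------------

#' Segment the phantom lungs
#'
#' Thresholds below `threshold` HU inside the body (exterior air is
#' excluded by filling the body outline slice-by-slice), labels connected
#' components in 3-D and keeps the two largest -- the left and right foam
#' lungs.  Insert payloads inside the tubular channels stay excluded
#' because the tube walls are denser than the threshold.
#'
#' @param vol a [voxel_volume()].
#' @param threshold HU below which a voxel can be lung foam.
#' @param min_voxels smallest credible lung-component size.
#' @return An [roi_mask()] covering both foam lungs.
#' @export
segment_lungs <- function(vol, threshold = -300, min_voxels = 100L) {
  vol <- as_voxel_volume(vol)
  d <- dim(vol$voxels)
  body <- vol$voxels > threshold
  if (sum(body) < min_voxels)
    stopf("no body found: nothing above %g HU", threshold)
  filled <- EBImage::fillHull(body * 1) > 0   # per-slice hole filling
  cand <- filled & (vol$voxels < threshold)
  cc <- connected_components_3d(cand)
  if (cc$n < 2L)
    stopf("fewer than two lung candidates found (got %d component(s))", cc$n)
  sizes <- tabulate(cc$labels[cc$labels > 0L], nbins = cc$n)
  top <- order(sizes, decreasing = TRUE)[1:2]
  if (sizes[top[2]] < min_voxels)
    stopf("second lung candidate too small (%d voxels)", sizes[top[2]])
  roi_mask("lungs", which(cc$labels == top[1] | cc$labels == top[2]), d)
}

## ---- insert segmentation ----------------------------------------------

## expected payload HU profile along z for one tube (phantom frame)
tube_profile <- function(layout, tube_center, zs) {
  p <- rep(-1000, length(zs))
  for (s in layout$inserts) {
    if (!isTRUE(all.equal(s$center[1:2], tube_center))) next
    if (s$shape == "cube") {
      inz <- abs(zs - s$center[3]) <= s$radius_or_halfedge
    } else inz <- abs(zs - s$center[3]) <= s$length / 2
    p[inz] <- s$material$nominal_hu
  }
  p
}

## translation of the scanned phantom relative to the layout frame;
## (x, y) from the centroid of the filled body outline (exactly the body
## centre by symmetry, and insensitive to interior structures and blur),
## z from tube-content matching
estimate_shift <- function(vol, layout, shift_search_mm = 20) {
  v <- vol$voxels; d <- dim(v)
  coords <- grid_coords(d, vol$spacing, vol$origin)
  body <- v > -300
  if (sum(body) < 100) stopf("no body found for alignment")
  filled <- EBImage::fillHull(body * 1) > 0
  ai <- which(filled)
  xs <- coords$x[(ai - 1) %% d[1] + 1]
  ys <- coords$y[((ai - 1) %/% d[1]) %% d[2] + 1]
  dxy <- c(mean(xs), mean(ys))

  ## z from matching tube content against the expected payload profile
  geom <- layout$geometry
  tubes <- c(list(geom$large_tube), unname(geom$small_tubes))
  zg <- coords$z
  steps <- round(shift_search_mm / vol$spacing[3])
  cand <- (-steps:steps) * vol$spacing[3]
  sse <- numeric(length(cand))
  prof <- list()
  for (t in seq_along(tubes)) {
    tb <- tubes[[t]]
    ctr <- c(tb$center + dxy, 0)
    idx2 <- cylinder_indices(coords, d, ctr, tb$inner_r * 0.7, 1e9)
    if (!length(idx2)) next
    sl <- ((idx2 - 1) %/% (d[1] * d[2])) + 1
    prof[[t]] <- list(meas = tapply(v[idx2], sl, mean), tube = tb)
  }
  for (ci in seq_along(cand)) {
    tot <- 0
    for (t in seq_along(prof)) {
      if (is.null(prof[[t]])) next
      pr <- tube_profile(layout, prof[[t]]$tube$center,
                         zg[as.integer(names(prof[[t]]$meas))] - cand[ci])
      tot <- tot + sum((prof[[t]]$meas - pr)^2)
    }
    sse[ci] <- tot
  }
  c(dxy, cand[which.min(sse)])
}

#' Segment and label phantom inserts
#'
#' Locates every labelled insert expected by a layout: the phantom's
#' translation is estimated from the filled body-outline centroid (x, y)
#' and from matching tube content against the expected axial HU profile
#' (z); each insert mask is then instantiated from the aligned geometry
#' and eroded by `margin` to exclude walls and partial-volume voxels.
#' An insert whose measured mean HU is far from its nominal value (or
#' which falls outside the volume) is reported as missing and the
#' remaining masks are still returned.
#'
#' @param vol a [voxel_volume()].
#' @param layout the [build_layout()] matching the scanned configuration.
#' @param margin erosion margin in mm (default 1 mm, about two in-plane
#'   voxels at the standard reconstruction geometry).
#' @param hu_tol reject an insert whose measured mean HU deviates from its
#'   nominal by more than this (HU).
#' @param shift_search_mm half-range of the z alignment search.
#' @return A list of [roi_mask()]s, one per found insert, with attribute
#'   `missing` naming any expected inserts that were not found and
#'   attribute `shift` giving the estimated translation (mm).
#' @export
segment_inserts <- function(vol, layout, margin = 1.0, hu_tol = 250,
                            shift_search_mm = 20) {
  vol <- as_voxel_volume(vol)
  d <- dim(vol$voxels)
  shift <- estimate_shift(vol, layout, shift_search_mm)
  ## evaluate layout geometry in the phantom frame
  coords <- grid_coords(d, vol$spacing, vol$origin)
  coords_ph <- list(x = coords$x - shift[1], y = coords$y - shift[2],
                    z = coords$z - shift[3])
  masks <- list(); missing <- character(0)
  for (s in layout$inserts) {
    if (s$role != "insert") next
    idx <- shape_indices(s, coords_ph, d)
    idx <- erode_indices(idx, d, vol$spacing, margin)
    if (!length(idx)) { missing <- c(missing, s$label); next }
    mu <- mean(vol$voxels[idx])
    if (abs(mu - s$material$nominal_hu) > hu_tol) {
      missing <- c(missing, s$label); next
    }
    masks[[s$label]] <- roi_mask(s$label, idx, d, erosion_margin = margin)
  }
  if (length(missing))
    warning(sprintf("inserts not found: %s", paste(missing, collapse = ", ")),
            call. = FALSE)
  attr(masks, "missing") <- missing
  attr(masks, "shift") <- shift
  masks
}

#' Dice overlap between two masks
#'
#' @param a,b [roi_mask()]s on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(a$dim, b$dim)) stopf("masks are on different grids")
  2 * length(intersect(a$indices, b$indices)) /
    (length(a$indices) + length(b$indices))
}
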