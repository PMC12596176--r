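## ---- noise power spectrum ---------------------------------------------

## 2-D polynomial detrending basis (total degree <= order), with a cached
## QR projector per (n, order)
poly_basis_2d <- function(n, order) {
  u <- seq(-1, 1, length.out = n)
  G <- expand.grid(x = u, y = u)
  cols <- list()
  for (i in 0:order) for (j in 0:(order - i))
    cols[[length(cols) + 1L]] <- G$x^i * G$y^j
  qr(do.call(cbind, cols))
}

detrend_patch <- function(patch, qrb) {
  patch - matrix(qr.fitted(qrb, as.vector(patch)), nrow(patch))
}

#' In-plane noise power spectrum
#'
#' Estimates the 2-D NPS from non-overlapping square patches tiled over a
#' uniform region: each patch is detrended with a 2-D polynomial, Fourier
#' transformed, and its squared modulus scaled by
#' `(pitch_x * pitch_y) / (Nx * Ny)`; patch spectra are averaged over all
#' patches and slices and radially binned to a 1-D profile.  With this
#' normalization the integral of the 2-D NPS over the frequency plane
#' equals the detrended voxel variance (Parseval).
#'
#' @param vol a [voxel_volume()].
#' @param uniform_mask [roi_mask()] over a homogeneous material.
#' @param patch_edge patch size in voxels.
#' @param detrend_order polynomial order for per-patch detrending.
#' @return An `nps_curve`: list with `axis = "in_plane"`, `frequencies`
#'   (1/mm, 0 to Nyquist), `power` (HU^2 mm^2), `n_patches`,
#'   `detrend_order`, `total_variance` (mean detrended patch variance) and
#'   `integral` (sum of the 2-D NPS times the frequency-bin area).
#' @export
nps_inplane <- function(vol, uniform_mask, patch_edge = 64L,
                        detrend_order = 2L) {
  vol <- as_voxel_volume(vol)
  d <- dim(vol$voxels)
  m <- mask_to_array(uniform_mask)
  ne <- as.integer(patch_edge)
  px <- vol$spacing[1]; py <- vol$spacing[2]
  qrb <- poly_basis_2d(ne, detrend_order)
  acc <- matrix(0, ne, ne)
  nP <- 0L
  vsum <- 0
  for (k in seq_len(d[3])) {
    mk <- m[, , k]
    if (!any(mk)) next
    ## tile the bounding box of the slice mask
    rr <- range(which(rowSums(mk) > 0)); cr <- range(which(colSums(mk) > 0))
    for (i0 in seq(rr[1], rr[2] - ne + 1L, by = ne))
      for (j0 in seq(cr[1], cr[2] - ne + 1L, by = ne)) {
        if (!all(mk[i0:(i0 + ne - 1L), j0:(j0 + ne - 1L)])) next
        p <- detrend_patch(vol$voxels[i0:(i0 + ne - 1L),
                                      j0:(j0 + ne - 1L), k], qrb)
        acc <- acc + Mod(fft(p))^2
        vsum <- vsum + sum(p^2) / (ne * ne)
        nP <- nP + 1L
      }
  }
  if (nP < 4L)
    stopf("too few patches: found %d, need at least 4 (mask too small for %dx%d patches)",
          nP, ne, ne)
  nps2d <- acc / nP * (px * py) / (ne * ne)
  fx <- c(0:(ne %/% 2), -((ne - ne %/% 2 - 1):1)) / (ne * px)
  fy <- c(0:(ne %/% 2), -((ne - ne %/% 2 - 1):1)) / (ne * py)
  fr <- sqrt(outer(fx^2, fy^2, "+"))
  dfb <- 1 / (ne * max(px, py))
  bins <- floor(fr / dfb)
  prof <- tapply(as.vector(nps2d), as.vector(bins), mean)
  bi <- as.integer(names(prof))
  nyq <- 1 / (2 * max(px, py))
  keepb <- (bi + 0.5) * dfb <= nyq * 1.0001
  structure(list(axis = "in_plane",
                 frequencies = (bi[keepb] + 0.5) * dfb,
                 power = as.vector(prof)[keepb],
                 n_patches = nP, detrend_order = detrend_order,
                 total_variance = vsum / nP,
                 integral = sum(nps2d) / (ne * px) / (ne * py) * 1,
                 nps2d = nps2d, df = c(1 / (ne * px), 1 / (ne * py))),
            class = "nps_curve")
}

#' z-direction noise power spectrum
#'
#' For every (x, y) column fully inside the mask over a contiguous run of
#' at least `min_slices` slices: detrend along z with a polynomial, take
#' the 1-D Fourier transform, scale the squared modulus by
#' `pitch_z / Nz`, and average over columns.
#'
#' @param vol a [voxel_volume()].
#' @param uniform_mask [roi_mask()] spanning at least `min_slices` slices.
#' @param detrend_order polynomial order along z.
#' @param min_slices minimum z extent.
#' @return An `nps_curve` with `axis = "z"`, `frequencies` (1/mm) and
#'   `power` (HU^2 mm).
#' @export
nps_z <- function(vol, uniform_mask, detrend_order = 2L, min_slices = 32L) {
  vol <- as_voxel_volume(vol)
  d <- dim(vol$voxels)
  m <- mask_to_array(uniform_mask)
  zin <- apply(m, 3, any)
  runs <- rle(zin)
  if (!any(runs$values & runs$lengths >= min_slices))
    stopf("mask spans fewer than %d contiguous slices", min_slices)
  ri <- which(runs$values & runs$lengths >= min_slices)[1]
  z1 <- sum(runs$lengths[seq_len(ri - 1)]) + 1L
  nz <- runs$lengths[ri]
  zr <- z1:(z1 + nz - 1L)
  cols <- which(apply(m[, , zr, drop = FALSE], c(1, 2), all))
  if (length(cols) < 4L) stopf("too few full columns inside the mask")
  u <- seq(-1, 1, length.out = nz)
  B <- do.call(cbind, lapply(0:detrend_order, function(i) u^i))
  qrb <- qr(B)
  pz <- vol$spacing[3]
  acc <- numeric(nz)
  vsum <- 0
  sl <- matrix(vol$voxels[, , zr], d[1] * d[2], nz)
  for (ci in cols) {
    col <- sl[ci, ]
    r <- col - qr.fitted(qrb, col)
    acc <- acc + Mod(fft(r))^2
    vsum <- vsum + sum(r^2) / nz
  }
  nP <- length(cols)
  p1 <- acc / nP * pz / nz
  fz <- (0:(nz %/% 2)) / (nz * pz)
  structure(list(axis = "z", frequencies = fz,
                 power = p1[seq_along(fz)],
                 n_patches = nP, detrend_order = detrend_order,
                 total_variance = vsum / nP,
                 integral = sum(p1) / (nz * pz)),
            class = "nps_curve")
}

#' Peak frequency of an NPS profile
#'
#' Frequency of maximum power with parabolic sub-bin refinement.  A
#' profile whose maximum is not clearly above its median (flat, white-like
#' spectrum) is flagged and reported with peak frequency 0.
#'
#' @param curve an `nps_curve`.
#' @param flatness_ratio flag the curve as flat when
#'   `max(power) < flatness_ratio * median(power)`.
#' @return List with `frequency` (1/mm) and logical `flat`.
#' @export
nps_peak <- function(curve, flatness_ratio = 1.5) {
  p <- curve$power; f <- curve$frequencies
  if (length(p) < 3L) stopf("degenerate NPS profile")
  if (max(p) < flatness_ratio * median(p))
    return(list(frequency = 0, flat = TRUE))
  i <- which.max(p)
  if (i == 1L || i == length(p))
    return(list(frequency = f[i], flat = FALSE))
  ## parabolic refinement on the three points around the maximum
  y1 <- p[i - 1]; y2 <- p[i]; y3 <- p[i + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (denom != 0) 0.5 * (y1 - y3) / denom else 0
  list(frequency = f[i] + delta * (f[2] - f[1]), flat = FALSE)
}

#' @export
print.nps_curve <- function(x, ...) {
  cat(sprintf("<nps_curve> %s: %d bins to %.3g /mm, %d patches, variance %.3g HU^2\n",
              x$axis, length(x$frequencies), max(x$frequencies),
              x$n_patches, x$total_variance))
  invisible(x)
}
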