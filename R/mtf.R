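## ---- modulation transfer function from the cube-edge insert -----------

face_axis <- function(face) {
  ax <- match(substr(face, 2, 2), c("x", "y", "z"))
  sgn <- if (substr(face, 1, 1) == "+") 1 else -1
  list(axis = ax, sign = sgn)
}

#' Locate the MTF cube insert
#'
#' Finds the pose of the high-density cube surrounded by air.  The centre
#' starts at the centroid of the supplied mask (or of the above-threshold
#' region), and each of the six candidate faces is located as the
#' half-level crossing of the mean HU profile cast outward along its axis.
#' A face whose apparent distance is far from the median face distance is
#' not an air edge (this is how the face glued to the insert end cap, which
#' shows no contrast, is excluded from the exposed set).
#'
#' @param vol a [voxel_volume()].
#' @param mask optional [roi_mask()] restricting the search region (e.g.
#'   from [segment_inserts()] or a ground-truth label mask); by default the
#'   whole volume is used.
#' @return A `cube_pose`: list with `center` (mm), `half_edge` (mm),
#'   `exposed` (named logical over `+x,-x,+y,-y,+z,-z`), and the plateau
#'   levels `hu_in`, `hu_out`.
#' @export
locate_cube <- function(vol, mask = NULL) {
  vol <- as_voxel_volume(vol)
  d <- dim(vol$voxels)
  coords <- grid_coords(d, vol$spacing, vol$origin)
  if (!is.null(mask)) {
    if (!identical(mask$dim, d)) stopf("mask does not match the volume grid")
    idx <- mask$indices
  } else {
    qlo <- quantile(vol$voxels, 0.02); qhi <- quantile(vol$voxels, 0.98)
    idx <- which(vol$voxels > (qlo + qhi) / 2)
    if (length(idx) < 27)
      stopf("no compact high-attenuation region found for the cube")
  }
  ai <- arrayInd(idx, d)
  c0 <- c(mean(coords$x[ai[, 1]]), mean(coords$y[ai[, 2]]),
          mean(coords$z[ai[, 3]]))
  h0 <- (length(idx) * prod(vol$spacing))^(1/3) / 2
  hu_in <- median(vol$voxels[idx])

  ## the search region itself must have cube-like proportions
  ext <- c(diff(range(coords$x[ai[, 1]])), diff(range(coords$y[ai[, 2]])),
           diff(range(coords$z[ai[, 3]]))) / 2 + vol$spacing / 2
  if (max(ext) / min(ext) > 1.25)
    stopf("region is not cube-like (half-edge extents %s mm)",
          paste(sprintf("%.1f", ext), collapse = "/"))

  ## mean-HU profile outward along each axis over a central transverse window
  axes <- list(x = coords$x, y = coords$y, z = coords$z)
  face_dist <- rep(NA_real_, 6)
  names(face_dist) <- c("+x", "-x", "+y", "-y", "+z", "-z")
  prof_out <- list()
  for (f in names(face_dist)) {
    fa <- face_axis(f)
    tr <- setdiff(1:3, fa$axis)
    s1 <- which(abs(axes[[tr[1]]] - c0[tr[1]]) <= 0.5 * h0)
    s2 <- which(abs(axes[[tr[2]]] - c0[tr[2]]) <= 0.5 * h0)
    u <- fa$sign * (axes[[fa$axis]] - c0[fa$axis])
    sa <- which(u >= 0 & u <= 2.2 * h0)
    if (!length(s1) || !length(s2) || length(sa) < 3) next
    sa <- sa[order(u[sa])]
    sub <- list(0, 0, 0)
    sub[[fa$axis]] <- sa; sub[[tr[1]]] <- s1; sub[[tr[2]]] <- s2
    pr <- apply(vol$voxels[sub[[1]], sub[[2]], sub[[3]], drop = FALSE],
                fa$axis, mean)
    uu <- u[sa]
    lo_est <- min(pr)
    half <- (hu_in + lo_est) / 2
    if (lo_est > hu_in - 100) next       # no air contrast along this axis
    cr <- which(pr[-length(pr)] > half & pr[-1] <= half)
    if (!length(cr)) next
    i <- cr[1]
    face_dist[f] <- uu[i] + (pr[i] - half) / (pr[i] - pr[i + 1]) *
      (uu[i + 1] - uu[i])
    prof_out[[f]] <- pr
  }
  if (all(is.na(face_dist)))
    stopf("no air-contrast cube faces found")
  h_med <- median(face_dist, na.rm = TRUE)
  exposed <- !is.na(face_dist) & abs(face_dist - h_med) <= 0.2 * h_med
  ## per-axis half-edge from exposed faces; centre refined where both
  ## opposite faces are exposed
  he <- numeric(0)
  center <- c0
  for (a in 1:3) {
    fp <- c("+x", "+y", "+z")[a]; fm <- c("-x", "-y", "-z")[a]
    if (exposed[fp] && exposed[fm]) {
      he <- c(he, (face_dist[fp] + face_dist[fm]) / 2)
      center[a] <- c0[a] + (face_dist[fp] - face_dist[fm]) / 2
    } else if (exposed[fp] || exposed[fm]) {
      he <- c(he, face_dist[if (exposed[fp]) fp else fm])
    }
  }
  if (!length(he)) stopf("no measurable cube faces")
  if (max(he) / min(he) > 1.2)
    stopf("region is not cube-like (half-edge extents %s mm)",
          paste(sprintf("%.1f", he), collapse = "/"))
  hu_out <- mean(vapply(which(exposed), function(i) {
    pr <- prof_out[[names(exposed)[i]]]
    mean(tail(pr, max(2L, round(0.2 * length(pr)))))
  }, 0))
  structure(list(center = center, half_edge = mean(he), exposed = exposed,
                 hu_in = hu_in, hu_out = hu_out),
            class = "cube_pose")
}

#' Extract an averaged edge-spread function from one cube face
#'
#' Casts rays through voxel centres across the central region of the face
#' (at least 25 % of the half-edge away from the cube edges), locates each
#' ray's edge at the half-height crossing, fits a plane through the per-ray
#' edge positions (sub-voxel alignment; the fitted obliquity also supplies
#' the small cosine distance correction for a near-axis-aligned face), and
#' accumulates all samples into a supersampled common grid: samples are
#' projected onto their signed distance from the fitted edge plane,
#' binned at `sample_pitch`, and averaged.
#'
#' @param vol a [voxel_volume()].
#' @param pose a [locate_cube()] result.
#' @param face one of `"+x","-x","+y","-y","+z","-z"` (must be exposed).
#' @param ray_count approximate number of rays (arranged on a square grid
#'   over the face's central region).
#' @param sample_pitch resampling pitch in mm; default one tenth of the
#'   voxel pitch along the face normal.
#' @param profile_halfwidth half-extent of the profile around the edge in
#'   mm; by default as wide as the cube interior and the surrounding air
#'   allow, capped at 12 mm.
#' @param face_margin_frac margin kept from the cube edges, as a fraction
#'   of the half-edge.
#' @return An `edge_profile`: list with `face`, `distances` (mm, uniform,
#'   negative inside the cube is the high plateau side... positive points
#'   outward), `esf` (HU), `n_rays`, `pitch`.
#' @export
extract_esf <- function(vol, pose, face, ray_count = 64,
                        sample_pitch = NULL, profile_halfwidth = NULL,
                        face_margin_frac = 0.25) {
  vol <- as_voxel_volume(vol)
  if (!face %in% names(pose$exposed) || !isTRUE(pose$exposed[face]))
    stopf("face '%s' is not an exposed cube face", face)
  d <- dim(vol$voxels)
  coords <- grid_coords(d, vol$spacing, vol$origin)
  fa <- face_axis(face)
  ax <- fa$axis; sgn <- fa$sign
  tr <- setdiff(1:3, ax)
  h <- pose$half_edge
  axc <- switch(ax, coords$x, coords$y, coords$z)
  face_pos <- pose$center[ax] + sgn * h
  pitch_ax <- vol$spacing[ax]
  if (is.null(sample_pitch)) sample_pitch <- pitch_ax / 10

  ## admissible half-width: inside up to 1.4 h past the face, outside up
  ## to the volume boundary
  u_all <- sgn * (axc - face_pos)
  out_max <- max(u_all) - pitch_ax
  in_max <- -(min(u_all)) - pitch_ax
  hw <- min(12, 1.4 * h, out_max, in_max,
            profile_halfwidth %||% Inf)
  if (hw < 4)
    stopf("rays leave the volume: only %.1f mm of profile available", hw)

  keep <- which(u_all >= -hw - pitch_ax & u_all <= hw + pitch_ax)
  us <- u_all[keep]
  ord <- order(us); keep <- keep[ord]; us <- us[ord]

  t1c <- switch(tr[1], coords$x, coords$y, coords$z)
  t2c <- switch(tr[2], coords$x, coords$y, coords$z)
  lim <- (1 - face_margin_frac) * h
  c1 <- which(abs(t1c - pose$center[tr[1]]) <= lim)
  c2 <- which(abs(t2c - pose$center[tr[2]]) <= lim)
  if (!length(c1) || !length(c2)) stopf("insufficient rays on face '%s'", face)
  side <- max(1L, round(sqrt(ray_count)))
  c1 <- c1[unique(round(seq(1, length(c1), length.out = min(side, length(c1)))))]
  c2 <- c2[unique(round(seq(1, length(c2), length.out = min(side, length(c2)))))]
  rays <- expand.grid(i = c1, j = c2)
  if (nrow(rays) < 1) stopf("insufficient rays on face '%s'", face)

  half_level <- (pose$hu_in + pose$hu_out) / 2
  nprof <- length(keep)
  P <- matrix(NA_real_, nprof, nrow(rays))
  epos <- numeric(nrow(rays))
  sel <- function(i, j, kk) {
    idx <- list(0, 0, 0)
    idx[[ax]] <- kk; idx[[tr[1]]] <- i; idx[[tr[2]]] <- j
    vol$voxels[idx[[1]], idx[[2]], idx[[3]]]
  }
  for (r in seq_len(nrow(rays))) {
    p <- sel(rays$i[r], rays$j[r], keep)
    P[, r] <- p
    dsign <- p - half_level
    cr <- which(dsign[-nprof] > 0 & dsign[-1] <= 0)
    if (!length(cr)) { epos[r] <- NA; next }
    cr <- cr[which.min(abs(us[cr]))]
    ## local cubic interpolation of the crossing (a two-point chord has a
    ## curvature-dependent sub-voxel bias that would shift the ESF)
    lo_i <- max(1L, cr - 1L); hi_i <- min(nprof, cr + 2L)
    fine <- spline(us[lo_i:hi_i], dsign[lo_i:hi_i], n = 64,
                   method = "natural")
    fc <- which(fine$y[-length(fine$y)] > 0 & fine$y[-1] <= 0)
    if (length(fc)) {
      fc <- fc[1]
      epos[r] <- fine$x[fc] + fine$y[fc] / (fine$y[fc] - fine$y[fc + 1]) *
        (fine$x[fc + 1] - fine$x[fc])
    } else {
      epos[r] <- us[cr] + dsign[cr] / (dsign[cr] - dsign[cr + 1]) *
        (us[cr + 1] - us[cr])
    }
  }
  ok <- which(!is.na(epos))
  if (length(ok) < 1) stopf("no edge crossing found on face '%s'", face)
  t1 <- t1c[rays$i[ok]]; t2 <- t2c[rays$j[ok]]
  if (length(ok) >= 3 && length(unique(t1)) + length(unique(t2)) > 2) {
    fit <- lm(epos[ok] ~ t1 + t2)
    ehat <- fitted(fit)
    ab <- coef(fit)[-1]; ab[is.na(ab)] <- 0
    cosfac <- 1 / sqrt(1 + sum(ab^2))
  } else { ehat <- epos[ok]; cosfac <- 1 }

  dist <- (rep(us, length(ok)) - rep(ehat, each = nprof)) * cosfac
  val <- as.vector(P[, ok])
  nb <- floor(2 * hw / sample_pitch)
  bins <- floor((dist + hw) / sample_pitch)
  inb <- bins >= 0 & bins < nb
  ## knots at the mean sample position of each bin (assigning values to
  ## bin centres would quantize the edge by up to half a bin)
  mv <- tapply(val[inb], bins[inb], mean)
  md <- tapply(dist[inb], bins[inb], mean)
  grid <- -hw + (seq_len(nb) - 0.5) * sample_pitch
  esf <- approx(as.vector(md), as.vector(mv), xout = grid, rule = 2,
                ties = "ordered")$y
  structure(list(face = face, distances = grid, esf = esf,
                 n_rays = length(ok), pitch = sample_pitch,
                 axis = c("x", "y", "z")[ax]),
            class = "edge_profile")
}

#' Convert an edge-spread function to an MTF curve
#'
#' Differentiates the ESF to the line-spread function, applies a Hann
#' window centred on the LSF peak (tapered tails with a flat core; the
#' window half-width adapts to the measured edge width so that tail noise
#' is removed without biasing the main lobe), Fourier-transforms the
#' windowed LSF and normalizes the modulus to 1 at zero frequency.
#'
#' @param profile an [extract_esf()] result.
#' @param fwhm_mult window half-width as a multiple of the LSF FWHM
#'   (estimated from the 10-90 % edge rise distance).
#' @param taper fraction of the window half-width occupied by the cosine
#'   taper (0 = rectangular, 1 = full Hann).
#' @return An `mtf_curve`: list with `frequencies` (cycles/cm, starting at
#'   0), `modulation` (1 at zero frequency), `f50`, `f20` (cycles/cm),
#'   `axis`, and the window half-width used (`window_hw_mm`).
#' @export
esf_to_mtf <- function(profile, fwhm_mult = 4, taper = 0.5) {
  st <- profile$distances
  pitch <- profile$pitch
  if (max(abs(diff(diff(st)))) > 1e-9) stopf("profile grid is not uniform")
  esf <- profile$esf
  n <- length(esf)
  lsf <- c(0, diff(esf)) / pitch

  hi <- mean(head(esf, max(3L, round(0.05 * n))))
  lo <- mean(tail(esf, max(3L, round(0.05 * n))))
  hf <- (hi + lo) / 2
  cr <- which(esf[-n] > hf & esf[-1] <= hf)
  if (!length(cr)) stopf("edge not contained in the profile")
  pk <- cr[which.min(abs(st[cr]))]
  if (pk <= 5L || pk >= n - 5L)
    stopf("LSF peak at the profile boundary; edge not contained")

  ## 10-90 % rise distance -> sigma -> FWHM (Gaussian-equivalent)
  dh <- hi - lo
  a90 <- hi - 0.1 * dh; a10 <- hi - 0.9 * dh
  i90 <- which(esf[-1] <= a90 & esf[-n] > a90)
  i10 <- which(esf[-1] <= a10 & esf[-n] > a10)
  i90 <- if (length(i90)) i90[which.min(abs(i90 - pk))] else pk
  i10 <- if (length(i10)) i10[which.min(abs(i10 - pk))] else pk
  sig_est <- max(abs(i10 - i90) * pitch, 0.3) / 2.563
  fwhm <- 2.355 * sig_est
  hwn <- min(pk - 1L, n - pk,
             max(round(2 / pitch), round(fwhm_mult * fwhm / pitch)))
  c0 <- (1 - taper) * hwn
  w <- numeric(n)
  idx <- (pk - hwn):(pk + hwn)
  tt <- abs(idx - pk)
  w[idx] <- ifelse(tt <= c0, 1, 0.5 * (1 + cos(pi * (tt - c0) / (hwn - c0))))
  lw <- lsf * w

  nfft <- 2^ceiling(log2(max(4 * n, 2048)))
  mod <- Mod(fft(c(lw, numeric(nfft - n))))
  if (mod[1] == 0) stopf("degenerate profile: zero edge height")
  mod <- mod / mod[1]
  fr_cm <- 10 * (seq_len(nfft) - 1) / (nfft * pitch)   # cycles/cm
  nk <- nfft %/% 2
  curve <- structure(list(axis = profile$axis,
                          frequencies = fr_cm[1:nk],
                          modulation = mod[1:nk],
                          window_hw_mm = hwn * pitch,
                          n_rays = profile$n_rays),
                     class = "mtf_curve")
  curve$f50 <- mtf_cutoff(curve, 0.5)
  curve$f20 <- mtf_cutoff(curve, 0.2)
  curve
}

#' Frequency at which an MTF curve falls to a given modulation level
#'
#' First downward crossing of the level, located by linear interpolation
#' between adjacent frequency samples.
#'
#' @param curve an [esf_to_mtf()] result.
#' @param level modulation level in (0, 1]; level 1 is the normalization
#'   point at zero frequency.
#' @return Frequency in cycles/cm.
#' @export
mtf_cutoff <- function(curve, level) {
  if (!is.finite(level) || level <= 0 || level > 1)
    stopf("level must be in (0, 1]")
  if (level == 1) return(0)
  m <- curve$modulation; f <- curve$frequencies
  n <- length(m)
  cr <- which(m[-n] > level & m[-1] <= level)
  if (!length(cr))
    stopf("modulation never falls below %.2f within the sampled band (up to %.2f cycles/cm)",
          level, max(f))
  i <- cr[1]
  f[i] + (m[i] - level) / (m[i] - m[i + 1]) * (f[i + 1] - f[i])
}

#' In-plane and z-direction MTF of the cube insert
#'
#' Measures one exposed face perpendicular to each axis.  The x- and
#' y-axis curves are averaged pointwise on a common frequency grid to give
#' the in-plane MTF (cutoffs recomputed on the averaged curve); the
#' z-direction curve is reported separately.
#'
#' @param vol a [voxel_volume()].
#' @param pose a [locate_cube()] result.
#' @param ... passed to [extract_esf()].
#' @return List with `in_plane` and `z` (both `mtf_curve`s) plus the
#'   per-axis `x` and `y` curves.
#' @export
inplane_and_z_mtf <- function(vol, pose, ...) {
  pick <- function(pos, neg) {
    if (isTRUE(pose$exposed[pos])) pos
    else if (isTRUE(pose$exposed[neg])) neg
    else stopf("no exposed face perpendicular to the %s axis",
               substr(pos, 2, 2))
  }
  cx <- esf_to_mtf(extract_esf(vol, pose, pick("+x", "-x"), ...))
  cy <- esf_to_mtf(extract_esf(vol, pose, pick("+y", "-y"), ...))
  cz <- esf_to_mtf(extract_esf(vol, pose, pick("+z", "-z"), ...))
  my <- approx(cy$frequencies, cy$modulation, xout = cx$frequencies,
               rule = 2)$y
  ip <- structure(list(axis = "in_plane", frequencies = cx$frequencies,
                       modulation = (cx$modulation + my) / 2,
                       window_hw_mm = mean(c(cx$window_hw_mm, cy$window_hw_mm)),
                       n_rays = cx$n_rays + cy$n_rays),
                  class = "mtf_curve")
  ip$f50 <- mtf_cutoff(ip, 0.5)
  ip$f20 <- mtf_cutoff(ip, 0.2)
  list(in_plane = ip, z = cz, x = cx, y = cy)
}

#' @export
print.mtf_curve <- function(x, ...) {
  cat(sprintf("<mtf_curve> axis %s: f50 = %.2f, f20 = %.2f cycles/cm (%d rays)\n",
              x$axis, x$f50, x$f20, x$n_rays %||% NA))
  invisible(x)
}
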