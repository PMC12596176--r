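## analytic Gaussian-blurred cube on the standard reconstruction grid
cube_vol <- function(sigma, noise_sd = 0, seed = 1, tilt = c(2, 2) * pi / 180,
                     dims = c(120, 120, 120)) {
  render_gaussian_cube(dims, c(0.51, 0.51, 0.5),
                       center = c(0.13, 0.07, -0.11), sigma = sigma,
                       tilt = tilt, noise_sd = noise_sd, seed = seed)
}

test_that("cube pose is recovered to sub-voxel accuracy", {
  vol <- cube_vol(0.5)
  pose <- locate_cube(vol)
  expect_lt(max(abs(pose$center - c(0.13, 0.07, -0.11))), 0.3)
  expect_lt(abs(pose$half_edge - 10), 0.3)
  expect_true(all(pose$exposed))

  ## translation invariance: same cube, shifted grid
  vol2 <- render_gaussian_cube(c(120, 120, 120), c(0.51, 0.51, 0.5),
                               center = c(4.5, -3.2, 2.7), sigma = 0.5,
                               tilt = c(2, 2) * pi / 180)
  pose2 <- locate_cube(vol2)
  expect_lt(abs(pose2$half_edge - pose$half_edge), 0.05)

  ## an elongated slab is rejected
  slab <- array(-1000, c(80, 80, 80))
  slab[20:60, 30:50, 30:50] <- -80
  expect_error(locate_cube(voxel_volume(slab, c(0.51, 0.51, 0.5))),
               "not cube-like")
})

test_that("averaged ESF matches the analytic Gaussian edge profile", {
  sig <- 0.5
  vol <- cube_vol(sig)
  pose <- locate_cube(vol)
  pr <- extract_esf(vol, pose, "+x", ray_count = 64)
  ## compare shapes allowing the common sub-voxel registration offset
  ## (the per-ray half-height crossings share a small discretization bias)
  half <- (-80 + -1000) / 2
  ic <- which(pr$esf[-length(pr$esf)] > half & pr$esf[-1] <= half)[1]
  d0 <- pr$distances[ic] + (pr$esf[ic] - half) /
    (pr$esf[ic] - pr$esf[ic + 1]) * (pr$distances[ic + 1] - pr$distances[ic])
  expected <- -1000 + 920 * pnorm(-(pr$distances - d0) / sig)
  height <- 920
  expect_lt(abs(d0), 0.1)          # registration bias is sub-voxel
  core <- abs(pr$distances) < 6    # away from the far tails
  expect_lt(max(abs(pr$esf[core] - expected[core])) / height, 0.01)

  ## plateau levels approximate the two materials
  expect_lt(abs(mean(head(pr$esf, 10)) - (-80)), 15)
  expect_lt(abs(mean(tail(pr$esf, 10)) - (-1000)), 15)

  ## one ray equals many rays on a noiseless axis-aligned volume
  volax <- cube_vol(0.5, tilt = c(0, 0))
  poseax <- locate_cube(volax)
  p1 <- extract_esf(volax, poseax, "+y", ray_count = 1)
  p64 <- extract_esf(volax, poseax, "+y", ray_count = 64)
  expect_lt(max(abs(p1$esf - p64$esf)) / height, 0.01)
})

test_that("MTF of a Gaussian PSF matches the closed form", {
  sig <- 0.5
  vol <- cube_vol(sig)
  pose <- locate_cube(vol)
  curve <- esf_to_mtf(extract_esf(vol, pose, "+x", ray_count = 64))
  expect_equal(curve$modulation[1], 1)
  expect_equal(curve$frequencies[1], 0)
  ## curve agrees with exp(-2 pi^2 sigma^2 f^2) within 0.02 up to f20
  fmm <- curve$frequencies / 10
  band <- curve$frequencies <= gauss_cutoff(sig, 0.2)
  expect_lt(max(abs(curve$modulation[band] -
                    exp(-2 * pi^2 * sig^2 * fmm[band]^2))), 0.02)

  ## windowing a noiseless LSF is a < 1% perturbation of f50
  pr <- extract_esf(vol, pose, "+x", ray_count = 64)
  f50a <- esf_to_mtf(pr, fwhm_mult = 4)$f50
  f50b <- esf_to_mtf(pr, fwhm_mult = 8)$f50
  expect_lt(abs(f50a - f50b) / f50a, 0.01)
})

test_that("cutoffs interpolate the first downward crossing", {
  ## synthetic analytic curve object: closed-form checks
  f <- seq(0, 12, by = 0.01)
  sig <- 0.5
  curve <- structure(list(axis = "x", frequencies = f,
                          modulation = exp(-2 * pi^2 * sig^2 * (f / 10)^2)),
                     class = "mtf_curve")
  expect_equal(mtf_cutoff(curve, 0.5), gauss_cutoff(0.5, 0.5), tolerance = 1e-4)
  expect_equal(mtf_cutoff(curve, 0.2), gauss_cutoff(0.5, 0.2), tolerance = 1e-4)
  expect_equal(gauss_cutoff(0.5, 0.5), 3.748, tolerance = 1e-3)
  expect_equal(gauss_cutoff(0.5, 0.2), 5.707, tolerance = 1e-3)
  expect_identical(mtf_cutoff(curve, 1), 0)
  shallow <- structure(list(frequencies = f[f < 1],
                            modulation = rep(1, sum(f < 1))),
                       class = "mtf_curve")
  expect_error(mtf_cutoff(shallow, 0.5), "within the sampled band")
})

test_that("in-plane averaging and axis ordering behave as expected", {
  vol <- cube_vol(0.5)
  pose <- locate_cube(vol)
  m <- inplane_and_z_mtf(vol, pose, ray_count = 49)
  ## isotropic PSF: in-plane and z cutoffs agree within 2%
  expect_lt(abs(m$in_plane$f50 - m$z$f50) / m$z$f50, 0.02)
  expect_gt(m$in_plane$f20, m$in_plane$f50)

  ## x and y curves identical implies the average equals either
  avg <- (m$x$modulation +
          approx(m$y$frequencies, m$y$modulation,
                 xout = m$x$frequencies, rule = 2)$y) / 2
  expect_equal(m$in_plane$modulation, avg, tolerance = 1e-12)

  ## anisotropic PSF (wider z) pushes the z cutoff below in-plane:
  ## separable analytic rendering, blur only differing along z
  va <- render_gaussian_cube(c(120, 120, 120), c(0.51, 0.51, 0.5),
                             sigma = 0.9, tilt = c(2, 2) * pi / 180)
  vb <- cube_vol(0.5)
  pa <- locate_cube(va)
  za <- esf_to_mtf(extract_esf(va, pa, "+z", ray_count = 49))
  ipb <- esf_to_mtf(extract_esf(vb, locate_cube(vb), "+x", ray_count = 49))
  expect_lt(za$f50, ipb$f50)
})

test_that("cutoffs are converged in the resampling pitch", {
  vol <- cube_vol(0.8)
  pose <- locate_cube(vol)
  c1 <- esf_to_mtf(extract_esf(vol, pose, "+x", ray_count = 49,
                               sample_pitch = 0.051))
  c2 <- esf_to_mtf(extract_esf(vol, pose, "+x", ray_count = 49,
                               sample_pitch = 0.0255))
  expect_lt(abs(c1$f50 - c2$f50) / c1$f50, 0.01)
  expect_lt(abs(c1$f20 - c2$f20) / c1$f20, 0.01)
})
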