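dims <- c(256L, 256L, 40L)
sp <- c(0.51, 0.51, 0.5)
full_mask <- roi_mask("uniform", seq_len(prod(dims)), dims)

test_that("in-plane NPS conserves variance and recognizes white noise", {
  wn <- correlated_noise(dims, 12, array(1, c(1, 1, 1)), seed = 41)
  cur <- nps_inplane(voxel_volume(wn, sp), full_mask, 64, 2)
  expect_gte(cur$n_patches, 4)
  expect_equal(cur$integral / cur$total_variance, 1, tolerance = 0.05)
  ## detrending removes almost nothing from white noise
  expect_equal(cur$total_variance, 144, tolerance = 0.05 * 144)
  pk <- nps_peak(cur)
  expect_true(pk$flat)
  expect_identical(pk$frequency, 0)

  ## zero-noise volume: negligible power
  z <- nps_inplane(voxel_volume(array(0, dims), sp), full_mask, 64, 2)
  expect_lt(max(z$power), 1e-12)
})

test_that("NPS shape follows the squared kernel transfer function", {
  k <- default_noise_kernel()
  cn <- correlated_noise(dims, 12, k, seed = 42)
  cur2 <- nps_inplane(voxel_volume(cn, sp), full_mask, 64, 2)
  expect_equal(cur2$integral / cur2$total_variance, 1, tolerance = 0.05)
  ## shape comparison with mean-only detrending (polynomial detrending
  ## deliberately suppresses the lowest-frequency bins)
  cur <- nps_inplane(voxel_volume(cn, sp), full_mask, 64, 0)

  ## analytic |H|^2: in-plane transfer of the (z-collapsed) kernel on the
  ## patch grid, radially binned exactly like the estimator (the FFT
  ## modulus is invariant to where the stencil sits in the padded patch)
  k2 <- apply(k, c(1, 2), sum)           # z-summed in-plane stencil
  pad <- matrix(0, 64, 64)
  pad[seq_len(nrow(k2)), seq_len(ncol(k2))] <- k2
  H2 <- Mod(fft(pad))^2
  fx <- c(0:32, -(31:1)) / (64 * sp[1])
  fr <- sqrt(outer(fx^2, fx^2, "+"))
  dfb <- 1 / (64 * sp[1])
  bins <- floor(fr / dfb)
  ref <- tapply(as.vector(H2), as.vector(bins), mean)
  keep <- 2:length(cur$power)        # drop the mean-removed DC bin
  a <- cur$power[keep]; b <- as.vector(ref)[keep]
  a <- a / mean(a); b <- b / mean(b)
  expect_lt(sqrt(mean((a - b)^2)), 0.05 * mean(b))
})

test_that("NPS amplitude is linear in the noise variance", {
  k <- default_noise_kernel()
  c1 <- nps_inplane(voxel_volume(correlated_noise(dims, 10, k, seed = 43), sp),
                    full_mask, 64, 2)
  c2 <- nps_inplane(voxel_volume(correlated_noise(dims, 10 * sqrt(2), k,
                                                  seed = 43), sp),
                    full_mask, 64, 2)
  expect_equal(c2$power / c1$power, rep(2, length(c1$power)),
               tolerance = 0.05)
})

test_that("z-direction NPS reflects axial correlation", {
  wn <- correlated_noise(dims, 12, array(1, c(1, 1, 1)), seed = 44)
  czv <- nps_z(voxel_volume(wn, sp), full_mask, 2)
  expect_equal(czv$integral / czv$total_variance, 1, tolerance = 0.05)
  ## flat away from the detrend-suppressed DC bin (mean-only detrending)
  cz <- nps_z(voxel_volume(wn, sp), full_mask, 0)
  lo <- mean(cz$power[cz$frequencies > 0 & cz$frequencies < 0.3])
  hi <- mean(cz$power[cz$frequencies > 0.7])
  expect_equal(hi / lo, 1, tolerance = 0.1)

  ## axially smoothed noise: profile proportional to |H(fz)|^2
  kz <- array(0, c(1, 1, 3)); kz[1, 1, ] <- c(0.5, 1, 0.5) / sqrt(1.5)
  sm <- correlated_noise(dims, 12, kz, seed = 45)
  cs <- nps_z(voxel_volume(sm, sp), full_mask, 0)
  hz <- numeric(dims[3]); hz[1:3] <- c(0.5, 1, 0.5) / sqrt(1.5)
  H2 <- (Mod(fft(hz))^2)[seq_along(cs$frequencies)]
  keep <- 2:length(cs$power)
  a <- cs$power[keep]; b <- H2[keep]
  a <- a / mean(a); b <- b / mean(b)
  expect_lt(sqrt(mean((a - b)^2)), 0.05 * mean(b))
  ## stronger axial smoothing lowers high-frequency content
  hi2 <- mean(cs$power[cs$frequencies > 0.7])
  expect_lt(hi2, 0.2 * lo)

  small <- roi_mask("thin", which(slice.index(array(0, dims), 3) <= 10), dims)
  expect_error(nps_z(voxel_volume(wn, sp), small, 2), "fewer than")
})

test_that("peak frequency tracks noise texture coarseness", {
  ## band-pass kernel with a known transfer maximum
  mk_band <- function(f0) {
    r <- 5
    k <- array(0, c(2 * r + 1, 2 * r + 1, 1))
    for (i in -r:r) for (j in -r:r)
      k[i + r + 1, j + r + 1, 1] <-
        cos(2 * pi * f0 * sp[1] * sqrt(i^2 + j^2)) * exp(-(i^2 + j^2) / 12)
    k - mean(k)            # zero-mean: a true band-pass stencil
  }
  analytic_peak <- function(k) {
    kk <- k[, , 1]
    pad <- matrix(0, 64, 64)
    pad[seq_len(nrow(kk)), seq_len(ncol(kk))] <- kk
    H2 <- Mod(fft(pad))^2
    fx <- c(0:32, -(31:1)) / (64 * sp[1])
    fr <- sqrt(outer(fx^2, fx^2, "+"))
    dfb <- 1 / (64 * sp[1])
    prof <- as.vector(tapply(as.vector(H2), as.vector(floor(fr / dfb)), mean))
    i <- which.max(prof)
    den <- prof[i - 1] - 2 * prof[i] + prof[i + 1]
    delta <- if (i > 1 && i < length(prof) && den != 0)
      0.5 * (prof[i - 1] - prof[i + 1]) / den else 0
    (i - 1 + 0.5 + delta) * dfb
  }
  fine <- mk_band(0.30); coarse <- mk_band(0.12)
  dfb <- 1 / (64 * sp[1])
  for (kset in list(list(k = fine, nm = "fine"), list(k = coarse, nm = "coarse"))) {
    cur <- nps_inplane(voxel_volume(correlated_noise(dims, 12, kset$k,
                                                     seed = 46), sp),
                       full_mask, 64, 0)
    pk <- nps_peak(cur)
    expect_false(pk$flat)
    expect_lt(abs(pk$frequency - analytic_peak(kset$k)), dfb + 1e-9)
    assign(paste0("peak_", kset$nm), pk$frequency, envir = environment())
  }
  expect_lt(peak_coarse, peak_fine)
})
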