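test_that("layouts contain the expected inserts per configuration", {
  iv <- build_layout("iv")
  labs <- layout_insert_labels(iv)
  expect_true(all(c("water_vial_1", "water_vial_2", "air", "mtf_cube",
                    "lung_sample_a") %in% labs))
  i <- build_layout("i")
  labs_i <- layout_insert_labels(i)
  expect_true("mtf_cube" %in% labs_i)
  expect_true(any(grepl("^nist_", labs_i)))
  expect_error(build_layout("v"), "valid options")

  ## all insert centres inside the body extent
  for (cfg in c("i", "ii", "iii", "iv")) {
    lay <- build_layout(cfg)
    for (s in lay$inserts) {
      expect_lt(abs(s$center[1]), lay$body_extent[1] / 2)
      expect_lt(abs(s$center[2]), lay$body_extent[2] / 2)
    }
  }
})

test_that("rasterization reproduces nominal HU and brute-force geometry", {
  lay <- build_layout("iv")
  sp <- c(1.5, 1.5, 2.0)
  rt <- rasterize(lay, sp, c(300L, 160L, 88L))
  v <- rt$volume$voxels

  air <- label_mask(rt$labels, "air")
  expect_true(all(v[air$indices] == -1000))
  w1 <- label_mask(rt$labels, "water_vial_1")
  expect_true(all(v[w1$indices] == 0))

  ## label voxel counts equal direct point-in-shape counts at voxel centres
  co <- lungqct:::grid_coords(dim(v), rt$volume$spacing, rt$volume$origin)
  for (lab in c("air", "water_vial_1", "nist_8")) {
    s <- Filter(function(s) s$label == lab, lay$inserts)[[1]]
    cnt <- 0L
    for (k in seq_along(co$z)) {
      if (abs(co$z[k] - s$center[3]) > s$length / 2) next
      d2 <- outer((co$x - s$center[1])^2, (co$y - s$center[2])^2, "+")
      cnt <- cnt + sum(d2 <= s$radius_or_halfedge^2)
    }
    expect_identical(length(label_mask(rt$labels, lab)$indices), cnt)
  }

  ## textured lung sample carries the configured heterogeneity
  ls <- label_mask(rt$labels, "lung_sample_a")
  expect_equal(mean(v[ls$indices]), -656, tolerance = 1e-8)
  expect_gt(sd(v[ls$indices]), 100)

  ## idempotent and seed-independent for untextured materials
  rt2 <- rasterize(lay, sp, c(300L, 160L, 88L), texture_seed = 99L)
  expect_identical(rt$labels$volume, rt2$labels$volume)
  expect_identical(v[air$indices], rt2$volume$voxels[air$indices])

  expect_error(rasterize(lay, sp, c(60L, 60L, 20L)), "grid too small")
})

test_that("simulated scans follow the blur + quantum-noise model", {
  tr <- voxel_volume(array(-1000, c(60, 60, 40)), c(1, 1, 1))
  ## zero PSF, zero noise: identity
  id <- simulate_scan(tr, acquisition_model(3, noise_sd_at_reference = 0,
                                            psf_sigma_inplane = 0,
                                            psf_sigma_z = 0))
  expect_identical(id$voxels, tr$voxels)

  ## quarter dose doubles the noise SD (within 5% at >= 1e5 voxels)
  ref <- 2.22
  a1 <- acquisition_model(ref, reference_ctdi = ref, seed = 3,
                          psf_sigma_inplane = 0, psf_sigma_z = 0)
  a4 <- acquisition_model(ref / 4, reference_ctdi = ref, seed = 4,
                          psf_sigma_inplane = 0, psf_sigma_z = 0)
  s1 <- sd(simulate_scan(tr, a1)$voxels)
  s4 <- sd(simulate_scan(tr, a4)$voxels)
  expect_gt(prod(dim(tr$voxels)), 1e5)
  expect_equal(s4 / s1, 2, tolerance = 0.05)

  ## log SD vs log dose slope -0.5 over a 16x dose range
  doses <- ref * c(1, 2, 4, 8, 16)
  sds <- vapply(seq_along(doses), function(i) {
    acq <- acquisition_model(doses[i], reference_ctdi = ref, seed = 10 + i,
                             psf_sigma_inplane = 0, psf_sigma_z = 0)
    sd(simulate_scan(tr, acq)$voxels)
  }, 0)
  slope <- coef(lm(log(sds) ~ log(doses)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.05)
  expect_true(all(diff(sds) < 0))   # higher dose, lower noise

  ## blur preserves the mean of an extended uniform region
  tr2 <- voxel_volume(array(-629, c(40, 40, 40)), c(0.51, 0.51, 0.5))
  bl <- simulate_scan(tr2, acquisition_model(3, noise_sd_at_reference = 0))
  core <- bl$voxels[10:30, 10:30, 10:30]
  expect_lt(abs(mean(core) + 629), 0.1)

  ## deterministic given the seed
  sA <- simulate_scan(tr, a1)
  sB <- simulate_scan(tr, a1)
  expect_identical(sA$voxels, sB$voxels)

  expect_error(simulate_scan(voxel_volume(array(0, c(2, 2, 2)), c(1, 1, 1)),
                             list()), "acquisition_model")
})

test_that("insert means recover nominal HU within 3 standard errors", {
  ## eroded interior of a uniform insert across seeds
  fx <- phantom_fixture("iv", seed = 1)
  masks <- segment_inserts(fx$scan, fx$layout, margin = 2)
  nominal <- c(air = -1000, water_vial_1 = 0, nist_8 = -883)
  ## the mean of N correlated-noise voxels has SE inflated by the kernel
  ## coherent gain (sum of weights; the kernel has unit sum of squares)
  gain <- sum(default_noise_kernel())
  for (lab in names(nominal)) {
    for (sd_ in 1:6) {
      acq <- acquisition_model(2.22, seed = 100 + sd_)
      sc <- simulate_scan(fx$truth, acq)
      v <- sc$voxels[masks[[lab]]$indices]
      se <- gain * sd(v) / sqrt(length(v))
      expect_lt(abs(mean(v) - nominal[lab]), 3 * se + 0.5)
    }
  }
})
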