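test_that("gaussian blur conserves total activity to 1e-6 relative", {
  for (g in list(default_truth(8), single_sphere_recon(40))) {
    # single_sphere_recon is already blurred once; blur again with another width
    b <- apply_psf(g, psf_model(7.5))
    expect_lt(abs(total_activity(b) - total_activity(g)) / total_activity(g),
              1e-6)
    expect_true(all(b$values >= 0))
  }
})

test_that("a blurred point source has the nominal FWHM", {
  n <- c(41, 41, 41)
  a <- array(0, n)
  a[21, 21, 21] <- 1
  pg <- voxel_grid(a, spacing = 2)
  fwhm_nominal <- 9
  pb <- apply_psf(pg, psf_model(fwhm_nominal))
  prof <- pb$values[, 21, 21]
  x <- (seq_len(41) - 21) * 2
  half <- max(prof) / 2
  # interpolated half-maximum crossings on both sides of the peak
  right <- which(prof < half & x > 0)[1]
  xr <- x[right - 1] + (half - prof[right - 1]) /
    (prof[right] - prof[right - 1]) * 2
  measured <- 2 * xr
  expect_lt(abs(measured - fwhm_nominal), 1) # within half a voxel
})

test_that("activity too close to the array boundary is an error", {
  a <- array(0, c(12, 12, 12))
  a[2, 6, 6] <- 1
  expect_error(apply_psf(voxel_grid(a, 3.2), psf_model(12)), "conservation")
})

test_that("blur of the 60 mm sphere keeps ~80% inside the true boundary", {
  recon <- single_sphere_recon(60)
  spec <- single_sphere_spec(60)
  s <- spec$spheres[[1]]
  m <- sphere_mask(recon, voi_sphere(s$center, 60))
  frac <- measure_voi(recon, m)$activity_bq / true_activity(s)
  expect_gt(frac, 0.78)
  expect_lt(frac, 0.82)
  # continuum oracle for the same quantity (field integral): 0.7987
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  expect_equal(oracle_activity_within(30, 30, sigma) / (4 / 3 * pi * 30^3),
               0.7987, tolerance = 1e-3)
})

test_that("successive blurs compose like a single wider gaussian", {
  g <- voxelize(single_sphere_spec(30, margin_mm = 50))
  b12 <- apply_psf(apply_psf(g, psf_model(8)), psf_model(9))
  b_comb <- apply_psf(g, psf_model(sqrt(8^2 + 9^2)))
  expect_lt(max(abs(b12$values - b_comb$values)) / max(b_comb$values), 1e-4)
})

test_that("counts conversion follows c*v*s*t and round-trips exactly", {
  a <- array(5, c(4, 4, 4))
  g <- voxel_grid(a, spacing = 2) # voxel volume 0.008 ml
  cal <- calibration_factor(3, 7)
  cg <- to_counts(g, cal)
  expect_equal(cg$values[1], 5 * 0.008 * 3 * 7)
  expect_equal(cg$units, "counts")
  back <- to_activity(cg, cal)
  expect_lt(max(abs(back$values - g$values)) / max(g$values), 1e-12)
  expect_error(calibration_factor(-1), "sensitivity")
  expect_error(to_counts(cg, cal), "concentration")
})

test_that("sensitivity measurement inverts the simulation", {
  g <- voxel_grid(array(1000, c(10, 10, 10)), spacing = 3.2)
  cal <- calibration_factor(4.2, 30)
  cg <- to_counts(g, cal)
  known <- total_activity(g)
  rec <- measure_sensitivity(cg, known, 30)
  expect_equal(rec$sensitivity_cps_per_bq, 4.2, tolerance = 1e-12)
  # with Poisson noise at >= 1e6 total counts: within 0.5% (sampling error)
  noisy <- add_poisson_noise(cg, seed = 11)
  expect_gt(sum(noisy$values), 1e6)
  rec_n <- measure_sensitivity(noisy, known, 30)
  expect_equal(rec_n$sensitivity_cps_per_bq, 4.2, tolerance = 5e-3)
  zero <- voxel_grid(array(0, c(3, 3, 3)), 1, units = "counts")
  expect_error(measure_sensitivity(zero, known, 30), "counts")
})

test_that("poisson noise is seed-deterministic, unbiased, and zero-preserving", {
  lam <- array(1000, c(4, 4, 4))
  lam[1, , ] <- 0
  cg <- voxel_grid(lam, 3.2, units = "counts")
  d1 <- add_poisson_noise(cg, seed = 42)
  d2 <- add_poisson_noise(cg, seed = 42)
  expect_identical(d1$values, d2$values)
  expect_true(all(d1$values[1, , ] == 0))
  expect_false(identical(d1$values, add_poisson_noise(cg, seed = 43)$values))
  means <- vapply(1:100, function(sd)
    mean(add_poisson_noise(cg, sd)$values[-1, , ]), 1)
  expect_equal(mean(means), 1000, tolerance = 0.01)
  # caller's RNG stream is untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(add_poisson_noise(cg, seed = 7)); x2 <- runif(1)
  expect_identical(x1, x2)
  neg <- voxel_grid(array(-1, c(2, 2, 2)), 1, units = "counts")
  expect_error(add_poisson_noise(neg, seed = 1), ">= 0")
})

test_that("edge enhancement is zero-net-sum and off at zero overshoot", {
  recon <- single_sphere_recon(40)
  expect_identical(apply_edge_enhancement(recon, 0), recon)
  art <- apply_edge_enhancement(recon, 0.3, ring_width_mm = 6)
  expect_lt(abs(total_activity(art) - total_activity(recon)) /
              total_activity(recon), 1e-6)
  expect_false(identical(art$values, recon$values))
  # ringing produces signed voxels; they are retained, not clipped
  expect_true(any(art$values < 0))
})

test_that("calibration bias scales the image exactly", {
  recon <- single_sphere_recon(40)
  b <- apply_calibration_bias(recon, 1.05)
  expect_equal(b$values, recon$values * 1.05)
  expect_error(apply_calibration_bias(recon, 0), "bias")
})
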