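test_that("the correction equation is A + A_SP - V_SP * B_mean", {
  expect_equal(activity_correct(100, 20, 10, 0.5), 115)
  expect_equal(activity_correct(80, 15, 33, 0), 95) # zero-background limit
  expect_equal(activity_correct(0, 0, 40, 2), -80)  # pure background, negative
  expect_error(activity_correct(NA, 0, 0, 0), "finite")
  expect_error(activity_correct(1, 1, -1, 1), "V_SP")
})

test_that("a pure-background VOI yields a flagged negative estimate", {
  g0 <- default_truth(0)
  # field present only in the background ring: A and A_SP vanish, the
  # correction subtracts V_SP * B_mean and the result must carry a flag
  ctr <- c(0, 60, -25)
  outer3 <- sphere_mask(g0, voi_sphere(ctr, 70))
  outer2 <- sphere_mask(g0, voi_sphere(ctr, 60))
  ringw <- outer3$weights - outer2$weights
  g <- voxel_grid(pmax(ringw, 0) * 500, g0$spacing, g0$origin)
  q <- quantify_sphere(g, voi_sphere(ctr, 40), 20, 10)
  expect_lt(q$A_corr, 0)
  expect_true("negative_A_corr" %in% q$flags)
})

test_that("uniform background with blur off is quantified exactly", {
  for (ratio in c(4, 2)) {
    spec <- single_sphere_spec(30, background_ratio = ratio)
    truth <- voxelize(spec)
    s <- spec$spheres[[1]]
    q <- quantify_sphere(truth, voi_sphere(s$center, 30), 20, 10,
                         true_activity(s))
    expect_equal(q$TF, 1, tolerance = 1e-2,
                 label = sprintf("no-blur TF at ratio %g:1", ratio))
    expect_equal(q$B_mean, spec$background_concentration_bq_ml,
                 tolerance = 1e-9) # ring samples pure background exactly
  }
})

test_that("blurred spheres are recovered within the published band", {
  # 40 mm sphere, fwhm 12 mm, zero background, 20 mm diameter expansion
  recon <- default_recon(0)
  spec <- iec_phantom_spec(0)
  s40 <- spec$spheres[[4]]
  q <- quantify_sphere(recon, voi_sphere(s40$center, 40), 20, 10,
                       true_activity(s40))
  expect_gt(q$TF, 0.97)
  expect_lt(q$TF, 1.01)
  # stored fields recompose: A_corr == A + A_SP - V_SP * B_mean exactly
  expect_equal(q$A_corr, q$A + q$A_SP - q$V_SP * q$B_mean, tolerance = 1e-12)
})

test_that("recovery coefficients grow with sphere size toward the oracle", {
  recon <- default_recon(0)
  spec <- iec_phantom_spec(0)
  sigma <- 12 / (2 * sqrt(2 * log(2)))
  rc <- vapply(spec$spheres, function(s)
    recovery_coefficient(recon, voi_sphere(s$center, s$diameter_mm),
                         true_activity(s)), 1)
  expect_true(all(diff(rc) > 0))
  # 60 mm sphere: ~20% spill-out
  expect_gt(rc[6], 0.78)
  expect_lt(rc[6], 0.82)
  # continuum oracle ordering agrees
  oracle <- vapply(c(10, 20, 30, 40, 50, 60), function(d)
    oracle_activity_within(d / 2, d / 2, sigma) / (pi / 6 * (d / 2)^3 * 8), 1)
  expect_true(all(diff(oracle) > 0))
  # discrete RCs track the continuum values (fractional-mask quadrature at
  # 3.2 mm voxels sits a little low, most visibly for the smallest sphere)
  expect_equal(rc[-1], oracle[-1], tolerance = 0.05)
})

test_that("scaling all concentrations scales A_corr and leaves TF unchanged", {
  k <- 3.7
  s1 <- single_sphere_spec(30, concentration = 100000, background_ratio = 8,
                           body_size_mm = 60)
  s2 <- single_sphere_spec(30, concentration = 100000 * k, background_ratio = 8,
                           body_size_mm = 60)
  q1 <- quantify_sphere(apply_psf(voxelize(s1), psf_model(12)),
                        voi_sphere(c(0.4, -0.9, 1.3), 30), 20, 10,
                        true_activity(s1$spheres[[1]]))
  q2 <- quantify_sphere(apply_psf(voxelize(s2), psf_model(12)),
                        voi_sphere(c(0.4, -0.9, 1.3), 30), 20, 10,
                        true_activity(s2$spheres[[1]]))
  expect_equal(q2$A_corr, k * q1$A_corr, tolerance = 1e-10)
  expect_equal(q2$TF, q1$TF, tolerance = 1e-10)
})

test_that("mask-based A_corr equals brute-force triple-loop summation", {
  # small 32^3 grid with a smooth field: the vectorized measurement must
  # agree with direct elementwise summation to 1e-10 relative
  spec <- single_sphere_spec(24, background_ratio = 6, margin_mm = 34,
                             body_size_mm = 50)
  stopifnot(all(spec$grid_shape <= 32))
  recon <- apply_psf(voxelize(spec), psf_model(10))
  ctr <- c(0.4, -0.9, 1.3)
  q <- quantify_sphere(recon, voi_sphere(ctr, 24), 14, 10)

  m1 <- sphere_mask(recon, voi_sphere(ctr, 24))
  m2 <- sphere_mask(recon, voi_sphere(ctr, 38))
  m3 <- sphere_mask(recon, voi_sphere(ctr, 48))
  vv <- voxel_volume_ml(recon)
  n <- dim(recon$values)
  A <- ASP <- VSP <- B_num <- B_vol <- 0
  for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3])) {
    v <- recon$values[i, j, k]
    w1 <- m1$weights[i, j, k]
    w2 <- m2$weights[i, j, k] - w1
    w3 <- m3$weights[i, j, k] - m2$weights[i, j, k]
    A <- A + w1 * v * vv
    ASP <- ASP + w2 * v * vv
    VSP <- VSP + w2 * vv
    B_num <- B_num + w3 * v * vv
    B_vol <- B_vol + w3 * vv
  }
  A_corr_loop <- A + ASP - VSP * (B_num / B_vol)
  expect_equal(q$A, A, tolerance = 1e-10)
  expect_equal(q$A_SP, ASP, tolerance = 1e-10)
  expect_equal(q$V_SP, VSP, tolerance = 1e-10)
  expect_equal(q$A_corr, A_corr_loop, tolerance = 1e-10)
})

test_that("whole-phantom quantification yields one row per sphere", {
  tab <- quantify_phantom(default_recon(0), iec_phantom_spec(0))
  expect_s3_class(tab, "data.frame")
  expect_equal(nrow(tab), 6)
  expect_equal(tab$diameter_mm, c(10, 20, 30, 40, 50, 60))
  expect_true(all(is.finite(tab$TF)))
  expect_equal(tab$A_corr, tab$A + tab$A_SP - tab$V_SP * tab$B_mean,
               tolerance = 1e-12)
})
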