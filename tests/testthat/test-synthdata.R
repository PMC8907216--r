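test_that("calibration scans are symmetric at focus midpoint and reproducible", {
  om <- optical_model()
  scan <- simulate_calibration_scan(om, noise = "none")
  mid <- scan[scan$z_stage == 0, ]
  expect_equal(mid$I1, mid$I2)

  s1 <- simulate_calibration_scan(om, noise = "poisson", seed = 33)
  s2 <- simulate_calibration_scan(om, noise = "poisson", seed = 33)
  expect_identical(s1, s2)
  s3 <- simulate_calibration_scan(om, noise = "poisson", seed = 34)
  expect_false(identical(s1$I1, s3$I1))
})

test_that("Poisson contrast noise matches the delta-method estimate", {
  om <- optical_model() # 2000 mean photons
  set.seed(35)
  scan <- simulate_calibration_scan(om, z_range = c(-1, 1), z_step = 2,
                                    n_per_step = 4000, noise = "poisson")
  g <- compute_gamma(scan$I1, scan$I2)
  # var(gamma) ~ 4 p (1-p) / N with p = 1/2 at z = 0
  expect_equal(sd(g), sqrt(1 / om$photons), tolerance = 0.2)
})

test_that("membrane simulation produces the requested axial structure", {
  om <- optical_model()
  tips <- simulate_membrane_locs(surface_model(fraction_on_tips = 1),
                                 om, n_frames = 400, seed = 36)
  expect_true(all(tips$truth$on_tip))
  expect_equal(mean(tips$truth$z), 150, tolerance = 0.05)
  expect_equal(sd(tips$truth$z), 25, tolerance = 0.15)

  mixed <- simulate_membrane_locs(surface_model(fraction_on_tips = 0.5),
                                  om, n_frames = 400, seed = 37)
  ztr <- mixed$truth$z
  expect_gt(mean(ztr > 75), 0.3) # both levels populated
  expect_lt(mean(ztr > 75), 0.7)

  # both channel tables carry one record per appearance
  expect_equal(nrow(tips$transmitted), nrow(tips$truth))
  expect_equal(nrow(tips$reflected), nrow(tips$truth))
  expect_identical(tips$transmitted$frame, tips$truth$frame)
})

test_that("noiseless end-to-end simulation inverts to true z within 2 nm", {
  om <- optical_model()
  lut <- default_lut()
  sim <- simulate_membrane_locs(surface_model(fraction_on_tips = 0.5),
                                om, n_frames = 500, sigma_xy = 0,
                                noise = "none", seed = 38)
  pairs <- pair_localizations(sim$transmitted, sim$reflected)
  zp <- assign_z(pairs, lut, quiet = TRUE)
  # with zero lateral noise, appearance order is preserved within frames,
  # so join on (frame, x) recovers the ground truth record
  m <- dplyr::inner_join(zp, sim$truth, by = c("frame", "x"))
  expect_gt(nrow(m), 0.9 * nrow(sim$truth))
  expect_lt(median(abs(m$z_raw - m$z_effective)), 2)
})

test_that("frame rendering conserves photons and closes the loop with spotfit", {
  locs <- tibble::tibble(x = c(900, 2300), y = c(1200, 700), frame = 0L,
                         intensity = c(1500, 2500))
  st <- simulate_frames(locs, 1, 31, 100)
  expect_equal(sum(st), 4000, tolerance = 1e-6)

  s1 <- simulate_frames(locs, 1, 31, 100, noise = "poisson", seed = 39)
  s2 <- simulate_frames(locs, 1, 31, 100, noise = "poisson", seed = 39)
  expect_identical(s1, s2)

  out <- localize_stack(st, 100, min_photons = 500)
  out <- out[order(out$x), ]
  expect_equal(nrow(out), 2)
  expect_equal(out$intensity, locs$intensity, tolerance = 0.05)
  expect_equal(out$x, locs$x, tolerance = 2)
})
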