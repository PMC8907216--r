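static_membrane <- function(n = 20000, n_frames = 10000, sd_z = 10, seed = 1) {
  set.seed(seed)
  tibble::tibble(frame = sample(0:(n_frames - 1), n, replace = TRUE),
                 x = runif(n, 0, 10000), y = runif(n, 0, 10000),
                 z = rnorm(n, 0, sd_z))
}

test_that("drift trace is flat for a static membrane and tracks injected drift", {
  locs <- static_membrane()
  tr <- axial_drift_trace(locs)
  sem <- 10 / sqrt(min(tr$n)) * sqrt(pi / 2) # SEM of a median, worst window
  expect_lt(max(abs(tr$z_med)), 3 * sem)

  # linear drift 0.02 nm/frame over 50k frames
  locs2 <- static_membrane(50000, 50000, seed = 2)
  locs2$z <- locs2$z + 0.02 * locs2$frame
  tr2 <- axial_drift_trace(locs2)
  slope <- coef(lm(z_med ~ frame, data = tr2))[[2]]
  expect_equal(slope, 0.02, tolerance = 0.1)

  expect_error(axial_drift_trace(locs[locs$frame < 500, ]), "windows")
})

test_that("polynomial drift correction removes injected cubic drift", {
  n_fr <- 50000
  locs <- static_membrane(100000, n_fr, seed = 3)
  locs$z <- locs$z + 100 * (locs$frame / n_fr)^3
  corr <- correct_axial_drift(locs)
  tr <- axial_drift_trace(corr)
  expect_lt(max(abs(tr$z_med - median(tr$z_med))), 5)
  expect_equal(nrow(corr), nrow(locs))
  expect_identical(corr$x, locs$x)

  # near-zero drift leaves the data essentially untouched
  flat <- static_membrane(seed = 4)
  cflat <- correct_axial_drift(flat)
  expect_lt(max(abs(cflat$z - flat$z)), 3)

  # applying the correction twice: the second model is near-constant
  corr2 <- correct_axial_drift(corr)
  m2 <- attr(corr2, "drift_model")
  fr <- seq(0, n_fr, by = 500)
  expect_lt(diff(range(nanotopo:::predict_drift(m2, fr))), 3)

  expect_error(correct_axial_drift(static_membrane(2000, 3000), poly_order = 6),
               "order")
})

test_that("tilt plane is estimated from the rendered image and removed", {
  locs <- static_membrane(seed = 5)
  tm0 <- fit_tilt_plane(locs)
  expect_lt(abs(tm0$a), 1e-4)
  expect_lt(abs(tm0$b), 1e-4)

  tilted <- locs
  tilted$z <- tilted$z + 0.01 * tilted$x # 10 nm/um
  tm <- fit_tilt_plane(tilted)
  expect_equal(tm$a, 0.01, tolerance = 0.05)

  corr <- correct_tilt(tilted, tm)
  tm2 <- fit_tilt_plane(corr)
  expect_lt(abs(tm2$a), 1e-4)
  expect_lt(abs(tm2$b), 1e-4)
  expect_identical(corr$x, tilted$x)
  expect_identical(corr$y, tilted$y)
  expect_equal(mean(corr$z), mean(tilted$z))
  expect_equal(nrow(corr), nrow(tilted))

  # zero plane -> identity
  zero <- structure(list(a = 0, b = 0, c = 0, n_pixels = 99, pixel_size = 100),
                    class = "tilt_model")
  expect_equal(correct_tilt(locs, zero)$z, locs$z)

  # collinear occupied pixels cannot define a plane
  line <- tibble::tibble(x = 50, y = seq(50, 5000, by = 100),
                         z = rnorm(50), frame = 0L)
  expect_error(fit_tilt_plane(line), "collinear")
})

test_that("drift and tilt corrections commute within tolerance", {
  n_fr <- 20000
  locs <- static_membrane(60000, n_fr, seed = 6)
  locs$z <- locs$z + 80 * (locs$frame / n_fr)^3 + 0.008 * locs$x
  a <- correct_tilt(correct_axial_drift(locs))
  b <- correct_axial_drift(correct_tilt(locs, fit_tilt_plane(locs)))
  expect_lt(median(abs(a$z - b$z)), 3)
})

test_that("track-based precision: forced two-point arithmetic and thresholds", {
  # two localizations 80 nm apart in consecutive frames are never linked
  apart <- tibble::tibble(x = c(0, 80), y = 0, z = 0, frame = 0:1)
  expect_error(estimate_localization_precision(apart), "track")

  # single 2-frame track with z = {0, 10}: deviations +/-5, pooled sd 5
  two <- tibble::tibble(x = c(0, 0), y = 0, z = c(0, 10), frame = 0:1)
  pr <- estimate_localization_precision(two)
  expect_equal(pr$sigma_z, 5)
  expect_equal(pr$n_tracks, 1)
  expect_equal(pr$sigma_x, 0)
})

test_that("precision recovery matches the track-length-limited expectation", {
  # Blinking emitters, 5-frame on-times, isotropic noise. The 75 nm
  # cumulative budget truncates tracks; with no per-track bias correction
  # the pooled RMS deviation is sigma * sqrt(1 - 1/n) for track length n,
  # so recovery is compared against that expectation, not raw sigma.
  for (sigma in c(5, 10)) {
    set.seed(100 + sigma)
    n_em <- 400
    em <- tibble::tibble(x = runif(n_em, 0, 5e4), y = runif(n_em, 0, 5e4),
                         z = runif(n_em, 0, 50),
                         start = sample(0:2000, n_em, TRUE))
    app <- em[rep(seq_len(n_em), each = 5), ]
    app$frame <- app$start + rep(0:4, n_em)
    n <- nrow(app)
    app$x <- app$x + rnorm(n, 0, sigma)
    app$y <- app$y + rnorm(n, 0, sigma)
    app$z <- app$z + rnorm(n, 0, sigma)
    pr <- estimate_localization_precision(app)
    expect_gt(pr$n_tracks, 200)
    # mean 3D jump is sigma * sqrt(2) * E[chi_3]; cap track length by budget
    jump <- sigma * sqrt(2) * 1.5958
    n_eff <- min(5, 1 + floor(75 / jump))
    expected <- sigma * sqrt(1 - 1 / n_eff)
    for (s in c(pr$sigma_x, pr$sigma_y, pr$sigma_z)) {
      expect_equal(s, expected, tolerance = 0.15)
    }
  }
})
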