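test_that("z-stack rendering conserves counts and uses half-open bins", {
  one <- tibble::tibble(x = 35, y = 55, z = 12)
  zs <- render_zstack(one)
  expect_equal(sum(zs$counts), 1)
  expect_equal(max(zs$counts), 1)

  set.seed(11)
  locs <- tibble::tibble(x = runif(5000, 0, 4000), y = runif(5000, 0, 4000),
                         z = rnorm(5000, 100, 60))
  zs <- render_zstack(locs)
  expect_equal(sum(zs$counts), 5000)

  # a coordinate exactly on a bin edge belongs to the upper bin
  edge <- tibble::tibble(x = c(10, 40), y = 10, z = c(19.999, 20))
  zs <- render_zstack(edge)
  expect_equal(dim(zs$counts)[3], 2) # two z slices: [0,20) and [20,40)

  expect_error(render_zstack(locs[0, ]), "empty")
})

test_that("color-coded rendering separates two axial levels", {
  flat <- tibble::tibble(x = runif(2000, 0, 2000), y = runif(2000, 0, 2000),
                         z = 100)
  img <- render_colorcoded(flat)
  expect_true(all(img$z_mean == 100))

  two <- tibble::tibble(x = c(runif(1000, 0, 900), runif(1000, 1100, 2000)),
                        y = runif(2000, 0, 2000),
                        z = rep(c(0, 150), each = 1000))
  img2 <- render_colorcoded(two)
  expect_true(all(abs(img2$z_mean) < 1 | abs(img2$z_mean - 150) < 1))
})

test_that("ROI tiling keeps squares by mask coverage and clips to the mask", {
  # full 10 x 10 um mask at 20 nm pixels -> 5 x 5 grid of 2 um ROIs
  mask <- matrix(TRUE, 500, 500)
  attr(mask, "pixel_size") <- 20
  rois <- tile_rois(mask)
  expect_equal(nrow(rois), 25)
  expect_true(all(rois$fraction == 1))

  # carving 20% out of one candidate keeps it; 30% drops it
  m2 <- mask; m2[1:100, 1:20] <- FALSE # 20% of ROI (1,1)
  r2 <- tile_rois(m2)
  expect_equal(nrow(r2), 25)
  expect_equal(min(r2$fraction), 0.8)
  expect_equal(nrow(r2$pixels[[which.min(r2$fraction)]]), 8000)

  m3 <- mask; m3[1:100, 1:30] <- FALSE # 30%
  expect_equal(nrow(tile_rois(m3)), 24)

  expect_error(tile_rois(matrix(FALSE, 10, 10)), "empty")
})

test_that("axial profiles conserve and partition localization counts", {
  set.seed(12)
  locs <- tibble::tibble(x = runif(8000, 0, 4000), y = runif(8000, 0, 4000),
                         z = rnorm(8000, 150, 50))
  zs <- render_zstack(locs)
  whole <- axial_profile(zs)
  expect_equal(sum(whole$count), 8000)

  # one z only -> single occupied bin
  mono <- render_zstack(tibble::tibble(x = runif(50, 0, 1000),
                                       y = runif(50, 0, 1000), z = 30))
  expect_equal(sum(axial_profile(mono)$count > 0), 1)

  # disjoint ROIs partition additively
  p1 <- axial_profile(zs, list(x0 = 0, y0 = 0), roi_side = 2000)
  p2 <- axial_profile(zs, list(x0 = 2000, y0 = 0), roi_side = 2000)
  p12 <- axial_profile(zs, list(x0 = 0, y0 = 0), roi_side = 4000)
  both <- p1$count + p2$count +
    axial_profile(zs, list(x0 = 0, y0 = 2000), roi_side = 2000)$count +
    axial_profile(zs, list(x0 = 2000, y0 = 2000), roi_side = 2000)$count
  expect_equal(both, p12$count)
})

test_that("bi-Gaussian fits recover known parameters", {
  z <- seq(-200, 600, by = 20)
  truth <- c(a1 = 100, m1 = 100, s1 = 20, a2 = 40, m2 = 250, s2 = 60)
  y <- truth["a1"] * exp(-0.5 * ((z - truth["m1"]) / truth["s1"])^2) +
    truth["a2"] * exp(-0.5 * ((z - truth["m2"]) / truth["s2"])^2)
  fit <- fit_bigaussian(tibble::tibble(z = z, count = y))
  got <- unlist(fit[c("a1", "m1", "s1", "a2", "m2", "s2")])
  expect_equal(got, truth, tolerance = 0.02)

  # Poisson counting noise at >= 1000 localizations: within 10%
  set.seed(13)
  fitn <- fit_bigaussian(tibble::tibble(z = z, count = rpois(length(z), y)))
  gotn <- unlist(fitn[c("m1", "s1", "m2", "s2")])
  expect_equal(gotn, truth[c("m1", "s1", "m2", "s2")], tolerance = 0.10)

  # effectively mono-Gaussian input collapses to one component
  y1 <- 100 * exp(-0.5 * ((z - 150) / 40)^2)
  f1 <- fit_bigaussian(tibble::tibble(z = z, count = y1))
  expect_equal(compute_axial_params(f1)$z_w, 2.355 * 40, tolerance = 0.05)

  expect_error(fit_bigaussian(tibble::tibble(z = z, count = 0)), "nonzero")
})

test_that("axial parameters follow the width/peak formulas and invariants", {
  p <- compute_axial_params(data.frame(m1 = 100, s1 = 20, m2 = 180, s2 = 30))
  expect_equal(p$z_w, 138.875)
  expect_equal(p$p_p, 80)
  expect_equal(p$delta_fwhm, 23.55)

  d <- compute_axial_params(data.frame(m1 = 50, s1 = 10, m2 = 50, s2 = 10))
  expect_equal(d$z_w, 23.55)
  expect_equal(d$p_p, 0)
  expect_equal(d$delta_fwhm, 0)

  # homogeneity: doubling m and s doubles all parameters
  p2 <- compute_axial_params(data.frame(m1 = 200, s1 = 40, m2 = 360, s2 = 60))
  expect_equal(unlist(p2), 2 * unlist(p), ignore_attr = TRUE)

  # invariants over randomized parameter sets (including swapped labels)
  set.seed(14)
  rand <- data.frame(m1 = runif(200, -200, 400), s1 = runif(200, 10, 120),
                     m2 = runif(200, -200, 400), s2 = runif(200, 10, 120))
  rp <- compute_axial_params(rand)
  fw <- 2.355 * cbind(rand$s1, rand$s2)
  expect_true(all(rp$z_w >= rp$p_p - 1e-9))
  expect_true(all(rp$z_w >= (fw[, 1] + fw[, 2]) / 2 - 1e-9))
  expect_true(all(rp$p_p >= 0 & rp$delta_fwhm >= 0))
})

test_that("population fits report mu, sigma, tau and rounded ranges", {
  set.seed(15)
  vals <- rnorm(3000, 120, 25)
  pf <- fit_population(vals, "mono_gaussian")
  expect_equal(pf$mu, 120, tolerance = 0.03)
  expect_equal(pf$sigma, 25, tolerance = 0.10)
  expect_equal(pf$lower, round(pf$mu - 2.355 * pf$sigma / 2))
  expect_s3_class(autoplot(pf), "ggplot")

  vexp <- rexp(4000, rate = 1 / 40)
  pe <- fit_population(vexp, "exponential")
  expect_equal(pe$tau, 40, tolerance = 0.15)

  vbi <- c(rnorm(2000, 140, 27), rnorm(700, 250, 80))
  pb <- fit_population(vbi, "bi_gaussian")
  expect_equal(nrow(pb), 2)
  expect_equal(pb$mu, c(140, 250), tolerance = 0.1)

  expect_error(fit_population(rnorm(10), "mono_gaussian"), "30")
})

test_that("population range arithmetic matches hand-computed values", {
  expect_equal(population_range(247, 83), tibble::tibble(lower = 149, upper = 345))
  expect_equal(population_range(63, 22), tibble::tibble(lower = 37, upper = 89))
  expect_equal(population_range(100, 0), tibble::tibble(lower = 100, upper = 100))
})
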