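make_cloud <- function(n, seed = 1) {
  set.seed(seed)
  tibble::tibble(x = runif(n, 0, 2e4), y = runif(n, 0, 2e4),
                 frame = sample(0:199, n, TRUE),
                 intensity = runif(n, 800, 3000))
}

test_that("channel transform recovers a pure translation within 1 nm", {
  t1 <- make_cloud(400)
  t2 <- t1
  t2$x <- t2$x + 100; t2$y <- t2$y - 50
  tr <- estimate_channel_transform(t1, t2)
  expect_equal(tr$t[1], -100, tolerance = 1)
  expect_equal(tr$t[2], 50, tolerance = 1)
  expect_equal(tr$scale, 1, tolerance = 1e-4)
  expect_lt(tr$rms, 1e-6)

  mapped <- apply_channel_transform(tr, t2)
  expect_equal(mapped$x, t1$x, tolerance = 1e-6)

  ident <- estimate_channel_transform(t1, t1)
  expect_equal(ident$t, c(0, 0), tolerance = 1e-9)
  expect_equal(unclass(ident$A), diag(2), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("channel transform recovers rotation + scale and flags disjoint sets", {
  t1 <- make_cloud(500, seed = 2)
  th <- 0.01; s <- 1.002
  R <- s * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xy <- cbind(t1$x, t1$y) %*% t(R)
  t2 <- t1; t2$x <- xy[, 1] + 300; t2$y <- xy[, 2] - 120
  tr <- estimate_channel_transform(t1, t2)
  back <- apply_channel_transform(tr, t2)
  expect_lt(sqrt(mean((back$x - t1$x)^2 + (back$y - t1$y)^2)), 0.1)
  expect_equal(tr$scale, 1 / s, tolerance = 1e-3)

  far <- make_cloud(50, seed = 3)
  far$frame <- far$frame + 1000 # no shared frames -> no control pairs
  expect_error(estimate_channel_transform(t1, far), "alignment failure")
})

test_that("framewise pairing respects the distance threshold", {
  t1 <- tibble::tibble(x = 0, y = 0, frame = 0L, intensity = 1000)
  near <- tibble::tibble(x = 100, y = 0, frame = 0L, intensity = 1200)
  expect_equal(nrow(pair_localizations(t1, near)), 1)
  far <- tibble::tibble(x = 600, y = 0, frame = 0L, intensity = 1200)
  p <- pair_localizations(t1, far)
  expect_equal(nrow(p), 0)
  expect_equal(attr(p, "n_unpaired_transmitted"), 1)
})

test_that("greedy ascending-distance matching picks the short pairs", {
  # distances t1 x t2: {50, 310} for record 1 and {300, 60} for record 2:
  # ascending order takes (1,1)=50 then (2,2)=60, never the long crossings
  t1 <- tibble::tibble(x = c(0, 1000), y = 0, frame = 0L, intensity = c(1000, 2000))
  t2 <- tibble::tibble(x = c(50, 1060), y = 0, frame = 0L, intensity = c(500, 700))
  p <- pair_localizations(t1, t2)
  expect_equal(nrow(p), 2)
  expect_equal(sort(p$pair_dist), c(50, 60))
  expect_equal(p$I2[order(p$x)], c(500, 700))

  # agreement with an independent brute-force greedy oracle on random sets
  set.seed(9)
  for (rep in 1:5) {
    a <- matrix(runif(24, 0, 1500), ncol = 2)
    b <- matrix(runif(20, 0, 1500), ncol = 2)
    ta <- tibble::tibble(x = a[, 1], y = a[, 2], frame = 0L, intensity = 1)
    tb <- tibble::tibble(x = b[, 1], y = b[, 2], frame = 0L, intensity = 1)
    p <- pair_localizations(ta, tb, max_dist = 400)
    oracle <- greedy_pairs_bruteforce(a, b, 400)
    expect_equal(nrow(p), NROW(oracle))
    if (NROW(oracle) > 0) {
      expect_setequal(round(p$x, 9), round(a[oracle[, 1], 1], 9))
    }
  }
})

test_that("pairing is one-to-one and symmetric under channel exchange", {
  set.seed(10)
  t1 <- make_cloud(300, seed = 10)
  t2 <- make_cloud(280, seed = 11)
  p12 <- pair_localizations(t1, t2)
  # injectivity: no transmitted (x, frame) or reflected intensity reused
  expect_equal(anyDuplicated(p12[c("frame", "x", "y")]), 0)
  p21 <- pair_localizations(t2, t1)
  expect_equal(nrow(p12), nrow(p21))
  expect_setequal(round(p12$pair_dist, 9), round(p21$pair_dist, 9))
})

test_that("z assignment interpolates the LUT and drops out-of-range contrasts", {
  lut <- default_lut()
  # exactly at a node
  k <- 150
  p <- assign_z(tibble::tibble(gamma = lut$gamma_nodes[k]), lut, quiet = TRUE)
  expect_equal(p$z_raw, lut$z_nodes[k])
  # midway between nodes -> midway z (nodes are 1 nm apart)
  gmid <- (lut$gamma_nodes[k] + lut$gamma_nodes[k + 1]) / 2
  p <- assign_z(tibble::tibble(gamma = gmid), lut, quiet = TRUE)
  expect_equal(p$z_raw, (lut$z_nodes[k] + lut$z_nodes[k + 1]) / 2, tolerance = 1e-6)
  # inversion of the forward model at an arbitrary depth
  p <- assign_z(tibble::tibble(gamma = gamma_oracle(137)), lut, quiet = TRUE)
  expect_equal(p$z_raw, 137, tolerance = 2)
  # out-of-range contrast dropped and counted
  p <- assign_z(tibble::tibble(gamma = c(0, 0.999)), lut, quiet = TRUE)
  expect_equal(nrow(p), 1)
  expect_equal(attr(p, "n_out_of_range"), 1)
})

test_that("refractive-index correction rescales z only, preserving order", {
  p <- tibble::tibble(x = 1:5, y = 5:1, z_raw = c(-50, 0, 30, 100, 200))
  out <- correct_refractive_index(p, 0.8)
  expect_equal(out$z, 0.8 * p$z_raw)
  expect_equal(out$x, p$x)
  expect_equal(correct_refractive_index(p, 1.0)$z, p$z_raw)
  expect_equal(order(out$z), order(p$z_raw))
  expect_error(correct_refractive_index(p, 0))
})
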