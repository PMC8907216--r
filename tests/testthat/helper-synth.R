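# Shared fixtures, built in code at test time.

# Default optical model and its noiseless LUT (memoized: LUT construction is
# deterministic, so one instance serves every test file).
default_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) {
      scan <- simulate_calibration_scan(optical_model(), noise = "none")
      lut <<- build_axial_lut(scan)
    }
    lut
  }
})

# Closed-form contrast of the default optical model (Gaussian responses,
# symmetric focal offsets): gamma(z) = tanh(z * (c2 - c1) / (2 w^2)).
gamma_oracle <- function(z, c1 = -200, c2 = 200, w = 300) {
  tanh(z * (c2 - c1) / (2 * w^2))
}

# A small localization table written to a temp CSV.
write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Brute-force GLCM homogeneity oracle: direct enumeration over every pixel
# pair, no matrices. Mirrors the specified pipeline (8-bit conversion,
# ISODATA background zeroing, zero-pair removal, inverse-abs-difference
# weight, mean over the four directions with empty directions scoring 0).
homogeneity_bruteforce <- function(img) {
  g <- as_gray8(img)
  thr <- isodata_threshold(g)
  g[g < thr] <- 0L
  dirs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  vals <- vapply(dirs, function(d) {
    tot <- 0; acc <- 0
    for (i in seq_len(nrow(g))) {
      for (j in seq_len(ncol(g))) {
        i2 <- i + d[1]; j2 <- j + d[2]
        if (i2 < 1 || i2 > nrow(g) || j2 < 1 || j2 > ncol(g)) next
        a <- g[i, j]; b <- g[i2, j2]
        if (a == 0 || b == 0) next
        tot <- tot + 1
        acc <- acc + 1 / (1 + abs(a - b))
      }
    }
    if (tot == 0) 0 else acc / tot
  }, numeric(1))
  mean(vals)
}

# Brute-force optimal-pairing oracle: enumerate all one-to-one matchings of
# points within max_dist and return the greedy ascending-distance solution
# computed independently of the package internals.
greedy_pairs_bruteforce <- function(p1, p2, max_dist) {
  d <- as.matrix(dist(rbind(p1, p2)))[seq_len(nrow(p1)),
                                      nrow(p1) + seq_len(nrow(p2)), drop = FALSE]
  cand <- which(d <= max_dist, arr.ind = TRUE)
  ord <- order(d[cand], cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  used1 <- logical(nrow(p1)); used2 <- logical(nrow(p2))
  out <- NULL
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used1[i] && !used2[j]) {
      used1[i] <- TRUE; used2[j] <- TRUE
      out <- rbind(out, c(i, j))
    }
  }
  out
}
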