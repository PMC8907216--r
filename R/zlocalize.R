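#' Estimate the reflected-to-transmitted channel transform
#'
#' Registers the reflected-channel coordinate system onto the transmitted
#' channel. A coarse translation is found by cross-correlating 2D localization
#' histograms; control pairs are then collected by framewise mutual
#' nearest-neighbor matching under the coarse shift, and a similarity
#' transform (translation + rotation + isotropic scale) is fitted to them in
#' closed form.
#'
#' @param t1 Transmitted-channel localization tibble.
#' @param t2 Reflected-channel localization tibble (same acquisition).
#' @param hist_bin Histogram bin for the coarse correlation, nm (default 100).
#' @param control_dist Match radius for control pairs after the coarse shift,
#'   nm (default 250).
#' @return An object of class `channel_transform`: rotation-scale matrix `A`,
#'   translation `t` (maps t2 coordinates onto t1 as `A x + t`), `scale`,
#'   `rms` residual in nm, and `n_pairs`.
#' @export
estimate_channel_transform <- function(t1, t2, hist_bin = 100, control_dist = 250) {
  require_columns(t1, c("x", "y", "frame"))
  require_columns(t2, c("x", "y", "frame"))
  if (nrow(t1) == 0 || nrow(t2) == 0) abort("both localization tables must be non-empty")

  shift <- coarse_histogram_shift(t1, t2, hist_bin)
  t2s <- t2
  t2s$x <- t2s$x + shift[1]
  t2s$y <- t2s$y + shift[2]

  pairs <- match_pairs_by_frame(t1, t2s, max_dist = control_dist)
  if (nrow(pairs) < 10) {
    abort(sprintf("channel alignment failure: only %d control pair(s) found (need >= 10)",
                  nrow(pairs)))
  }
  P <- cbind(t2$x[pairs$j], t2$y[pairs$j]) # original reflected coords
  Q <- cbind(t1$x[pairs$i], t1$y[pairs$i])
  fit <- fit_similarity(P, Q)
  structure(c(fit, list(n_pairs = nrow(pairs), coarse_shift = shift)),
            class = "channel_transform")
}

# Integer-bin translation (t2 -> t1) maximizing the cross-correlation of the
# two 2D localization histograms, computed via FFT.
coarse_histogram_shift <- function(t1, t2, bin) {
  xr <- range(c(t1$x, t2$x)); yr <- range(c(t1$y, t2$y))
  nx <- max(2L, ceiling(diff(xr) / bin) + 1L)
  ny <- max(2L, ceiling(diff(yr) / bin) + 1L)
  h <- function(t) {
    ix <- pmin(nx, pmax(1L, floor((t$x - xr[1]) / bin) + 1L))
    iy <- pmin(ny, pmax(1L, floor((t$y - yr[1]) / bin) + 1L))
    m <- matrix(0, nx, ny)
    for (k in seq_along(ix)) m[ix[k], iy[k]] <- m[ix[k], iy[k]] + 1
    m
  }
  h1 <- h(t1); h2 <- h(t2)
  # zero-pad to avoid wrap-around
  px <- 2L * nx; py <- 2L * ny
  pad <- function(m) { out <- matrix(0, px, py); out[1:nx, 1:ny] <- m; out }
  cc <- Re(stats::fft(stats::fft(pad(h1)) * Conj(stats::fft(pad(h2))), inverse = TRUE))
  k <- arrayInd(which.max(cc), dim(cc))
  dx <- k[1] - 1L; dy <- k[2] - 1L
  if (dx > px / 2) dx <- dx - px
  if (dy > py / 2) dy <- dy - py
  c(dx, dy) * bin
}

# Closed-form least-squares similarity transform P -> Q (Procrustes/Umeyama).
fit_similarity <- function(P, Q) {
  mp <- colMeans(P); mq <- colMeans(Q)
  Pc <- sweep(P, 2, mp); Qc <- sweep(Q, 2, mq)
  S <- crossprod(Pc, Qc) / nrow(P)
  sv <- svd(S)
  D <- diag(2)
  if (det(sv$u) * det(sv$v) < 0) D[2, 2] <- -1
  R <- sv$v %*% D %*% t(sv$u)
  var_p <- mean(rowSums(Pc^2))
  s <- sum(diag(D %*% diag(sv$d))) / var_p
  A <- s * R
  t_vec <- mq - A %*% mp
  resid <- Q - (P %*% t(A) + matrix(t_vec, nrow(P), 2, byrow = TRUE))
  list(A = A, t = as.numeric(t_vec), scale = s,
       rms = sqrt(mean(rowSums(resid^2))))
}

#' Apply a channel transform to coordinates
#'
#' @param transform A `channel_transform`.
#' @param locs Localization tibble whose `x`, `y` are mapped.
#' @return The tibble with transformed coordinates.
#' @export
apply_channel_transform <- function(transform, locs) {
  stopifnot(inherits(transform, "channel_transform"))
  xy <- cbind(locs$x, locs$y) %*% t(transform$A)
  locs$x <- xy[, 1] + transform$t[1]
  locs$y <- xy[, 2] + transform$t[2]
  locs
}

#' @export
print.channel_transform <- function(x, ...) {
  cat("<channel_transform> similarity (reflected -> transmitted)\n")
  cat(sprintf("  translation: (%.2f, %.2f) nm, scale: %.6f\n",
              x$t[1], x$t[2], x$scale))
  cat(sprintf("  rms residual: %.2f nm over %d control pairs\n", x$rms, x$n_pairs))
  invisible(x)
}

# Greedy mutual-nearest matching in ascending distance order within each
# frame. Returns tibble(i, j, frame, dist) of row indices into t1/t2.
match_pairs_by_frame <- function(t1, t2, max_dist) {
  i1 <- split(seq_len(nrow(t1)), t1$frame)
  i2 <- split(seq_len(nrow(t2)), t2$frame)
  frames <- intersect(names(i1), names(i2))
  res <- purrr::map(frames, function(f) {
    a <- i1[[f]]; b <- i2[[f]]
    dx <- outer(t1$x[a], t2$x[b], "-")
    dy <- outer(t1$y[a], t2$y[b], "-")
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= max_dist, arr.ind = TRUE)
    if (nrow(cand) == 0) return(NULL)
    dd <- d[cand]
    # ties broken by lower record index (row, then col)
    ord <- order(dd, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_a <- logical(length(a)); used_b <- logical(length(b))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      r <- cand[k, 1]; c <- cand[k, 2]
      if (!used_a[r] && !used_b[c]) {
        used_a[r] <- TRUE; used_b[c] <- TRUE; keep[k] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    tibble::tibble(i = a[cand[, 1]], j = b[cand[, 2]],
                   frame = as.integer(f), dist = dd[ord][keep])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(i = integer(), j = integer(),
                          frame = integer(), dist = double())
  }
  out
}

#' Pair transmitted and reflected localizations frame by frame
#'
#' Within each frame, candidate pairs closer than `max_dist` (after mapping
#' the reflected channel through `transform`) are accepted greedily in
#' ascending distance order, so every localization is used at most once and
#' each accepted pair is mutually nearest among the remaining candidates.
#' Lateral coordinates of a pair are taken from the transmitted channel.
#'
#' @param t1 Transmitted-channel localization tibble.
#' @param t2 Reflected-channel localization tibble.
#' @param transform Optional `channel_transform` applied to `t2` first.
#' @param max_dist Pairing distance threshold in nm (default 500).
#' @return Tibble with columns `frame`, `x`, `y` (transmitted), `I1`, `I2`,
#'   `gamma`, `pair_dist`. Attributes `n_unpaired_transmitted` and
#'   `n_unpaired_reflected` count the leftovers.
#' @export
pair_localizations <- function(t1, t2, transform = NULL, max_dist = 500) {
  require_columns(t1, c("x", "y", "frame", "intensity"))
  require_columns(t2, c("x", "y", "frame", "intensity"))
  check_number(max_dist, "max_dist", min = 0)
  t2m <- if (is.null(transform)) t2 else apply_channel_transform(transform, t2)
  m <- match_pairs_by_frame(t1, t2m, max_dist)
  out <- tibble::tibble(
    frame = t1$frame[m$i],
    x = t1$x[m$i], y = t1$y[m$i],
    I1 = t1$intensity[m$i], I2 = t2$intensity[m$j],
    gamma = compute_gamma(t1$intensity[m$i], t2$intensity[m$j]),
    pair_dist = m$dist
  )
  attr(out, "n_unpaired_transmitted") <- nrow(t1) - nrow(out)
  attr(out, "n_unpaired_reflected") <- nrow(t2) - nrow(out)
  out
}

#' Assign axial coordinates from the lookup table
#'
#' Inverts the calibration: each pair's contrast \eqn{\gamma} is located
#' between its bracketing lookup-table nodes and the axial coordinate is the
#' linear interpolation of the node z values. Contrasts outside the table's
#' gamma range are dropped (no extrapolation) and counted.
#'
#' @param pairs Paired-localization tibble (from [pair_localizations()], or
#'   any tibble with a `gamma` column).
#' @param lut An `axial_lut`.
#' @param quiet Suppress the out-of-range message.
#' @return The tibble with a new `z_raw` column (nm); attribute
#'   `n_out_of_range` counts dropped pairs.
#' @export
assign_z <- function(pairs, lut, quiet = FALSE) {
  stopifnot(inherits(lut, "axial_lut"))
  require_columns(pairs, "gamma", what = "paired table")
  if (length(lut$gamma_nodes) < 2) abort("empty axial lookup table")
  z <- approx(x = lut$gamma_nodes, y = lut$z_nodes, xout = pairs$gamma,
              method = "linear", rule = 1)$y
  keep <- !is.na(z)
  out <- pairs[keep, , drop = FALSE]
  out$z_raw <- z[keep]
  n_oor <- sum(!keep)
  if (!quiet && n_oor > 0) {
    inform(sprintf("assign_z: dropped %d pair(s) with gamma outside the LUT range", n_oor))
  }
  attr(out, "n_out_of_range") <- n_oor
  attr(out, "n_unpaired_transmitted") <- attr(pairs, "n_unpaired_transmitted")
  attr(out, "n_unpaired_reflected") <- attr(pairs, "n_unpaired_reflected")
  out
}

#' Correct axial coordinates for refractive-index mismatch
#'
#' Rescales the raw axial coordinate by a single calibration factor
#' (objective immersion vs. sample medium); lateral coordinates are untouched.
#' The factor is a required user calibration constant; 1.0 leaves z unchanged.
#'
#' @param pairs Tibble with a `z_raw` column.
#' @param factor Positive scale factor (default 1.0).
#' @return The tibble with `z = factor * z_raw`.
#' @export
correct_refractive_index <- function(pairs, factor = 1.0) {
  check_number(factor, "factor", min = 1e-12)
  require_columns(pairs, "z_raw", what = "z-assigned table")
  pairs$z <- factor * pairs$z_raw
  pairs
}
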