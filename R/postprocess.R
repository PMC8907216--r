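#' Per-window axial footprint trace
#'
#' Fiducial-free drift estimation treats the thin membrane layer as its own
#' fiducial: the axial footprint of all localizations is summarized per
#' temporal window and tracked over the acquisition. The per-window summary is
#' the median z (robust against protrusion localizations); on the synthetic
#' membrane model it differs from the mean by well under the correction
#' tolerance.
#'
#' @param locs 3D localization tibble (columns `frame`, `z`).
#' @param window Window length in frames, non-overlapping (default 500).
#' @return Tibble with columns `window`, `frame` (window center), `z_med`,
#'   `n`.
#' @export
axial_drift_trace <- function(locs, window = 500) {
  require_columns(locs, c("frame", "z"))
  check_number(window, "window", min = 1)
  win_len <- window
  trace <- locs |>
    dplyr::mutate(window = floor(.data$frame / win_len)) |>
    dplyr::summarise(z_med = median(.data$z), n = dplyr::n(), .by = "window") |>
    dplyr::arrange(.data$window) |>
    dplyr::mutate(frame = (.data$window + 0.5) * win_len, .after = "window")
  if (nrow(trace) < 4) {
    abort("drift-fit error: fewer than 4 populated temporal windows")
  }
  trace
}

#' Fiducial-free axial drift correction
#'
#' Fits the drift trace with a polynomial in time (weighted by window
#' occupancy) and linearizes the axial coordinate:
#' `z_corrected = z - poly(frame) + poly(frame_ref)`, with the reference taken
#' at the first populated window so the early-acquisition level is preserved.
#' Localization count and lateral coordinates are untouched.
#'
#' @param locs 3D localization tibble (`frame`, `z`).
#' @param poly_order Drift polynomial order (default 6).
#' @param window Trace window length in frames (default 500).
#' @return The corrected tibble; the fitted model (class `drift_model`) is
#'   attached as attribute `drift_model`.
#' @export
correct_axial_drift <- function(locs, poly_order = 6, window = 500) {
  trace <- axial_drift_trace(locs, window = window)
  if (poly_order >= nrow(trace)) {
    abort(sprintf(
      "ill-conditioned drift fit: order %d with only %d populated windows; lower the order",
      poly_order, nrow(trace)))
  }
  # scaled frame variable for conditioning
  fscale <- max(trace$frame)
  fit <- lm(z_med ~ stats::poly(frame / fscale, poly_order, raw = TRUE),
            data = trace, weights = trace$n)
  coeffs <- unname(coef(fit))
  coeffs[is.na(coeffs)] <- 0
  drift_at <- function(frame) eval_poly(coeffs, frame / fscale)
  ref <- drift_at(trace$frame[1])
  out <- locs
  out$z <- locs$z - drift_at(locs$frame) + ref

  model <- structure(list(
    coefficients = coeffs, frame_scale = fscale, poly_order = poly_order,
    window = window, reference = ref,
    rms = sqrt(weighted.mean((trace$z_med - drift_at(trace$frame))^2, trace$n)),
    trace = trace
  ), class = "drift_model")
  attr(out, "drift_model") <- model
  out
}

#' @export
print.drift_model <- function(x, ...) {
  cat(sprintf("<drift_model> order-%d polynomial over %d windows of %d frames\n",
              x$poly_order, nrow(x$trace), x$window))
  cat(sprintf("  trace fit rms: %.2f nm; reference level: %.2f nm\n", x$rms, x$reference))
  invisible(x)
}

# Evaluate a drift model at given frames (internal; used by tests/plots).
predict_drift <- function(model, frame) {
  eval_poly(model$coefficients, frame / model$frame_scale)
}

#' Fit the residual sample-tilt plane
#'
#' Renders the localizations as a 2D image of per-pixel mean z (default
#' 100 nm pixels) and fits a plane `z = a x + b y + c` over the occupied
#' pixels by least squares. Apply drift correction first; the drift trace
#' otherwise leaks into the plane estimate.
#'
#' @param locs 3D localization tibble (`x`, `y`, `z`).
#' @param pixel_size Image pixel size in nm (default 100).
#' @return An object of class `tilt_model` with slopes `a`, `b` (nm per nm),
#'   offset `c`, and `n_pixels`.
#' @export
fit_tilt_plane <- function(locs, pixel_size = 100) {
  require_columns(locs, c("x", "y", "z"))
  check_number(pixel_size, "pixel_size", min = 1e-6)
  img <- locs |>
    dplyr::mutate(px = floor(.data$x / pixel_size), py = floor(.data$y / pixel_size)) |>
    dplyr::summarise(z = mean(.data$z), .by = c("px", "py"))
  if (nrow(img) < 10) abort("tilt fit error: fewer than 10 occupied pixels")
  xc <- (img$px + 0.5) * pixel_size
  yc <- (img$py + 0.5) * pixel_size
  fit <- lm(img$z ~ xc + yc)
  cf <- coef(fit)
  if (anyNA(cf)) abort("tilt fit error: occupied pixels are collinear (rank-deficient plane)")
  structure(list(a = unname(cf["xc"]), b = unname(cf["yc"]),
                 c = unname(cf["(Intercept)"]),
                 n_pixels = nrow(img), pixel_size = pixel_size),
            class = "tilt_model")
}

#' @export
print.tilt_model <- function(x, ...) {
  cat(sprintf("<tilt_model> z = %.3g x + %.3g y + %.3g (nm; %d occupied %g nm pixels)\n",
              x$a, x$b, x$c, x$n_pixels, x$pixel_size))
  invisible(x)
}

#' Remove the sample-tilt plane from axial coordinates
#'
#' Subtracts the local plane value from every localization; the plane is
#' centered on the data so the global mean z is unchanged. Lateral
#' coordinates are untouched bitwise.
#'
#' @param locs 3D localization tibble.
#' @param tilt A `tilt_model` (fitted on `locs` if omitted).
#' @return The corrected tibble.
#' @export
correct_tilt <- function(locs, tilt = NULL) {
  require_columns(locs, c("x", "y", "z"))
  if (is.null(tilt)) tilt <- fit_tilt_plane(locs)
  stopifnot(inherits(tilt, "tilt_model"))
  plane <- tilt$a * locs$x + tilt$b * locs$y
  locs$z <- locs$z - (plane - mean(plane))
  locs
}

#' Localization precision from short single-fluorophore tracks
#'
#' Links localizations in consecutive frames by mutual 3D nearest neighbors;
#' a track keeps growing while its cumulative inter-localization distance
#' stays below `max_track_dist` (default 75 nm), so each track plausibly stems
#' from one fluorophore. Per track and axis, deviations from the track mean
#' are pooled over all tracks; the per-axis precision is the sigma of a
#' Gaussian fitted to the pooled deviation histogram (root-mean-square
#' deviation when too few deviations are available for a stable histogram
#' fit). Deviations are not bias-corrected for track length.
#'
#' @param locs 3D localization tibble (`x`, `y`, `z`, `frame`).
#' @param max_track_dist Cumulative track-length budget in nm (default 75).
#' @return Tibble with one row: `sigma_x`, `sigma_y`, `sigma_z` (nm),
#'   `n_tracks`, `n_localizations`.
#' @export
estimate_localization_precision <- function(locs, max_track_dist = 75) {
  require_columns(locs, c("x", "y", "z", "frame"))
  check_number(max_track_dist, "max_track_dist", min = 0)

  ord <- order(locs$frame)
  locs <- locs[ord, , drop = FALSE]
  n <- nrow(locs)
  track_id <- seq_len(n)       # union-find-free: next-frame relinking
  cum_dist <- numeric(n)       # cumulative distance of the track ending here

  by_frame <- split(seq_len(n), locs$frame)
  frames <- as.integer(names(by_frame))
  for (k in seq_along(frames)) {
    f <- frames[k]
    nxt <- match(as.character(f + 1L), names(by_frame))
    if (is.na(nxt)) next
    a <- by_frame[[k]]; b <- by_frame[[nxt]]
    dx <- outer(locs$x[a], locs$x[b], "-")
    dy <- outer(locs$y[a], locs$y[b], "-")
    dz <- outer(locs$z[a], locs$z[b], "-")
    d <- sqrt(dx^2 + dy^2 + dz^2)
    cand <- which(d <= max_track_dist, arr.ind = TRUE)
    if (nrow(cand) == 0) next
    dd <- d[cand]
    ordc <- order(dd, cand[, 1], cand[, 2])
    cand <- cand[ordc, , drop = FALSE]; dd <- dd[ordc]
    used_a <- logical(length(a)); used_b <- logical(length(b))
    for (m in seq_len(nrow(cand))) {
      r <- cand[m, 1]; c <- cand[m, 2]
      if (used_a[r] || used_b[c]) next
      ia <- a[r]; ib <- b[c]
      if (cum_dist[ia] + dd[m] < max_track_dist) {
        track_id[ib] <- track_id[ia]
        cum_dist[ib] <- cum_dist[ia] + dd[m]
        used_a[r] <- TRUE; used_b[c] <- TRUE
      }
    }
  }

  sizes <- table(track_id)
  keep <- track_id %in% as.integer(names(sizes)[sizes >= 2])
  if (!any(keep)) abort("no track of length >= 2; cannot estimate precision")
  grp <- factor(track_id[keep])
  dev_axis <- function(v) {
    v <- v[keep]
    unlist(tapply(v, grp, function(u) u - mean(u)), use.names = FALSE)
  }
  devx <- dev_axis(locs$x); devy <- dev_axis(locs$y); devz <- dev_axis(locs$z)
  tibble::tibble(
    sigma_x = gaussian_sigma(devx),
    sigma_y = gaussian_sigma(devy),
    sigma_z = gaussian_sigma(devz),
    n_tracks = nlevels(grp),
    n_localizations = sum(keep)
  )
}

# Sigma of a zero-mean Gaussian fitted to the deviation histogram; falls back
# to the RMS for small samples or non-convergence.
gaussian_sigma <- function(dev, min_n = 50) {
  rms <- sqrt(mean(dev^2))
  if (length(dev) < min_n || rms == 0) return(rms)
  h <- graphics::hist(dev, breaks = "FD", plot = FALSE)
  df <- data.frame(x = h$mids, y = h$density)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ 1 / (sqrt(2 * pi) * s) * exp(-0.5 * (x / s)^2),
                      data = df, start = list(s = rms),
                      lower = rms / 10, upper = rms * 10),
    error = function(e) NULL)
  if (is.null(fit)) rms else unname(coef(fit)["s"])
}
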