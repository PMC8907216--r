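#' Normalized biplane intensity contrast
#'
#' The axial observable of intensity-ratio biplane localization: for fitted
#' intensities `i1` (transmitted plane) and `i2` (reflected plane) of the same
#' emitter appearance,
#' \deqn{\gamma = (I_2 - I_1) / (I_1 + I_2) \in [-1, 1].}
#' Because both intensities come from fixed-width Gaussian fits of the same
#' spot, any common photometric factor cancels; \eqn{\gamma} depends only on
#' the relative defocus of the two detection planes and therefore on z.
#'
#' @param i1,i2 Non-negative fitted intensities (photons); vectorized.
#' @return Numeric vector of contrasts in \eqn{[-1, 1]}.
#' @export
#' @examples
#' compute_gamma(1000, 1000) # 0
#' compute_gamma(750, 250)   # -0.5
compute_gamma <- function(i1, i2) {
  if (length(i1) != length(i2)) abort("`i1` and `i2` must have equal length")
  if (any(!is.finite(i1)) || any(!is.finite(i2)) || any(i1 < 0) || any(i2 < 0)) {
    abort("intensities must be finite and non-negative")
  }
  tot <- i1 + i2
  if (any(tot == 0)) abort("undefined intensity ratio: I1 + I2 = 0")
  (i2 - i1) / tot
}

#' Build the axial lookup table from a calibration scan
#'
#' A calibration scan sweeps the focal plane linearly through a single-molecule
#' surface, yielding matched biplane intensities at known stage z. The contrast
#' \eqn{\gamma} is computed per intensity pair, reduced to a running median in
#' non-overlapping z bins (default width 25 nm), and the bin medians are fitted
#' with a high-order polynomial (default order 7). The lookup table is the
#' polynomial sampled at 1 nm over the largest contiguous interval on which it
#' is strictly monotone; outside this range localizations are rejected rather
#' than extrapolated.
#'
#' @param scan Data frame with columns `z_stage` (nm; `z_stage_nm` accepted),
#'   `I1`, `I2` (photons).
#' @param bin_width Running-median bin width in nm (default 25).
#' @param poly_order Polynomial order, 3--11 (default 7; odd orders track a
#'   sigmoid trend without endpoint oscillation).
#' @param min_per_bin Minimum intensity pairs per retained bin (default 5);
#'   underfilled bins are dropped with a warning.
#' @return An object of class `axial_lut`: list with `z_nodes` (1 nm grid),
#'   `gamma_nodes`, `poly_coeffs` (raw polynomial coefficients in the scaled
#'   variable z/1000), `valid_range`, `bin_width`, `poly_order`, and the bin
#'   median table `bins`.
#' @export
build_axial_lut <- function(scan, bin_width = 25, poly_order = 7, min_per_bin = 5) {
  scan <- normalize_scan_columns(scan)
  check_number(bin_width, "bin_width", min = 1)
  if (!poly_order %in% 3:11) abort("`poly_order` must be an integer in 3..11")

  gamma <- compute_gamma(scan$I1, scan$I2)
  bin <- floor(scan$z_stage / bin_width)
  # Each bin is summarized by its median gamma at its median z; using the
  # median z (not the bin center) keeps the node unbiased when the scan
  # samples a bin asymmetrically.
  med <- tibble::tibble(bin = bin, z = scan$z_stage, gamma = gamma) |>
    dplyr::summarise(z = median(.data$z), gamma = median(.data$gamma),
                     n = dplyr::n(), .by = "bin") |>
    dplyr::arrange(.data$bin)
  under <- med$n < min_per_bin
  if (any(under)) {
    warn(sprintf("build_axial_lut: dropping %d underfilled z bin(s) (< %d pairs)",
                 sum(under), min_per_bin))
    med <- med[!under, , drop = FALSE]
  }
  if (nrow(med) < 10) abort("calibration scan must cover at least 10 populated z bins")

  # Fit in z/1000 for conditioning; keep raw coefficients for serialization.
  zs <- med$z / 1000
  fit <- lm(med$gamma ~ stats::poly(zs, poly_order, raw = TRUE))
  coeffs <- unname(coef(fit))
  coeffs[is.na(coeffs)] <- 0

  z_grid <- seq(min(med$z), max(med$z), by = 1)
  g_grid <- eval_poly(coeffs, z_grid / 1000)

  rng <- longest_monotone_run(g_grid)
  if (is.null(rng) || (z_grid[rng[2]] - z_grid[rng[1]]) < 100) {
    abort("calibration failure: fitted gamma(z) has no strictly monotone interval of at least 100 nm")
  }
  idx <- seq(rng[1], rng[2])

  structure(list(
    z_nodes = z_grid[idx],
    gamma_nodes = g_grid[idx],
    poly_coeffs = coeffs,
    valid_range = c(z_grid[rng[1]], z_grid[rng[2]]),
    bin_width = bin_width,
    poly_order = poly_order,
    bins = tibble::tibble(z = med$z, gamma = med$gamma, n = med$n)
  ), class = "axial_lut")
}

normalize_scan_columns <- function(scan) {
  nm <- names(scan)
  nm[nm %in% c("z_stage_nm", "z")] <- "z_stage"
  nm[nm %in% c("i1", "I1_photons")] <- "I1"
  nm[nm %in% c("i2", "I2_photons")] <- "I2"
  names(scan) <- nm
  require_columns(scan, c("z_stage", "I1", "I2"), what = "calibration scan")
  if (any(scan$I1 + scan$I2 <= 0)) abort("calibration scan contains pairs with I1 + I2 <= 0")
  scan
}

eval_poly <- function(coeffs, x) {
  # coeffs[1] + coeffs[2] x + ... (Horner)
  out <- rep(0, length(x))
  for (ck in rev(coeffs)) out <- out * x + ck
  out
}

# Longest run of indices over which diff(g) keeps one strict sign.
# Returns c(start, end) or NULL.
longest_monotone_run <- function(g) {
  d <- sign(diff(g))
  if (all(d == 0)) return(NULL)
  best <- NULL; best_len <- 0
  start <- 1
  for (i in seq_along(d)) {
    if (d[i] == 0 || (i > start && d[i] != d[i - 1])) start <- if (d[i] == 0) i + 1 else i
    len <- i - start + 1
    if (d[i] != 0 && len > best_len) {
      best_len <- len
      best <- c(start, i + 1)
    }
  }
  best
}

#' @export
print.axial_lut <- function(x, ...) {
  cat(sprintf("<axial_lut> order-%d polynomial, %d nm bins\n", x$poly_order, x$bin_width))
  cat(sprintf("  valid z range: [%g, %g] nm (%d nodes at 1 nm)\n",
              x$valid_range[1], x$valid_range[2], length(x$z_nodes)))
  cat(sprintf("  gamma range: [%.4f, %.4f]\n", min(x$gamma_nodes), max(x$gamma_nodes)))
  invisible(x)
}

#' Tabulate an axial lookup table
#'
#' @param lut An `axial_lut`.
#' @return Tibble with columns `z_nm`, `gamma`, one row per 1 nm node.
#' @export
lut_to_table <- function(lut) {
  stopifnot(inherits(lut, "axial_lut"))
  tibble::tibble(z_nm = lut$z_nodes, gamma = lut$gamma_nodes)
}

#' Save / load an axial lookup table
#'
#' The node table is written as CSV and the fit metadata (polynomial
#' coefficients, valid range, bin width, order) as a JSON sidecar next to it.
#'
#' @param lut An `axial_lut`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `write_axial_lut()`: `path` invisibly. `read_axial_lut()`: the
#'   reconstructed `axial_lut`.
#' @export
write_axial_lut <- function(lut, path) {
  stopifnot(inherits(lut, "axial_lut"))
  readr::write_csv(lut_to_table(lut), path, progress = FALSE)
  meta <- list(poly_coeffs = lut$poly_coeffs, valid_range = lut$valid_range,
               bin_width = lut$bin_width, poly_order = lut$poly_order)
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_axial_lut
#' @export
read_axial_lut <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar, simplifyVector = TRUE) else list()
  structure(list(
    z_nodes = tab$z_nm,
    gamma_nodes = tab$gamma,
    poly_coeffs = meta$poly_coeffs,
    valid_range = meta$valid_range %||% range(tab$z_nm),
    bin_width = meta$bin_width %||% NA_real_,
    poly_order = meta$poly_order %||% NA_integer_,
    bins = NULL
  ), class = "axial_lut")
}
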