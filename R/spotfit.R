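#' Detect candidate emitters in a single frame
#'
#' Local-maximum detection on the raw pixel grid: a pixel is a candidate
#' center when it dominates its 8-neighborhood and the
#' background-subtracted photon sum over the fit window (background taken as
#' the window minimum) exceeds `min_photons`. Centers are reported at pixel
#' precision; sub-pixel refinement is the fitter's job.
#'
#' @param img Numeric matrix of photon counts (one frame).
#' @param pixel_size nm per pixel.
#' @param min_photons Detection threshold on the windowed photon sum
#'   (default 500).
#' @param window_radius Window half-width in nm (default 1200); must be at
#'   least two pixels.
#' @return Tibble with columns `row`, `col` (pixel indices), `x`, `y`
#'   (nm, pixel centers), `photons` (windowed background-subtracted sum).
#' @export
detect_candidates <- function(img, pixel_size, min_photons = 500, window_radius = 1200) {
  if (!is.matrix(img)) abort("`img` must be a matrix")
  check_number(pixel_size, "pixel_size", min = 1e-6)
  r <- floor(window_radius / pixel_size)
  if (r < 2) abort("`window_radius` must span at least 2 pixels")
  nr <- nrow(img); nc <- ncol(img)
  out <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      v <- img[i, j]
      if (v <= 0) next
      ni <- max(1, i - 1):min(nr, i + 1)
      nj <- max(1, j - 1):min(nc, j + 1)
      if (v < max(img[ni, nj])) next
      wi <- max(1, i - r):min(nr, i + r)
      wj <- max(1, j - r):min(nc, j + r)
      win <- img[wi, wj]
      signal <- sum(win) - min(win) * length(win)
      if (signal > min_photons) {
        out[[length(out) + 1L]] <- c(i, j, signal)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(row = integer(), col = integer(),
                          x = double(), y = double(), photons = double()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(row = as.integer(m[, 1]), col = as.integer(m[, 2]),
                 x = (m[, 1] - 0.5) * pixel_size,
                 y = (m[, 2] - 0.5) * pixel_size,
                 photons = m[, 3])
}

#' Fit one spot with a fixed-width Gaussian
#'
#' The defining fit of intensity-ratio axial localization: total photons,
#' position and constant background are free, the PSF width is held fixed at
#' `fwhm` (default 300 nm, sigma = fwhm / 2.355). The spot model is the
#' pixel-integrated 2D Gaussian, so the fitted photon parameter is directly
#' the total fitted intensity (equivalently `2 pi sigma^2 * amplitude /
#' pixel_area` of the continuous profile) and photons are conserved between
#' rendering and fitting. Overlapping windows are fitted independently, which
#' is what permits the higher emitter densities of the intensity-ratio
#' scheme.
#'
#' @param img Numeric matrix of photon counts (one frame).
#' @param center Length-2 pixel indices `c(row, col)` of the candidate.
#' @param pixel_size nm per pixel.
#' @param fwhm Fixed PSF FWHM in nm (default 300).
#' @param window_radius Fit-window half-width in nm (default 1200); windows
#'   reaching beyond the frame are clipped and flagged.
#' @return Tibble with one row: `x`, `y` (nm), `intensity` (photons),
#'   `background` (photons/pixel), `residual` (sum of squared residuals),
#'   `clipped`, `converged`.
#' @export
fit_spot_fixed_fwhm <- function(img, center, pixel_size, fwhm = 300,
                                window_radius = 1200) {
  check_number(fwhm, "fwhm", min = 1e-6)
  r <- floor(window_radius / pixel_size)
  i0 <- center[1]; j0 <- center[2]
  wi <- max(1, i0 - r):min(nrow(img), i0 + r)
  wj <- max(1, j0 - r):min(ncol(img), j0 + r)
  clipped <- length(wi) < 2 * r + 1 || length(wj) < 2 * r + 1
  win <- img[wi, wj]
  sigma <- fwhm / FWHM_FACTOR / pixel_size # pixels

  df <- data.frame(
    i = rep(wi, times = length(wj)),
    j = rep(wj, each = length(wi)),
    v = as.numeric(win)
  )
  bg0 <- max(min(df$v), 0)
  # centroid of background-subtracted counts as position start
  wpos <- pmax(df$v - bg0, 0)
  n0 <- max(sum(wpos), 1e-3)
  i_start <- if (sum(wpos) > 0) sum(df$i * wpos) / sum(wpos) else i0
  j_start <- if (sum(wpos) > 0) sum(df$j * wpos) / sum(wpos) else j0

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ b + n *
        (pnorm((i - ci) / sigma) - pnorm((i - 1 - ci) / sigma)) *
        (pnorm((j - cj) / sigma) - pnorm((j - 1 - cj) / sigma)),
      data = df,
      start = list(n = n0, ci = i_start - 0.5, cj = j_start - 0.5, b = bg0),
      lower = c(n = 0, ci = min(wi) - 1, cj = min(wj) - 1, b = 0),
      upper = c(n = Inf, ci = max(wi), cj = max(wj), b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)

  if (is.null(fit)) {
    return(tibble::tibble(x = NA_real_, y = NA_real_, intensity = NA_real_,
                          background = NA_real_, residual = NA_real_,
                          clipped = clipped, converged = FALSE))
  }
  cf <- as.list(coef(fit))
  tibble::tibble(
    x = cf$ci * pixel_size, y = cf$cj * pixel_size,
    intensity = cf$n,
    background = cf$b,
    residual = sum(stats::residuals(fit)^2),
    clipped = clipped, converged = TRUE
  )
}

#' Localize all spots of an image stack
#'
#' Runs [detect_candidates()] and [fit_spot_fixed_fwhm()] over every frame of
#' a stack and assembles a localization table compatible with the rest of the
#' pipeline. Failed fits are dropped.
#'
#' @param stack 3D array `[x, y, frame]` of photon counts (e.g. from
#'   [simulate_frames()] or a TIFF stack read with `tiff::readTIFF`).
#' @param pixel_size nm per pixel.
#' @param fwhm Fixed PSF FWHM in nm (default 300).
#' @param window_radius Fit window half-width in nm (default 1200).
#' @param min_photons Detection threshold (default 500).
#' @return Localization tibble (`x`, `y`, `frame`, `intensity`,
#'   `background`, `residual`).
#' @export
localize_stack <- function(stack, pixel_size, fwhm = 300,
                           window_radius = 1200, min_photons = 500) {
  stopifnot(length(dim(stack)) == 3)
  purrr::map(seq_len(dim(stack)[3]), function(f) {
    img <- stack[, , f]
    cand <- detect_candidates(img, pixel_size, min_photons, window_radius)
    if (nrow(cand) == 0) return(NULL)
    fits <- purrr::map(seq_len(nrow(cand)), function(k) {
      fit_spot_fixed_fwhm(img, c(cand$row[k], cand$col[k]), pixel_size,
                          fwhm, window_radius)
    }) |> dplyr::bind_rows()
    fits$frame <- f - 1L
    fits[fits$converged, , drop = FALSE]
  }) |>
    purrr::compact() |>
    dplyr::bind_rows() |>
    dplyr::select(dplyr::any_of(c("x", "y", "frame", "intensity", "background", "residual")))
}
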