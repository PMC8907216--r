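#' Fit a bi-Gaussian model to an axial profile
#'
#' Models an ROI's axial localization histogram as the sum of two Gaussians,
#' \deqn{y = a_1 e^{-\frac12 ((x - m_1)/s_1)^2} + a_2 e^{-\frac12 ((x - m_2)/s_2)^2},}
#' by bounded nonlinear least squares (amplitudes non-negative, widths within
#' `s_bounds`, means within the profile range). Initialization uses the two
#' most prominent local maxima of the lightly smoothed profile, falling back
#' to a single peak split by one bin; components are relabeled so
#' `m1 <= m2`.
#'
#' @param profile Tibble with columns `z` and `count` (from
#'   [axial_profile()]).
#' @param s_bounds Allowed width range in nm (default `c(10, 1000)`).
#' @return An object of class `bigauss_fit` with elements `a1`, `m1`, `s1`,
#'   `a2`, `m2`, `s2`, `goodness` (R-squared against the profile),
#'   `converged`, and the input `profile`.
#' @export
fit_bigaussian <- function(profile, s_bounds = c(10, 1000)) {
  require_columns(profile, c("z", "count"), what = "axial profile")
  nz <- sum(profile$count > 0)
  if (nz < 8) abort(sprintf("axial profile has only %d nonzero bins (need >= 8)", nz))

  x <- profile$z; y <- profile$count
  zr <- range(x)
  starts <- list(bigauss_init(x, y, s_bounds), bigauss_init_moments(x, y, s_bounds))
  fit <- NULL
  for (init in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a1 * exp(-0.5 * ((x - m1) / s1)^2) + a2 * exp(-0.5 * ((x - m2) / s2)^2),
        data = data.frame(x = x, y = y),
        start = init,
        lower = c(a1 = 0, m1 = zr[1], s1 = s_bounds[1],
                  a2 = 0, m2 = zr[1], s2 = s_bounds[1]),
        upper = c(a1 = Inf, m1 = zr[2], s1 = s_bounds[2],
                  a2 = Inf, m2 = zr[2], s2 = s_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) abort("bi-Gaussian fit did not converge")

  p <- as.list(coef(fit))
  # Effectively mono-modal profiles converge with one amplitude at ~0; the
  # vanished component's location and width are then unconstrained, so they
  # are tied to the dominant component to keep the derived axial parameters
  # meaningful (z_w collapses to the dominant FWHM, p-p and delta to 0).
  if (min(p$a1, p$a2) < 1e-3 * max(p$a1, p$a2)) {
    if (p$a1 < p$a2) {
      p$m1 <- p$m2; p$s1 <- p$s2
    } else {
      p$m2 <- p$m1; p$s2 <- p$s1
    }
  }
  if (p$m1 > p$m2) {
    p <- list(a1 = p$a2, m1 = p$m2, s1 = p$s2, a2 = p$a1, m2 = p$m1, s2 = p$s1)
  }
  ss_res <- sum((y - bigauss_eval(p, x))^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(c(p, list(
    goodness = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
    converged = TRUE, profile = profile
  )), class = "bigauss_fit")
}

bigauss_eval <- function(p, x) {
  p$a1 * exp(-0.5 * ((x - p$m1) / p$s1)^2) + p$a2 * exp(-0.5 * ((x - p$m2) / p$s2)^2)
}

# Fallback start: count-weighted quartiles as component locations, half the
# weighted sd as widths. Robust when noise hides the true local maxima.
bigauss_init_moments <- function(x, y, s_bounds) {
  w <- pmax(y, 0)
  if (sum(w) == 0) w <- rep(1, length(x))
  mu <- sum(w * x) / sum(w)
  s <- sqrt(sum(w * (x - mu)^2) / sum(w))
  cw <- cumsum(w) / sum(w)
  q <- function(p) x[which(cw >= p)[1]]
  s0 <- min(max(s / 2, s_bounds[1] + 1), s_bounds[2] - 1)
  list(a1 = max(y) * 0.8, m1 = q(0.25), s1 = s0,
       a2 = max(y) * 0.4, m2 = q(0.75), s2 = s0)
}

# Start values: two most prominent local maxima of the 3-bin running mean;
# ties broken toward lower z. Single-peak profiles start split by one bin.
bigauss_init <- function(x, y, s_bounds) {
  ys <- stats::filter(y, rep(1 / 3, 3), sides = 2)
  ys[is.na(ys)] <- y[is.na(ys)]
  n <- length(ys)
  is_max <- c(FALSE, ys[2:(n - 1)] >= ys[1:(n - 2)] & ys[2:(n - 1)] > ys[3:n], FALSE)
  peaks <- which(is_max)
  peaks <- peaks[order(-ys[peaks], x[peaks])]
  dx <- if (n > 1) x[2] - x[1] else 20
  s0 <- min(max(diff(range(x)) / 10, s_bounds[1] + 1), s_bounds[2] - 1)
  if (length(peaks) >= 2) {
    p1 <- peaks[1]; p2 <- peaks[2]
    list(a1 = max(y[p1], 1), m1 = x[min(p1, p2)], s1 = s0,
         a2 = max(y[p2], 1), m2 = x[max(p1, p2)], s2 = s0)
  } else {
    p1 <- if (length(peaks) == 1) peaks[1] else which.max(y)
    list(a1 = max(y[p1], 1), m1 = x[p1] - dx, s1 = s0,
         a2 = max(y[p1], 1) / 2, m2 = x[p1] + dx, s2 = s0)
  }
}

#' @export
print.bigauss_fit <- function(x, ...) {
  cat("<bigauss_fit>\n")
  cat(sprintf("  component 1: a = %.3g, m = %.2f nm, s = %.2f nm\n", x$a1, x$m1, x$s1))
  cat(sprintf("  component 2: a = %.3g, m = %.2f nm, s = %.2f nm\n", x$a2, x$m2, x$s2))
  cat(sprintf("  R-squared: %.4f\n", x$goodness))
  invisible(x)
}

tidy_bigauss_row <- function(fit) {
  tibble::tibble(a1 = fit$a1, m1 = fit$m1, s1 = fit$s1,
                 a2 = fit$a2, m2 = fit$m2, s2 = fit$s2)
}

#' @exportS3Method generics::tidy
tidy.bigauss_fit <- function(x, ...) {
  tibble::tibble(
    component = c(1L, 2L),
    amplitude = c(x$a1, x$a2),
    mean = c(x$m1, x$m2),
    sd = c(x$s1, x$s2),
    fwhm = FWHM_FACTOR * c(x$s1, x$s2)
  )
}

#' @exportS3Method generics::glance
glance.bigauss_fit <- function(x, ...) {
  dplyr::bind_cols(tidy_bigauss_row(x),
                   compute_axial_params(x),
                   tibble::tibble(goodness = x$goodness, converged = x$converged))
}

#' Axial distribution parameters from a bi-Gaussian fit
#'
#' Derives the three descriptors of an ROI's axial receptor distribution
#' (with `FWHM_i = 2.355 s_i` and the convention `m1 <= m2`):
#' the z-distribution width
#' \deqn{z_w = (m_2 + FWHM_2/2) - (m_1 - FWHM_1/2),}
#' the peak-to-peak distance \eqn{p\mbox{-}p = |m_2 - m_1|}, and the width
#' difference \eqn{\Delta_{FWHM} = |FWHM_1 - FWHM_2|}.
#'
#' @param fit A `bigauss_fit`, or a data frame with columns `m1`, `s1`,
#'   `m2`, `s2` (vectorized).
#' @return Tibble with columns `z_w`, `p_p`, `delta_fwhm` (nm).
#' @export
#' @examples
#' compute_axial_params(data.frame(m1 = 100, s1 = 20, m2 = 180, s2 = 30))
compute_axial_params <- function(fit) {
  if (inherits(fit, "bigauss_fit")) {
    fit <- tidy_bigauss_row(fit)
  }
  require_columns(fit, c("m1", "s1", "m2", "s2"), what = "bi-Gaussian parameters")
  m1 <- pmin(fit$m1, fit$m2); m2 <- pmax(fit$m1, fit$m2)
  s1 <- ifelse(fit$m1 <= fit$m2, fit$s1, fit$s2)
  s2 <- ifelse(fit$m1 <= fit$m2, fit$s2, fit$s1)
  f1 <- FWHM_FACTOR * s1; f2 <- FWHM_FACTOR * s2
  tibble::tibble(
    z_w = (m2 + f2 / 2) - (m1 - f1 / 2),
    p_p = abs(m2 - m1),
    delta_fwhm = abs(f1 - f2)
  )
}

#' Population range of a Gaussian component
#'
#' The reporting convention for population histograms: a Gaussian component
#' with mean `mu` and standard deviation `sigma` is summarized by the range
#' `mu +/- FWHM/2` with `FWHM = 2.355 sigma`, rounded half-up to integer nm.
#'
#' @param mu,sigma Component mean and sd in nm (vectorized).
#' @return Tibble with columns `lower`, `upper` (integer nm).
#' @export
#' @examples
#' population_range(247, 83) # 149--345
population_range <- function(mu, sigma) {
  half <- FWHM_FACTOR * sigma / 2
  tibble::tibble(lower = round_half_up(mu - half),
                 upper = round_half_up(mu + half))
}

#' Fit a population model to per-ROI parameter values
#'
#' Histograms a per-ROI parameter (such as `z_w`, `p_p` or `delta_fwhm`
#' pooled over many ROIs and cells) and fits the user-chosen model:
#' a mono-Gaussian, a bi-Gaussian, or a mono-exponential decay. Gaussian
#' components are reported with `mu`, `sigma` and the rounded
#' `mu +/- FWHM/2` range; the exponential is reported by `tau`, the inverse
#' decay constant (the distribution mean).
#'
#' @param values Numeric vector of per-ROI parameter values (>= 30).
#' @param model `"mono_gaussian"`, `"bi_gaussian"` or `"exponential"`.
#' @param bin_width Histogram bin width in nm (default 10).
#' @return An object of class `population_fit`: tibble of components with
#'   columns `component`, `mu`, `sigma`, `lower`, `upper` (Gaussians) or
#'   `tau` (exponential); the histogram is attached as attribute
#'   `histogram`.
#' @export
fit_population <- function(values,
                           model = c("mono_gaussian", "bi_gaussian", "exponential"),
                           bin_width = 10) {
  model <- match.arg(model)
  values <- values[is.finite(values)]
  if (length(values) < 30) abort("population fit needs at least 30 values")
  breaks <- seq(floor(min(values) / bin_width) * bin_width,
                max(values) + bin_width, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$counts)

  out <- switch(model,
    mono_gaussian = {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-0.5 * ((x - mu) / sigma)^2), data = df,
                          start = list(a = max(df$y), mu = mean(values), sigma = sd(values)),
                          lower = c(a = 0, mu = min(values), sigma = bin_width / 10)),
        error = function(e) abort("population fit (mono_gaussian) did not converge"))
      cf <- as.list(coef(fit))
      dplyr::bind_cols(tibble::tibble(component = 1L, mu = cf$mu, sigma = cf$sigma),
                       population_range(cf$mu, cf$sigma))
    },
    bi_gaussian = {
      prof <- tibble::tibble(z = df$x, count = df$y)
      fit <- tryCatch(fit_bigaussian(prof, s_bounds = c(bin_width / 10, diff(range(values)))),
                      error = function(e) abort("population fit (bi_gaussian) did not converge"))
      dplyr::bind_cols(
        tibble::tibble(component = c(1L, 2L),
                       mu = c(fit$m1, fit$m2), sigma = c(fit$s1, fit$s2)),
        population_range(c(fit$m1, fit$m2), c(fit$s1, fit$s2)))
    },
    exponential = {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ a * exp(-x / tau), data = df,
                          start = list(a = max(df$y), tau = mean(values)),
                          lower = c(a = 0, tau = bin_width / 10)),
        error = function(e) abort("population fit (exponential) did not converge"))
      cf <- as.list(coef(fit))
      tibble::tibble(component = 1L, tau = cf$tau)
    })
  attr(out, "model") <- model
  attr(out, "histogram") <- tibble::tibble(mid = h$mids, count = h$counts)
  attr(out, "n") <- length(values)
  class(out) <- c("population_fit", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.population_fit <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @exportS3Method generics::glance
glance.population_fit <- function(x, ...) {
  tibble::tibble(model = attr(x, "model"), n = attr(x, "n"),
                 n_components = nrow(x))
}
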