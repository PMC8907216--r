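#' Biplane optical response model
#'
#' Parametric model of the axially dependent fitted intensities of the two
#' detection planes. Each plane has a focal offset (`c1` transmitted, `c2`
#' reflected) and a common response width `w`; the response shape is a
#' Gaussian (default) or Lorentzian of the distance to the focal offset. A
#' single-molecule appearance with photon budget `photons` is split between
#' the channels in proportion to the two responses, so the contrast
#' \eqn{\gamma(z)} is determined by the response curves alone. For the default
#' Gaussian model with symmetric offsets,
#' \eqn{\gamma(z) = \tanh(z (c_2 - c_1) / (2 w^2))}, near-linear over roughly
#' the inter-focal distance.
#'
#' @param c1,c2 Focal-plane offsets in nm; `c1 < c2` (defaults -200, +200).
#' @param w Response width in nm (default 300).
#' @param shape `"gaussian"` or `"lorentzian"`.
#' @param photons Mean photon budget per appearance, both channels combined
#'   (default 2000).
#' @param background Background photons per pixel, used when rendering raw
#'   frames (default 0).
#' @return An object of class `optical_model`.
#' @export
optical_model <- function(c1 = -200, c2 = 200, w = 300,
                          shape = c("gaussian", "lorentzian"),
                          photons = 2000, background = 0) {
  shape <- match.arg(shape)
  if (!(c1 < c2)) abort("`c1` must be smaller than `c2`")
  check_number(w, "w", min = 1e-6)
  check_number(photons, "photons", min = 1)
  check_number(background, "background", min = 0)
  structure(list(c1 = c1, c2 = c2, w = w, shape = shape,
                 photons = photons, background = background),
            class = "optical_model")
}

# Unnormalized channel responses f1(z), f2(z) as a 2-column matrix.
channel_response <- function(model, z) {
  f <- switch(model$shape,
    gaussian = function(c) exp(-(z - c)^2 / (2 * model$w^2)),
    lorentzian = function(c) 1 / (1 + ((z - c) / model$w)^2)
  )
  cbind(f(model$c1), f(model$c2))
}

# Mean channel intensities: photon budget split by relative response.
channel_means <- function(model, z, photons = model$photons) {
  f <- channel_response(model, z)
  p1 <- f[, 1] / (f[, 1] + f[, 2])
  cbind(photons * p1, photons * (1 - p1))
}

#' Simulate a biplane calibration scan
#'
#' Emulates sweeping the focal plane linearly through a single-molecule
#' surface: at each stage z, `n_per_step` emitter appearances yield matched
#' transmitted/reflected intensity pairs drawn from the optical model,
#' optionally Poisson-perturbed.
#'
#' @param model An [optical_model()].
#' @param z_range Length-2 stage range in nm (default `c(-400, 400)`, i.e.
#'   the inter-focal distance of the default model).
#' @param z_step Stage step in nm (default 10).
#' @param n_per_step Appearances per stage position (default 25).
#' @param noise `"none"` or `"poisson"`.
#' @param seed Optional integer seed; fixed seed gives an identical scan.
#' @return Tibble with columns `z_stage`, `I1`, `I2`; the noiseless mean
#'   intensities are attached as columns of attribute `ground_truth`.
#' @export
simulate_calibration_scan <- function(model, z_range = c(-400, 400),
                                      z_step = 10, n_per_step = 25,
                                      noise = c("none", "poisson"),
                                      seed = NULL) {
  stopifnot(inherits(model, "optical_model"))
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  z <- rep(seq(z_range[1], z_range[2], by = z_step), each = n_per_step)
  mu <- channel_means(model, z)
  if (noise == "poisson") {
    I1 <- rpois(length(z), mu[, 1])
    I2 <- rpois(length(z), mu[, 2])
  } else {
    I1 <- mu[, 1]; I2 <- mu[, 2]
  }
  keep <- (I1 + I2) > 0
  out <- tibble::tibble(z_stage = z[keep], I1 = I1[keep], I2 = I2[keep])
  attr(out, "ground_truth") <- tibble::tibble(z_stage = z, mu1 = mu[, 1], mu2 = mu[, 2])
  out
}

#' Membrane surface model with protrusions
#'
#' Two-level surface emulating a lymphocyte membrane: a flat base and
#' protrusion tips at a higher axial level. A fraction of emitters sits on
#' tips, the rest on the base; every emitter gets Gaussian axial jitter.
#'
#' @param base_level Base membrane level in nm (default 0).
#' @param tip_level Protrusion tip level in nm (default 150, a typical tip
#'   height above the contact-plane base).
#' @param tip_density Tips per square micron (default 2).
#' @param tip_radius Lateral tip radius in nm (default 50, microvilli-like).
#' @param fraction_on_tips Fraction of emitters placed on tips (default 1).
#' @param axial_jitter Per-emitter axial sd in nm (default 25).
#' @return An object of class `surface_model`.
#' @export
surface_model <- function(base_level = 0, tip_level = 150, tip_density = 2,
                          tip_radius = 50, fraction_on_tips = 1,
                          axial_jitter = 25) {
  check_number(tip_density, "tip_density", min = 0)
  check_number(tip_radius, "tip_radius", min = 0)
  check_number(fraction_on_tips, "fraction_on_tips", min = 0, max = 1)
  check_number(axial_jitter, "axial_jitter", min = 0)
  structure(list(base_level = base_level, tip_level = tip_level,
                 tip_density = tip_density, tip_radius = tip_radius,
                 fraction_on_tips = fraction_on_tips,
                 axial_jitter = axial_jitter),
            class = "surface_model")
}

#' Simulate blinking membrane emitters as biplane localization tables
#'
#' Places emitters on a two-level membrane surface, schedules blink
#' appearances with geometric on-times (mean `mean_on` frames), and renders
#' each appearance as one localization per channel: lateral position plus
#' isotropic noise `sigma_xy`, biplane intensities from the optical model
#' evaluated at the emitter's true z plus injected drift and tilt, optionally
#' Poisson-noised. The reflected table can be displaced by a known affine
#' offset to exercise channel registration.
#'
#' @param surface A [surface_model()].
#' @param optical An [optical_model()].
#' @param n_frames Number of camera frames.
#' @param emitters_per_frame Mean active emitters per frame.
#' @param extent Lateral field side length in nm (default 10000).
#' @param sigma_xy Lateral localization noise sd in nm (default 10).
#' @param drift Function of frame giving axial drift in nm, or `NULL`.
#' @param tilt Length-2 plane slopes `c(a, b)` in nm per nm, or `NULL`.
#' @param noise `"poisson"` or `"none"` for the intensities.
#' @param mean_on Mean blink on-time in frames (default 3).
#' @param refl_offset Length-2 lateral offset in nm added to the reflected
#'   channel coordinates (default `c(0, 0)`).
#' @param seed Optional integer seed.
#' @return List with elements `transmitted`, `reflected` (localization
#'   tibbles) and `truth` (one row per appearance: emitter id, frame, true
#'   x/y/z, on-tip flag, effective z seen by the optics, mean intensities).
#' @export
simulate_membrane_locs <- function(surface, optical,
                                   n_frames = 2000, emitters_per_frame = 4,
                                   extent = 10000, sigma_xy = 10,
                                   drift = NULL, tilt = NULL,
                                   noise = c("poisson", "none"),
                                   mean_on = 3, refl_offset = c(0, 0),
                                   seed = NULL) {
  stopifnot(inherits(surface, "surface_model"), inherits(optical, "optical_model"))
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)

  # Emitter pool: enough emitters that, with geometric on-times, the expected
  # number of active emitters per frame matches the request.
  n_appearances <- n_frames * emitters_per_frame
  n_events <- max(1L, round(n_appearances / mean_on))

  area_um2 <- (extent / 1000)^2
  n_tips <- max(1L, rpois(1, surface$tip_density * area_um2))
  tips <- tibble::tibble(x = runif(n_tips, 0, extent), y = runif(n_tips, 0, extent))

  on_tip <- runif(n_events) < surface$fraction_on_tips
  ex <- runif(n_events, 0, extent)
  ey <- runif(n_events, 0, extent)
  tip_id <- sample.int(n_tips, n_events, replace = TRUE)
  ex[on_tip] <- tips$x[tip_id[on_tip]] + rnorm(sum(on_tip), 0, surface$tip_radius)
  ey[on_tip] <- tips$y[tip_id[on_tip]] + rnorm(sum(on_tip), 0, surface$tip_radius)
  ez <- ifelse(on_tip, surface$tip_level, surface$base_level) +
    rnorm(n_events, 0, surface$axial_jitter)

  start <- sample.int(n_frames, n_events, replace = TRUE) - 1L
  dur <- 1L + rgeom(n_events, 1 / mean_on)

  truth <- tibble::tibble(
    emitter = rep(seq_len(n_events), dur),
    frame = unlist(purrr::map2(start, dur, function(s, d) s + seq_len(d) - 1L)),
    x = rep(ex, dur), y = rep(ey, dur), z = rep(ez, dur),
    on_tip = rep(on_tip, dur)
  )
  truth <- truth[truth$frame < n_frames, , drop = FALSE]
  truth <- dplyr::arrange(truth, .data$frame, .data$emitter)

  z_eff <- truth$z
  if (!is.null(drift)) z_eff <- z_eff + drift(truth$frame)
  if (!is.null(tilt)) z_eff <- z_eff + tilt[1] * truth$x + tilt[2] * truth$y
  truth$z_effective <- z_eff

  mu <- channel_means(optical, z_eff)
  truth$mu1 <- mu[, 1]; truth$mu2 <- mu[, 2]
  n <- nrow(truth)
  if (noise == "poisson") {
    I1 <- rpois(n, mu[, 1]); I2 <- rpois(n, mu[, 2])
  } else {
    I1 <- mu[, 1]; I2 <- mu[, 2]
  }

  trans <- tibble::tibble(
    x = truth$x + rnorm(n, 0, sigma_xy),
    y = truth$y + rnorm(n, 0, sigma_xy),
    frame = truth$frame, intensity = I1, channel = "transmitted"
  )
  refl <- tibble::tibble(
    x = truth$x + rnorm(n, 0, sigma_xy) + refl_offset[1],
    y = truth$y + rnorm(n, 0, sigma_xy) + refl_offset[2],
    frame = truth$frame, intensity = I2, channel = "reflected"
  )
  list(transmitted = trans, reflected = refl, truth = truth)
}

#' Render localizations as raw biplane image frames
#'
#' Front-end for the fixed-width spot fitter: each appearance is drawn as an
#' integrated 2D Gaussian of the stated FWHM carrying its channel intensity,
#' on an optional Poisson background.
#'
#' @param locs Localization tibble (`x`, `y` nm, `frame`, `intensity`).
#' @param n_frames Number of frames in the stack.
#' @param size_px Frame side length in pixels.
#' @param pixel_size nm per pixel (default 100).
#' @param fwhm Spot FWHM in nm (default 300).
#' @param background Mean background photons per pixel (default 0).
#' @param noise Apply Poisson noise to the rendered frames (`"none"` keeps
#'   the expected counts).
#' @param seed Optional integer seed.
#' @return A 3D array `[x, y, frame]` of photon counts.
#' @export
simulate_frames <- function(locs, n_frames, size_px, pixel_size = 100,
                            fwhm = 300, background = 0,
                            noise = c("none", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(seed)
  sigma <- fwhm / FWHM_FACTOR / pixel_size # in pixels
  stack <- array(background, dim = c(size_px, size_px, n_frames))
  edges <- seq(0, size_px)
  for (k in seq_len(nrow(locs))) {
    f <- locs$frame[k] + 1L
    if (f < 1 || f > n_frames) next
    cx <- locs$x[k] / pixel_size
    cy <- locs$y[k] / pixel_size
    # integrated Gaussian over pixel areas (exact, conserves photons)
    px <- diff(stats::pnorm(edges, cx, sigma))
    py <- diff(stats::pnorm(edges, cy, sigma))
    stack[, , f] <- stack[, , f] + locs$intensity[k] * outer(px, py)
  }
  if (noise == "poisson") {
    stack <- array(rpois(length(stack), stack), dim = dim(stack))
  }
  stack
}
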