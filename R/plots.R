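# ggplot2 presentation layer. Each result type gets an autoplot() method so
# figures compose with the usual grammar.

#' @exportS3Method ggplot2::autoplot
autoplot.axial_lut <- function(object, ...) {
  p <- ggplot2::ggplot(lut_to_table(object),
                       ggplot2::aes(x = .data$z_nm, y = .data$gamma)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "z (nm)", y = expression(gamma),
                  title = "Axial lookup table")
  if (!is.null(object$bins)) {
    p <- p + ggplot2::geom_point(
      data = object$bins, ggplot2::aes(x = .data$z, y = .data$gamma),
      color = "grey40", size = 1)
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.drift_model <- function(object, ...) {
  tr <- object$trace
  tr$fit <- predict_drift(object, tr$frame)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$frame)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$z_med, size = .data$n),
                        alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), color = "red") +
    ggplot2::labs(x = "frame", y = "median z (nm)",
                  title = "Axial drift trace and polynomial fit")
}

#' @exportS3Method ggplot2::autoplot
autoplot.bigauss_fit <- function(object, ...) {
  prof <- object$profile
  grid <- tibble::tibble(z = seq(min(prof$z), max(prof$z), length.out = 400))
  grid$fit <- bigauss_eval(object, grid$z)
  g1 <- object$a1 * exp(-0.5 * ((grid$z - object$m1) / object$s1)^2)
  g2 <- object$a2 * exp(-0.5 * ((grid$z - object$m2) / object$s2)^2)
  comp <- tibble::tibble(z = rep(grid$z, 2), y = c(g1, g2),
                         component = rep(c("1", "2"), each = nrow(grid)))
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$z)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$count), fill = "grey80",
                      width = diff(prof$z[1:2]) * 0.9) +
    ggplot2::geom_line(data = comp,
                       ggplot2::aes(y = .data$y, color = .data$component),
                       linetype = 2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit), linewidth = 0.8) +
    ggplot2::labs(x = "z (nm)", y = "localizations",
                  title = "Axial profile and bi-Gaussian fit")
}

#' @exportS3Method ggplot2::autoplot
autoplot.population_fit <- function(object, ...) {
  h <- attr(object, "histogram")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "parameter (nm)", y = "ROIs",
                  title = sprintf("Population histogram (%s fit)", attr(object, "model")))
}

#' Axially color-coded localization image
#'
#' Renders the classic depth-coded view of a 3D localization set: hue maps
#' the per-pixel mean z, opacity the localization count.
#'
#' @param locs 3D localization tibble.
#' @param xy_pixel Lateral pixel size in nm (default 20).
#' @return A ggplot object.
#' @export
plot_colorcoded <- function(locs, xy_pixel = 20) {
  img <- render_colorcoded(locs, xy_pixel = xy_pixel)
  img$alpha <- pmin(1, img$n / quantile(img$n, 0.95))
  ggplot2::ggplot(img, ggplot2::aes(x = .data$x / 1000, y = .data$y / 1000)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$z_mean, alpha = .data$alpha)) +
    ggplot2::scale_fill_viridis_c(name = "z (nm)", option = "turbo") +
    ggplot2::scale_alpha_identity() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}
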