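#' Render localizations into a quantitative z-stack
#'
#' Bins 3D localizations onto a voxel grid (default 20 nm laterally and 20 nm
#' z separation); each voxel value is the number of localizations it
#' contains. Binning is half-open, `[k*s, (k+1)*s)`, so a coordinate exactly
#' on a bin edge belongs to the upper bin.
#'
#' @param locs 3D localization tibble (`x`, `y`, `z`).
#' @param xy_pixel Lateral pixel size in nm (default 20).
#' @param z_step Axial slice separation in nm (default 20).
#' @param z_range Optional length-2 axial range; localizations outside are
#'   dropped and counted in attribute `n_out_of_range`.
#' @return An object of class `zstack`: list with the 3D `counts` array
#'   (x, y, z), `origin` (nm), `xy_pixel`, `z_step`.
#' @export
render_zstack <- function(locs, xy_pixel = 20, z_step = 20, z_range = NULL) {
  require_columns(locs, c("x", "y", "z"))
  if (nrow(locs) == 0) abort("cannot render a z-stack from an empty table")
  check_number(xy_pixel, "xy_pixel", min = 1e-6)
  check_number(z_step, "z_step", min = 1e-6)

  n_oor <- 0L
  if (!is.null(z_range)) {
    keep <- locs$z >= z_range[1] & locs$z < z_range[2]
    n_oor <- sum(!keep)
    locs <- locs[keep, , drop = FALSE]
    if (nrow(locs) == 0) abort("no localization inside the requested z range")
  }
  ix <- floor(locs$x / xy_pixel); iy <- floor(locs$y / xy_pixel)
  iz <- floor(locs$z / z_step)
  x0 <- min(ix); y0 <- min(iy); z0 <- min(iz)
  dims <- c(max(ix) - x0 + 1L, max(iy) - y0 + 1L, max(iz) - z0 + 1L)
  counts <- array(0L, dim = dims)
  idx <- cbind(ix - x0 + 1L, iy - y0 + 1L, iz - z0 + 1L)
  tab <- table(idx[, 1] + dims[1] * ((idx[, 2] - 1L) + dims[2] * (idx[, 3] - 1L)))
  counts[as.integer(names(tab))] <- as.integer(tab)
  structure(list(counts = counts,
                 origin = c(x0 * xy_pixel, y0 * xy_pixel, z0 * z_step),
                 xy_pixel = xy_pixel, z_step = z_step,
                 n_out_of_range = n_oor),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<zstack> %d x %d px (%g nm) x %d z-slices (%g nm), %d localizations\n",
              d[1], d[2], x$xy_pixel, d[3], x$z_step, sum(x$counts)))
  invisible(x)
}

#' Color-coded 2D summary of a 3D localization set
#'
#' Collapses 3D localizations onto a lateral pixel grid, reporting the number
#' of localizations and their mean axial position per pixel; the companion
#' [plot_colorcoded()] renders this as the usual axially color-coded image
#' (hue = depth, brightness = counts).
#'
#' @param locs 3D localization tibble.
#' @param xy_pixel Lateral pixel size in nm (default 20).
#' @return Tibble with columns `x`, `y` (pixel centers, nm), `n`, `z_mean`.
#' @export
render_colorcoded <- function(locs, xy_pixel = 20) {
  require_columns(locs, c("x", "y", "z"))
  locs |>
    dplyr::mutate(px = floor(.data$x / xy_pixel), py = floor(.data$y / xy_pixel)) |>
    dplyr::summarise(n = dplyr::n(), z_mean = mean(.data$z), .by = c("px", "py")) |>
    dplyr::mutate(x = (.data$px + 0.5) * xy_pixel,
                  y = (.data$py + 0.5) * xy_pixel) |>
    dplyr::select("x", "y", "n", "z_mean")
}

#' Automatic master mask of the cell interior
#'
#' Stand-in for the manual cell-interior selection: thresholds the 2D
#' localization density image (default >= 1 localization per 100 nm pixel),
#' closes small holes morphologically, and erodes the result (default 1 um)
#' to spare the cell edges. Requires the EBImage package for the
#' morphological operations; a user-supplied logical mask can be passed to
#' [tile_rois()] directly instead.
#'
#' @param locs Localization tibble (`x`, `y`).
#' @param pixel_size Mask pixel size in nm (default 100).
#' @param min_count Density threshold per pixel (default 1).
#' @param erode_nm Erosion radius in nm (default 1000).
#' @return Logical matrix with attributes `pixel_size` and `origin` (nm).
#' @export
make_master_mask <- function(locs, pixel_size = 100, min_count = 1, erode_nm = 1000) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    abort("make_master_mask() needs the EBImage package; supply a logical mask instead")
  }
  require_columns(locs, c("x", "y"))
  ix <- floor(locs$x / pixel_size); iy <- floor(locs$y / pixel_size)
  x0 <- min(ix); y0 <- min(iy)
  dims <- c(max(ix) - x0 + 1L, max(iy) - y0 + 1L)
  img <- matrix(0L, dims[1], dims[2])
  tab <- table((ix - x0 + 1L) + dims[1] * (iy - y0))
  img[as.integer(names(tab))] <- as.integer(tab)
  bin <- img >= min_count
  brush_close <- EBImage::makeBrush(5, shape = "disc")
  closed <- EBImage::closing(EBImage::Image(bin * 1), brush_close)
  r_px <- max(1L, round(erode_nm / pixel_size))
  brush_erode <- EBImage::makeBrush(2L * r_px + 1L, shape = "disc")
  eroded <- EBImage::erode(closed, brush_erode)
  mask <- EBImage::imageData(eroded) > 0.5
  attr(mask, "pixel_size") <- pixel_size
  attr(mask, "origin") <- c(x0, y0) * pixel_size
  mask
}

#' Tile a master mask into square analysis ROIs
#'
#' Lays a regular, non-overlapping grid of square candidate ROIs (default
#' 2 x 2 um) anchored at the bounding box of the mask; a candidate is kept
#' when the mask covers more than `min_fraction` of its area (default 0.75),
#' and the retained ROI is clipped to the mask so it may be confined by the
#' master-ROI border.
#'
#' @param mask Logical matrix (TRUE = inside the master ROI) with optional
#'   attributes `pixel_size` (nm, default 20) and `origin` (nm).
#' @param roi_side ROI side length in nm (default 2000).
#' @param min_fraction Minimum mask coverage of a kept ROI (default 0.75).
#' @param pixel_size Mask pixel size in nm; overrides the attribute.
#' @return An object of class `roi_set`: tibble with columns `roi`, `x0`,
#'   `y0` (nm, ROI origin), `fraction`, and a list-column `pixels` of
#'   two-column pixel-index matrices (mask grid coordinates, clipped).
#' @export
tile_rois <- function(mask, roi_side = 2000, min_fraction = 0.75, pixel_size = NULL) {
  if (!is.matrix(mask) || !is.logical(mask)) abort("`mask` must be a logical matrix")
  if (!any(mask)) abort("master mask is empty")
  ps <- pixel_size %||% attr(mask, "pixel_size") %||% 20
  origin <- attr(mask, "origin") %||% c(0, 0)
  side_px <- max(1L, round(roi_side / ps))

  occ <- which(mask, arr.ind = TRUE)
  rx <- range(occ[, 1]); ry <- range(occ[, 2])
  starts_x <- seq(rx[1], rx[2], by = side_px)
  starts_y <- seq(ry[1], ry[2], by = side_px)

  rois <- tidyr::expand_grid(sx = starts_x, sy = starts_y) |>
    purrr::pmap(function(sx, sy) {
      ex <- min(sx + side_px - 1L, nrow(mask))
      ey <- min(sy + side_px - 1L, ncol(mask))
      sub <- mask[sx:ex, sy:ey, drop = FALSE]
      frac <- sum(sub) / (side_px^2)
      if (frac <= min_fraction) return(NULL)
      inside <- which(sub, arr.ind = TRUE)
      inside[, 1] <- inside[, 1] + sx - 1L
      inside[, 2] <- inside[, 2] + sy - 1L
      tibble::tibble(x0 = origin[1] + (sx - 1L) * ps,
                     y0 = origin[2] + (sy - 1L) * ps,
                     fraction = frac, pixels = list(inside))
    }) |>
    purrr::compact() |>
    dplyr::bind_rows()
  if (nrow(rois) == 0) abort("no ROI satisfies the coverage criterion")
  rois <- dplyr::mutate(rois, roi = dplyr::row_number(), .before = 1)
  attr(rois, "pixel_size") <- ps
  attr(rois, "origin") <- origin
  attr(rois, "roi_side") <- roi_side
  class(rois) <- c("roi_set", class(rois))
  rois
}

#' Axial localization profile of one ROI
#'
#' Accumulates the z-stack counts over the ROI's pixels, slice by slice,
#' giving the ROI's axial localization histogram at the stack's z step.
#'
#' @param zstack A [render_zstack()] result.
#' @param roi One row of a `roi_set` (or any list with `x0`, `y0` in nm), or
#'   `NULL` to use the whole stack.
#' @param roi_side ROI side length in nm (default 2000), used with `x0`/`y0`.
#' @return Tibble with columns `z` (bin centers, nm) and `count`.
#' @export
axial_profile <- function(zstack, roi = NULL, roi_side = 2000) {
  stopifnot(inherits(zstack, "zstack"))
  d <- dim(zstack$counts)
  if (is.null(roi)) {
    counts <- apply(zstack$counts, 3, sum)
  } else {
    x0 <- roi$x0; y0 <- roi$y0
    ix <- floor((x0 - zstack$origin[1]) / zstack$xy_pixel) + 1L
    iy <- floor((y0 - zstack$origin[2]) / zstack$xy_pixel) + 1L
    nx <- round(roi_side / zstack$xy_pixel)
    sel_x <- max(1L, ix):min(d[1], ix + nx - 1L)
    sel_y <- max(1L, iy):min(d[2], iy + nx - 1L)
    counts <- apply(zstack$counts[sel_x, sel_y, , drop = FALSE], 3, sum)
  }
  tibble::tibble(
    z = zstack$origin[3] + (seq_len(d[3]) - 0.5) * zstack$z_step,
    count = as.numeric(counts)
  )
}

#' Per-ROI axial quantification
#'
#' Convenience wrapper running [axial_profile()], [fit_bigaussian()] and
#' [compute_axial_params()] over every ROI of a set; non-converged ROIs are
#' flagged and excluded from downstream population statistics.
#'
#' @param zstack A [render_zstack()] result.
#' @param rois A `roi_set` from [tile_rois()].
#' @return Tibble with one row per ROI: the six bi-Gaussian parameters,
#'   `z_w`, `p_p`, `delta_fwhm`, `goodness`, `converged`.
#' @export
quantify_rois <- function(zstack, rois) {
  roi_side <- attr(rois, "roi_side") %||% 2000
  purrr::map(seq_len(nrow(rois)), function(k) {
    prof <- axial_profile(zstack, rois[k, ], roi_side = roi_side)
    fit <- tryCatch(fit_bigaussian(prof), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(roi = rois$roi[k], converged = FALSE))
    }
    params <- compute_axial_params(fit)
    dplyr::bind_cols(
      tibble::tibble(roi = rois$roi[k]),
      tidy_bigauss_row(fit), params,
      tibble::tibble(goodness = fit$goodness, converged = fit$converged)
    )
  }) |>
    dplyr::bind_rows()
}
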