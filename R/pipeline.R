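#' Default pipeline configuration
#'
#' All tunable parameters of the calibrate / localize / correct / quantify
#' chain with their defaults: fixed PSF FWHM 300 nm, 500-photon intensity
#' threshold, 1200 nm fit window, 25 nm calibration bins, 500 nm pairing
#' distance, refractive-index factor 1.0, drift polynomial order 6 over
#' 500-frame windows, 100 nm tilt pixels, 20 nm render pixels and z step,
#' 2 um ROIs kept above 75% coverage, 75 nm track budget.
#'
#' @param ... Named overrides of any default.
#' @return Named list of parameters (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fwhm_nm = 300, min_photons = 500, window_radius_nm = 1200,
    bin_width_nm = 25, poly_order = 7,
    max_dist_nm = 500, ri_factor = 1.0,
    drift_order = 6, drift_window = 500, tilt_pixel_nm = 100,
    xy_pixel_nm = 20, z_step_nm = 20,
    roi_side_nm = 2000, roi_min_fraction = 0.75,
    track_dist_nm = 75
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown pipeline parameter(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("fwhm_nm", "window_radius_nm", "bin_width_nm", "max_dist_nm",
           "ri_factor", "drift_window", "tilt_pixel_nm", "xy_pixel_nm",
           "z_step_nm", "roi_side_nm", "track_dist_nm")
  for (p in pos) check_number(cfg[[p]], p, min = 1e-9)
  check_number(cfg$min_photons, "min_photons", min = 0)
  check_number(cfg$roi_min_fraction, "roi_min_fraction", min = 0, max = 1)
  if (!cfg$poly_order %in% 3:11) abort("poly_order must be in 3..11")
  check_number(cfg$drift_order, "drift_order", min = 1, max = 12)
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys override [pipeline_config()] defaults.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full axial-nanotopography pipeline
#'
#' Executes the analysis chain in the required order: intensity filtering,
#' channel registration, framewise pairing, lookup-table z assignment,
#' refractive-index correction, axial drift correction, then tilt
#' correction (drift strictly before tilt), localization precision, and the
#' per-ROI axial quantification. Returns the corrected localizations, the
#' per-ROI table and a bookkeeping report in which every localization is
#' accounted for: `reads = 2 * pairs + unpaired` and
#' `pairs = z_assigned + gamma_out_of_range`.
#'
#' @param transmitted,reflected Localization tibbles of the two channels
#'   (or file paths readable by [read_localizations()]).
#' @param lut An `axial_lut` (or path to a LUT CSV written by
#'   [write_axial_lut()]).
#' @param config A [pipeline_config()].
#' @param mask Optional logical master mask for ROI tiling; `NULL` uses
#'   [make_master_mask()] when EBImage is available, otherwise the full
#'   field.
#' @param align Estimate the channel transform (default TRUE; set FALSE if
#'   the channels are already registered).
#' @return List of class `nanotopo_report`: `locs` (corrected 3D table),
#'   `rois` (per-ROI parameters), `precision`, `models` (transform, drift,
#'   tilt), `counts` (stage ledger), `config`.
#' @export
run_pipeline <- function(transmitted, reflected, lut,
                         config = pipeline_config(), mask = NULL,
                         align = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(transmitted)) transmitted <- read_localizations(transmitted)
  if (is.character(reflected)) reflected <- read_localizations(reflected)
  if (is.character(lut)) {
    if (!file.exists(lut)) abort(sprintf("LUT file not found: %s", lut))
    lut <- read_axial_lut(lut)
  }
  counts <- list(read_transmitted = nrow(transmitted), read_reflected = nrow(reflected))

  t1 <- validate_table(transmitted, config$min_photons, quiet = TRUE)
  t2 <- validate_table(reflected, config$min_photons, quiet = TRUE)
  counts$below_threshold <- attr(t1, "n_removed") + attr(t2, "n_removed")

  transform <- if (align) estimate_channel_transform(t1, t2) else NULL
  pairs <- pair_localizations(t1, t2, transform, max_dist = config$max_dist_nm)
  counts$pairs <- nrow(pairs)
  counts$unpaired <- attr(pairs, "n_unpaired_transmitted") +
    attr(pairs, "n_unpaired_reflected")

  zp <- assign_z(pairs, lut, quiet = TRUE)
  counts$gamma_out_of_range <- attr(zp, "n_out_of_range")
  counts$z_assigned <- nrow(zp)
  locs <- correct_refractive_index(zp, config$ri_factor)

  locs <- correct_axial_drift(locs, poly_order = config$drift_order,
                              window = config$drift_window)
  drift <- attr(locs, "drift_model")
  tilt <- fit_tilt_plane(locs, pixel_size = config$tilt_pixel_nm)
  locs <- correct_tilt(locs, tilt)

  precision <- tryCatch(
    estimate_localization_precision(locs, max_track_dist = config$track_dist_nm),
    error = function(e) NULL)

  zstack <- render_zstack(locs, xy_pixel = config$xy_pixel_nm,
                          z_step = config$z_step_nm)
  if (is.null(mask)) {
    d <- dim(zstack$counts)
    mask <- matrix(TRUE, d[1], d[2])
    attr(mask, "pixel_size") <- config$xy_pixel_nm
    attr(mask, "origin") <- zstack$origin[1:2]
  }
  rois <- tile_rois(mask, roi_side = config$roi_side_nm,
                    min_fraction = config$roi_min_fraction)
  roi_tab <- quantify_rois(zstack, rois)
  counts$rois = nrow(roi_tab)
  counts$rois_converged <- sum(roi_tab$converged)

  structure(list(locs = locs, rois = roi_tab, precision = precision,
                 models = list(transform = transform, drift = drift, tilt = tilt),
                 counts = counts, config = unclass(config)),
            class = "nanotopo_report")
}

#' @export
print.nanotopo_report <- function(x, ...) {
  cat("<nanotopo_report>\n")
  cat(sprintf("  localizations: %d transmitted + %d reflected -> %d pairs -> %d with z\n",
              x$counts$read_transmitted, x$counts$read_reflected,
              x$counts$pairs, x$counts$z_assigned))
  cat(sprintf("  ROIs: %d (%d converged)\n", x$counts$rois, x$counts$rois_converged))
  if (!is.null(x$precision)) {
    cat(sprintf("  precision (nm): x %.1f, y %.1f, z %.1f over %d tracks\n",
                x$precision$sigma_x, x$precision$sigma_y, x$precision$sigma_z,
                x$precision$n_tracks))
  }
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report A `nanotopo_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nanotopo_report"))
  out <- list(
    counts = report$counts,
    precision = if (!is.null(report$precision)) as.list(report$precision),
    drift = if (!is.null(report$models$drift)) {
      m <- report$models$drift
      list(poly_order = m$poly_order, window = m$window, rms = m$rms,
           coefficients = m$coefficients)
    },
    tilt = if (!is.null(report$models$tilt)) {
      m <- report$models$tilt
      list(a = m$a, b = m$b, c = m$c, n_pixels = m$n_pixels)
    },
    transform = if (!is.null(report$models$transform)) {
      m <- report$models$transform
      list(translation = m$t, scale = m$scale, rms = m$rms, n_pairs = m$n_pairs)
    },
    config = report$config
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
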