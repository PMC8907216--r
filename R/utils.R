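# Internal helpers shared across modules.

# Round half away from zero (Table-style range arithmetic), not banker's
# rounding as in base round().
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Gaussian FWHM <-> sigma conversion constant, 2*sqrt(2*log(2)) to the
# field's customary 3 decimals.
FWHM_FACTOR <- 2.355

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# Normalize a localization table to internal column names x, y, frame,
# intensity (+ optional z). Accepts the on-disk aliases x_nm, y_nm,
# intensity_photons, z_nm.
normalize_loc_columns <- function(df) {
  aliases <- c(x_nm = "x", y_nm = "y", intensity_photons = "intensity", z_nm = "z")
  for (ext in names(aliases)) {
    int <- aliases[[ext]]
    if (ext %in% names(df) && !(int %in% names(df))) {
      names(df)[names(df) == ext] <- int
    }
  }
  df
}

require_columns <- function(df, cols, what = "localization table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
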