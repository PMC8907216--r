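#' Read a single-molecule localization table
#'
#' Reads a per-emitter localization table as produced by SMLM fitting software.
#' Two dialects are supported: plain CSV with columns `x_nm`, `y_nm`, `frame`,
#' `intensity` (or `intensity_photons`), and the whitespace-separated text
#' format written by rapidSTORM, whose first line is an XML-like header that
#' declares the column semantics via `identifier` attributes
#' (`Position-0-0` = x, `Position-1-0` = y, `ImageNumber-0-0` = frame,
#' `Amplitude-0-0` = fitted intensity).
#'
#' All coordinates are held in nanometers internally. If the source file is in
#' camera pixels, pass `pixel_size` to convert x and y on ingest.
#'
#' @param path Path to the localization file.
#' @param dialect `"csv"` or `"rapidstorm_text"`.
#' @param pixel_size Optional nm-per-pixel factor applied to x and y when the
#'   source stores pixel coordinates. Default `NULL` means coordinates are
#'   already in nm.
#' @param channel Optional channel label (`"transmitted"` or `"reflected"`)
#'   attached to every record.
#'
#' @return A tibble with columns `x`, `y` (nm), `frame` (0-based integer),
#'   `intensity` (photons) and, when present in the file, `z` (nm) and
#'   `channel`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("x_nm,y_nm,frame,intensity", "10,20,0,1500", "30,40,1,800"), f)
#' read_localizations(f)
read_localizations <- function(path,
                               dialect = c("csv", "rapidstorm_text"),
                               pixel_size = NULL,
                               channel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("localization file not found: %s", path))

  if (dialect == "csv") {
    tab <- read_locs_csv(path)
  } else {
    tab <- read_locs_rapidstorm(path)
  }

  if (!is.null(pixel_size)) {
    check_number(pixel_size, "pixel_size", min = 1e-6)
    tab$x <- tab$x * pixel_size
    tab$y <- tab$y * pixel_size
  }
  if (!is.null(channel)) tab$channel <- channel

  bad <- !is.finite(tab$x) | !is.finite(tab$y) | tab$frame < 0
  if (any(bad)) abort("localization table contains non-finite coordinates or negative frames")
  tab
}

read_locs_csv <- function(path) {
  # na = character(): literal "NA" cells are parse failures, not silent NAs,
  # so a corrupt cell is reported with its line number.
  tab <- suppressWarnings(readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_double()),
    na = character(), progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(tab)
  if (nrow(probs) > 0) {
    # readr reports rows counted from the top of the file (header included),
    # so the row number is already the file line number.
    abort(sprintf("parse error in %s at line %d (column %d): expected a number",
                  path, probs$row[[1]], probs$col[[1]]))
  }
  tab <- normalize_loc_columns(tab)
  require_columns(tab, c("x", "y", "frame", "intensity"), what = path)
  keep <- intersect(c("x", "y", "frame", "intensity", "z", "channel"), names(tab))
  tab <- tibble::as_tibble(tab[keep])
  tab$frame <- as.integer(tab$frame)
  tab
}

read_locs_rapidstorm <- function(path) {
  header <- readLines(path, n = 1L)
  ids <- regmatches(header, gregexpr('identifier="[^"]+"', header))[[1]]
  ids <- gsub('identifier="|"', "", ids)
  if (length(ids) == 0) {
    abort(sprintf("%s: first line is not a rapidSTORM field header", path))
  }
  semantics <- c("Position-0-0" = "x", "Position-1-0" = "y",
                 "ImageNumber-0-0" = "frame", "Amplitude-0-0" = "intensity",
                 "Position-2-0" = "z")
  cols <- unname(semantics[ids])
  cols[is.na(cols)] <- paste0("extra", seq_len(sum(is.na(cols))))
  for (mandatory in c("x", "y", "frame", "intensity")) {
    if (!mandatory %in% cols) {
      abort(sprintf("%s: rapidSTORM header lacks mandatory field for '%s'",
                    path, mandatory))
    }
  }
  body <- readLines(path)[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) {
    return(tibble::tibble(x = double(), y = double(),
                          frame = integer(), intensity = double()))
  }
  fields <- strsplit(trimws(body), "[[:space:]]+")
  n_bad <- which(lengths(fields) != length(cols))
  if (length(n_bad) > 0) {
    abort(sprintf("%s: line %d has %d fields, header declares %d",
                  path, n_bad[[1]] + 1L, lengths(fields)[n_bad[[1]]], length(cols)))
  }
  mat <- matrix(unlist(fields), ncol = length(cols), byrow = TRUE)
  num <- suppressWarnings(array(as.numeric(mat), dim = dim(mat)))
  if (anyNA(num)) {
    bad <- which(apply(is.na(num), 1, any))[[1]]
    abort(sprintf("parse error in %s at line %d: expected a number", path, bad + 1L))
  }
  tab <- tibble::as_tibble(setNames(as.data.frame(num), cols))
  tab <- tab[intersect(c("x", "y", "frame", "intensity", "z"), cols)]
  tab$frame <- as.integer(tab$frame)
  tab[c("x", "y", "frame", "intensity", intersect("z", names(tab)))]
}

#' Write a localization table to CSV
#'
#' Emits the canonical on-disk form with columns
#' `x_nm,y_nm,frame,intensity_photons` and, when the table carries axial
#' coordinates, `z_nm`. A read of the written file reproduces all numeric
#' fields to at least 6 significant digits (readr writes full precision).
#'
#' @param locs Localization tibble (columns `x`, `y`, `frame`, `intensity`,
#'   optionally `z`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(locs, path) {
  require_columns(locs, c("x", "y", "frame", "intensity"))
  out <- tibble::tibble(
    x_nm = locs$x, y_nm = locs$y,
    frame = locs$frame, intensity_photons = locs$intensity
  )
  if ("z" %in% names(locs)) out$z_nm <- locs$z
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Filter localizations by minimum fitted intensity
#'
#' Applies the lower photon threshold used when fitting with a fixed PSF
#' width (default 500 photons), dropping dim localizations whose intensity
#' ratio would be noise-dominated. The operation preserves record order and
#' is idempotent.
#'
#' @param locs Localization tibble.
#' @param min_intensity Minimum fitted intensity in photons (default 500).
#' @param quiet Suppress the message reporting how many records were removed.
#' @return The filtered tibble; the number of removed records is attached as
#'   attribute `n_removed`.
#' @export
validate_table <- function(locs, min_intensity = 500, quiet = FALSE) {
  require_columns(locs, c("x", "y", "frame", "intensity"))
  check_number(min_intensity, "min_intensity", min = 0)
  keep <- is.finite(locs$intensity) & locs$intensity > 0 &
    locs$intensity >= min_intensity &
    is.finite(locs$x) & is.finite(locs$y) & locs$frame >= 0
  out <- locs[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (!quiet && n_removed > 0) {
    inform(sprintf("validate_table: removed %d of %d records below %g photons",
                   n_removed, length(keep), min_intensity))
  }
  attr(out, "n_removed") <- n_removed
  out
}
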