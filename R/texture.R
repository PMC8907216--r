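#' Convert an image matrix to 8-bit gray levels
#'
#' Min--max rescales a numeric matrix to integer gray values 0..255. Images
#' that are already integer-valued in that range pass through unchanged only
#' if they span it; the rescale is always applied so downstream thresholds
#' see a full dynamic range.
#'
#' @param img Numeric matrix.
#' @return Integer matrix with values in 0..255.
#' @export
as_gray8 <- function(img) {
  if (!is.matrix(img) || !is.numeric(img)) abort("`img` must be a numeric matrix")
  rng <- range(img)
  if (diff(rng) == 0) {
    out <- matrix(0L, nrow(img), ncol(img))
  } else {
    out <- matrix(as.integer(round_half_up((img - rng[1]) / diff(rng) * 255)),
                  nrow(img), ncol(img))
  }
  out
}

#' ISODATA intensity threshold
#'
#' Iterative threshold selection: starting from the global mean, the
#' threshold is repeatedly moved to the midpoint of the mean gray value below
#' and the mean at-or-above it, until it converges. Used to zero the
#' background before texture analysis: all values strictly below the
#' converged threshold are set to 0 by [homogeneity_score()].
#'
#' @param img Numeric matrix with at least two distinct values.
#' @return The converged threshold (possibly fractional).
#' @export
#' @examples
#' isodata_threshold(matrix(c(1, 1, 1, 10, 10, 10), 2)) # 5.5
isodata_threshold <- function(img) {
  v <- as.numeric(img)
  if (length(unique(v)) < 2) {
    abort("ISODATA threshold undefined: image has a single gray level")
  }
  t_cur <- mean(v)
  for (it in 1:100) {
    lo <- v[v < t_cur]; hi <- v[v >= t_cur]
    if (length(lo) == 0 || length(hi) == 0) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < 1e-9) { t_cur <- t_new; break }
    t_cur <- t_new
  }
  t_cur
}

# Pixel displacement (drow, dcol) for a GLCM angle at unit offset; matches
# the usual image-processing convention (angle 0 horizontal, pi/2 vertical,
# pi/4 and 3pi/4 the two diagonals).
glcm_displacement <- function(angle, offset = 1) {
  c(round(offset * sin(angle)), round(offset * cos(angle)))
}

#' Gray-level co-occurrence matrix of a background-zeroed image
#'
#' Counts ordered co-occurring gray-level pairs at the given pixel offset and
#' angle, then removes every pair involving gray value 0 (the zeroed
#' background row and column) and normalizes to total 1. If no pair survives
#' the background removal the matrix is flagged empty.
#'
#' @param img Integer matrix of gray levels 0..255 (background already set
#'   to 0, see [isodata_threshold()]).
#' @param angle One of `0`, `pi/4`, `pi/2`, `3*pi/4`.
#' @param offset Pixel offset (default 1).
#' @return A 256 x 256 matrix summing to 1, or with attribute `empty = TRUE`
#'   when no non-background pair exists.
#' @export
compute_glcm <- function(img, angle, offset = 1) {
  if (!is.matrix(img) || nrow(img) < 1 || ncol(img) < 1) abort("`img` must be a matrix")
  if (any(img < 0 | img > 255)) abort("gray levels must lie in 0..255")
  d <- glcm_displacement(angle, offset)
  nr <- nrow(img); nc <- ncol(img)
  rows <- seq_len(nr); cols <- seq_len(nc)
  r_ok <- rows[rows + d[1] >= 1 & rows + d[1] <= nr]
  c_ok <- cols[cols + d[2] >= 1 & cols + d[2] <= nc]
  glcm <- matrix(0, 256, 256)
  attr(glcm, "empty") <- TRUE
  if (length(r_ok) == 0 || length(c_ok) == 0) return(glcm)
  from <- img[r_ok, c_ok, drop = FALSE]
  to <- img[r_ok + d[1], c_ok + d[2], drop = FALSE]
  keep <- from != 0 & to != 0
  if (!any(keep)) return(glcm)
  tab <- table(factor(from[keep], levels = 0:255), factor(to[keep], levels = 0:255))
  glcm <- unclass(tab) / sum(tab)
  dimnames(glcm) <- NULL
  attr(glcm, "empty") <- FALSE
  glcm
}

#' GLCM homogeneity score of a fluorescence image
#'
#' Quantifies how evenly a fluorescence signal is distributed over a cell
#' contact: the image is converted to 8-bit, background is zeroed with the
#' ISODATA threshold, and for each of the four directions (0, pi/4, pi/2,
#' 3pi/4 at unit offset) the normalized co-occurrence matrix is weighted by
#' the inverse gray-level difference and summed. The score is the mean over
#' the four directions; directions whose matrix is empty after background
#' removal contribute 0. A score of 1 means every counted pixel pair has
#' identical gray levels in all four directions.
#'
#' @param img Numeric image matrix.
#' @param weight `"abs_diff"` for \eqn{1/(1 + |i - j|)} (the standard
#'   inverse-difference homogeneity weight, default) or `"sq_diff"` for
#'   \eqn{1/(1 + (i - j)^2)}.
#' @param offset Pixel offset (default 1).
#' @return Homogeneity score in \eqn{[0, 1]}.
#' @export
homogeneity_score <- function(img, weight = c("abs_diff", "sq_diff"), offset = 1) {
  weight <- match.arg(weight)
  g <- as_gray8(img)
  thr <- isodata_threshold(g)
  g[g < thr] <- 0L

  idx <- 0:255
  dif <- abs(outer(idx, idx, "-"))
  w <- if (weight == "abs_diff") 1 / (1 + dif) else 1 / (1 + dif^2)

  angles <- c(0, pi / 4, pi / 2, 3 * pi / 4)
  vals <- vapply(angles, function(a) {
    glcm <- compute_glcm(g, a, offset)
    if (isTRUE(attr(glcm, "empty"))) 0 else sum(glcm * w)
  }, numeric(1))
  mean(vals)
}
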