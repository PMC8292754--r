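#' Spot constellations
#'
#' A `spotset` is an ordered collection of spots, each with an `x`, `y`
#' position and a `size` (area in squared pixels before normalization, in
#' squared fish-length units after). Coordinates follow the image convention:
#' x to the right, y downwards, 0-based pixel centres. After normalization
#' (see [pca_align()]) positions are expressed in fish-length units, with the
#' x range spanning approximately \[0, 1\].
#'
#' @param x,y numeric vectors of spot positions.
#' @param size numeric vector of spot sizes (areas); must be positive.
#' @param frame integer-ish `c(width, height)` of the source frame, or `NULL`.
#' @param normalized logical; `TRUE` once coordinates are in fish-length units.
#' @param length_scale pixels per fish-length unit (`NA` before normalization).
#'
#' @return An object of class `spotset`.
#' @examples
#' s <- spotset(x = c(10, 20), y = c(5, 8), size = c(12, 9), frame = c(100, 50))
#' as.data.frame(s)
#' @export
spotset <- function(x = numeric(), y = numeric(), size = numeric(),
                    frame = NULL, normalized = FALSE, length_scale = NA_real_) {
  x <- as.numeric(x); y <- as.numeric(y); size <- as.numeric(size)
  if (length(size) == 0L && length(x) > 0L) size <- rep(1, length(x))
  if (length(x) != length(y) || length(x) != length(size))
    stop_spotmatch("x, y and size must have equal length",
                   "spotmatch_invalid_argument")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_spotmatch("spot coordinates must be finite",
                   "spotmatch_invalid_argument")
  if (any(size <= 0))
    stop_spotmatch("spot sizes must be positive", "spotmatch_invalid_argument")
  structure(
    list(x = x, y = y, size = size,
         frame = if (!is.null(frame)) as.numeric(frame) else NULL,
         normalized = isTRUE(normalized),
         length_scale = as.numeric(length_scale)),
    class = "spotset")
}

#' @export
print.spotset <- function(x, ...) {
  cat(sprintf("<spotset: %d spots, %s>\n", n_spots(x),
              if (x$normalized) "normalized (fish-length units)" else "pixel coordinates"))
  invisible(x)
}

#' @export
as.data.frame.spotset <- function(x, ...) {
  data.frame(x = x$x, y = x$y, size = x$size)
}

#' Number of spots in a spotset
#' @param spots a [spotset()].
#' @return integer count.
#' @export
n_spots <- function(spots) length(spots$x)

# subset a spotset by index, keeping metadata
subset_spots <- function(spots, idx) {
  spotset(spots$x[idx], spots$y[idx], spots$size[idx], frame = spots$frame,
          normalized = spots$normalized, length_scale = spots$length_scale)
}
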