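# Lossless plateau compression: maximal runs of identical counts collapse to
# a single weighted observation. There always exists an optimal segmentation
# with no change-point strictly inside a plateau, so the optimal cost is
# unchanged while the sweep length can shrink dramatically (RNA-seq coverage
# is dominated by long zero runs between transcribed regions).

#' Run-length compress a count series into weighted plateaux
#'
#' @param y numeric vector of observations.
#' @return an object of class `plateau_map` with fields `values`, `weights`
#'   (positive integers summing to `length(y)`) and `offsets` (1-based
#'   original start position of each run).
#' @examples
#' compress_series(c(5, 5, 5, 2, 2, 7))
#' @export
compress_series <- function(y) {
  if (length(y) == 0L) stop("empty series")
  r <- rle(as.numeric(y))
  structure(list(values = r$values,
                 weights = as.integer(r$lengths),
                 offsets = c(1L, 1L + cumsum(r$lengths)[-length(r$lengths)])),
            class = "plateau_map")
}

#' @export
print.plateau_map <- function(x, ...) {
  cat(sprintf("<plateau_map> %d points compressed to %d (factor %.2f)\n",
              sum(x$weights), length(x$values),
              sum(x$weights) / length(x$values)))
  invisible(x)
}

#' Expand a plateau map back to the original series
#'
#' @param map a [compress_series()] result.
#' @return the original numeric vector.
#' @export
decompress_series <- function(map) {
  stopifnot(inherits(map, "plateau_map"))
  rep(map$values, map$weights)
}

#' Lift breakpoints from compressed to original coordinates
#'
#' A breakpoint after compressed point i maps to the end of that run in the
#' original series (1-based inclusive-end convention). When an optimal
#' breakpoint abuts a plateau this places it on the downstream side of the
#' run, which never increases the cost.
#'
#' @param breaks integer vector of breakpoints in compressed coordinates
#'   (indices of compressed points after which a segment ends).
#' @param map a `plateau_map`.
#' @return breakpoints in original coordinates.
#' @export
map_breakpoints_to_original <- function(breaks, map) {
  stopifnot(inherits(map, "plateau_map"))
  if (length(breaks) == 0L) return(integer(0))
  breaks <- as.integer(breaks)
  if (any(breaks < 1L | breaks > length(map$values)))
    stop("breakpoint index outside the compressed series")
  ends <- cumsum(map$weights)
  ends[breaks]
}
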