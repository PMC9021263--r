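#' Genomic interval (0-based half-open)
#'
#' All coordinates inside the package are 0-based half-open. Every number a
#' user sees in a report, VCF or call object is 1-based inclusive; the single
#' conversion point is [to_report_coords()].
#'
#' @param chrom Sequence identifier.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @return An object of class `"gi"`: a list with `chrom`, `start`, `end`.
#' @examples
#' gi("chr12", 45504426, 45517614)
#' @export
gi <- function(chrom, start, end) {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("interval start/end must be single non-missing numbers")
  if (start < 0) stop("interval start must be >= 0")
  if (start >= end) stop("interval requires start < end (0-based half-open), got [",
                         start, ", ", end, ")")
  structure(list(chrom = chrom, start = start, end = end), class = "gi")
}

#' @export
print.gi <- function(x, ...) {
  r <- to_report_coords(x)
  cat(sprintf("<gi> %s:%s-%s (1-based; length %d)\n", r$chrom,
              format(r$start, big.mark = ","), format(r$end, big.mark = ","),
              gi_length(x)))
  invisible(x)
}

#' Interval length in bases
#' @param interval A [gi()] interval.
#' @return Integer length `end - start`.
#' @export
gi_length <- function(interval) {
  stopifnot(inherits(interval, "gi"))
  as.integer(interval$end - interval$start)
}

#' Convert an internal interval to reporting (1-based inclusive) coordinates
#'
#' The inverse of [from_report_coords()]. Interval length is invariant under
#' the conversion.
#'
#' @param interval A [gi()] interval.
#' @return List with `chrom`, `start`, `end` (1-based inclusive) and `length`.
#' @examples
#' to_report_coords(gi("chr12", 45504426, 45517614))  # 45,504,427..45,517,614
#' @export
to_report_coords <- function(interval) {
  stopifnot(inherits(interval, "gi"))
  list(chrom = interval$chrom, start = interval$start + 1, end = interval$end,
       length = gi_length(interval))
}

#' Convert 1-based inclusive reporting coordinates to an internal interval
#' @param chrom Sequence identifier.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return A [gi()] interval.
#' @export
from_report_coords <- function(chrom, start, end) {
  gi(chrom, start - 1, end)
}
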