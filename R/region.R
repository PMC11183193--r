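# 1-based inclusive coordinate intervals with negative-index support,
# as used by faidx, range and the amplicon region spec.  A negative
# coordinate k counts from the end of a length-L sequence: L + k + 1,
# so -1 is the last base.

#' Construct a region
#'
#' @param name sequence identifier the region refers to ("" when the
#'   region stands alone, e.g. a record range).
#' @param begin,end signed 1-based inclusive coordinates; negative
#'   values count from the end (-1 = last base).  Zero is invalid.
#' @return object of class `seq_region`.
#' @export
region <- function(name, begin = 1L, end = -1L) {
  begin <- as.integer(begin); end <- as.integer(end)
  if (is.na(begin) || is.na(end) || begin == 0L || end == 0L) {
    stop_region("region coordinates must be nonzero integers")
  }
  structure(list(name = name, begin = begin, end = end), class = "seq_region")
}

#' Parse a region string
#'
#' Grammar: `"name:begin-end"` (either coordinate may be negative, e.g.
#' `"chr:-4--1"` for the last four bases) or just `"name"` for the whole
#' sequence.
#'
#' @param x region string.
#' @return a `seq_region`.
#' @examples
#' parse_region("s1:2-5")
#' parse_region("s1:-4--1")
#' parse_region("s1")
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^(.+):(-?[0-9]+)-(-?[0-9]+)$", x))[[1L]]
  if (length(m) == 4L) {
    region(m[2L], as.integer(m[3L]), as.integer(m[4L]))
  } else if (!grepl(":", x) && nzchar(x)) {
    region(x, 1L, -1L)
  } else {
    stop_region("cannot parse region string '%s'", x)
  }
}

#' Resolve signed region coordinates against a sequence length
#'
#' @param begin,end signed 1-based coordinates (negative = from the end).
#' @param length sequence length L (>= 1).
#' @param clip when TRUE, out-of-range resolved coordinates are clamped
#'   to \[1, L\] instead of raising an error (still errors if the clamped
#'   interval is empty).
#' @return integer vector `c(begin, end)` with 1 <= begin <= end <= L.
#' @examples
#' resolve_region(1, -1, 10)   # c(1, 10)
#' resolve_region(-4, -1, 12)  # c(9, 12)
#' @export
resolve_region <- function(begin, end, length, clip = FALSE) {
  stopifnot(length >= 1L)
  b <- if (begin < 0) length + begin + 1L else begin
  e <- if (end < 0) length + end + 1L else end
  if (clip) {
    b <- max(1L, b); e <- min(length, e)
  }
  if (b > e || b < 1L || e > length) {
    stop_region("region %d..%d resolves to %d..%d, outside 1..%d",
                begin, end, b, e, length)
  }
  c(as.integer(b), as.integer(e))
}
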