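# Online monitoring of read properties.  The accumulator keeps fixed
# bin edges, per-bin counts and running moments, so memory is bounded
# by the bin count no matter how long the stream is.  Bin edges are
# fixed up front from (min, max); observations outside clamp to the end
# bins, keeping sum(counts) == n.

.watch_defaults <- list(
  length       = c(0, 10000),
  mean_quality = c(0, 60),
  gc_content   = c(0, 1)
)

#' Mean quality of a read from its Phred+33 string
#'
#' Aggregates by averaging error probabilities, not quality scores:
#' `-10 * log10(mean(10^(-Q/10)))`.  This is the aggregation that
#' reflects the read's actual expected error rate; the arithmetic mean
#' of Q overstates quality whenever scores vary.
#'
#' @param qual nonempty Phred+33 quality string.
#' @return quality on the Phred scale.
#' @examples
#' read_mean_quality("II")  # 40
#' read_mean_quality("!I")  # ~3.01: one terrible base dominates
#' @export
read_mean_quality <- function(qual) {
  if (!nzchar(qual)) stop_data("read_mean_quality: empty quality string")
  q <- quality_scores(qual)
  -10 * log10(mean(10^(-q / 10)))
}

#' Create a streaming histogram accumulator
#'
#' @param property one of `"length"`, `"mean_quality"`, `"gc_content"`.
#' @param bins number of equal-width bins.
#' @param range numeric `c(min, max)` fixing the bin edges; defaults per
#'   property: length 0–10000, mean_quality 0–60, gc_content 0–1.
#' @return environment of class `stream_histogram`.
#' @export
stream_histogram <- function(property = c("length", "mean_quality", "gc_content"),
                             bins = 30L, range = NULL) {
  property <- match.arg(property)
  if (is.null(range)) range <- .watch_defaults[[property]]
  stopifnot(bins >= 1L, range[2L] > range[1L])
  h <- new.env(parent = emptyenv())
  h$property <- property
  h$edges <- seq(range[1L], range[2L], length.out = bins + 1L)
  h$counts <- integer(bins)
  h$n <- 0L
  h$sum <- 0; h$sum_sq <- 0
  h$min_seen <- Inf; h$max_seen <- -Inf
  class(h) <- "stream_histogram"
  h
}

hist_update <- function(h, value) {
  bin <- findInterval(value, h$edges, rightmost.closed = TRUE)
  bin <- min(max(bin, 1L), length(h$counts))  # clamp outside values
  h$counts[bin] <- h$counts[bin] + 1L
  h$n <- h$n + 1L
  h$sum <- h$sum + value
  h$sum_sq <- h$sum_sq + value * value
  h$min_seen <- min(h$min_seen, value)
  h$max_seen <- max(h$max_seen, value)
  invisible(h)
}

hist_mean <- function(h) if (h$n > 0L) h$sum / h$n else NaN

hist_sd <- function(h) {
  if (h$n < 2L) return(NaN)
  v <- (h$sum_sq - h$sum^2 / h$n) / (h$n - 1L)
  sqrt(max(v, 0))
}

#' Render a streaming histogram as fixed-width text
#'
#' @param h a [stream_histogram()].
#' @param width bar width in characters for the fullest bin.
#' @return character vector of lines.
#' @export
hist_render <- function(h, width = 40L) {
  top <- max(h$counts, 1L)
  bars <- vapply(h$counts, function(cnt) {
    strrep("█", round(width * cnt / top))
  }, "")
  lines <- sprintf("%10.4g-%-10.4g |%-*s %d",
                   h$edges[-length(h$edges)], h$edges[-1L], width, bars, h$counts)
  c(sprintf("[%s] n=%d mean=%.4g sd=%.4g min=%.4g max=%.4g",
            h$property, h$n, hist_mean(h), hist_sd(h),
            if (is.finite(h$min_seen)) h$min_seen else NA,
            if (is.finite(h$max_seen)) h$max_seen else NA),
    lines)
}

hist_tsv <- function(h) {
  data.frame(bin_low = h$edges[-length(h$edges)],
             bin_high = h$edges[-1L],
             count = h$counts)
}

#' Watch a property of a record stream
#'
#' Tallies one value per record into a [stream_histogram()], rendering
#' the histogram (with n/mean/sd/min/max) to the diagnostic stream every
#' `print_every` records and at end of stream.  Periodicity affects
#' rendering only — final tallies are identical for any `print_every`.
#'
#' @param records list of [seq_record()]s.
#' @param property `"length"`, `"mean_quality"` (FASTQ only), or
#'   `"gc_content"`.
#' @param bins number of histogram bins.
#' @param range optional `c(min, max)` for the bin edges.
#' @param print_every render every this many records; `Inf` renders
#'   only the final state.
#' @param quiet suppress all rendering.
#' @param tsv optional path: write the final (bin_low, bin_high, count)
#'   table as TSV.
#' @param pass optional path or connection: records are re-serialized
#'   there unchanged (tee contract for pipelines).
#' @return the final `stream_histogram`, invisibly.
#' @export
watch_stream <- function(records, property = "length", bins = 30L,
                         range = NULL, print_every = Inf, quiet = FALSE,
                         tsv = NULL, pass = NULL) {
  h <- stream_histogram(property, bins, range)
  if (print_every < 1) stop_usage("watch: print_every must be >= 1")
  value_of <- switch(h$property,
    length = function(rec) nchar(rec$seq),
    gc_content = function(rec) gc_fraction(rec$seq),
    mean_quality = function(rec) {
      if (!is_fastq_record(rec)) {
        stop_usage("watch: mean_quality requires FASTQ input")
      }
      read_mean_quality(rec$qual)
    })
  for (k in seq_along(records)) {
    hist_update(h, value_of(records[[k]]))
    if (!quiet && is.finite(print_every) && k %% print_every == 0L) {
      message(paste(hist_render(h), collapse = "\n"))
    }
  }
  if (!quiet) message(paste(hist_render(h), collapse = "\n"))
  if (!is.null(tsv)) {
    utils::write.table(hist_tsv(h), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(pass)) write_seqs(records, pass)
  invisible(h)
}
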