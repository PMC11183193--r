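# Mismatch-tolerant IUPAC motif search on both strands of linear or
# circular sequences.  The mismatch model is Hamming (substitutions
# only).  Degenerate matching is asymmetric: a window position matches
# when the subject base's set is contained in the pattern base's set,
# so an N-rich subject never spuriously matches a specific pattern.
# Matching is case-insensitive throughout.

#' Find motif occurrences in a sequence
#'
#' A window of `nchar(pattern)` bases matches when the number of
#' positions failing [base_match()] is at most `max_mismatch`.  Minus
#' strand searching scans the plus strand with the reverse-complemented
#' pattern; hits are always reported in plus-strand coordinates with
#' `start < end`.  Circular searching scans the first
#' `L + nchar(pattern) - 1` positions of the doubled sequence and keeps
#' hits starting at or before `L`, so a junction-spanning occurrence is
#' reported exactly once, with `end > L` denoting the wrap.
#'
#' @param sequence subject sequence (IUPAC alphabet, any case).
#' @param pattern query motif (IUPAC alphabet; degenerate codes allowed).
#' @param max_mismatch maximum Hamming mismatches (must be smaller than
#'   the pattern length).
#' @param strands `"+"`, `"-"`, or `"both"`.
#' @param circular treat the sequence as circular.
#' @return data.frame of hits sorted by (start, strand): columns
#'   `start`, `end` (1-based inclusive; `end` may exceed the sequence
#'   length for circular wraps), `strand`, `mismatches`, `pattern`.
#' @examples
#' find_motif("ACGTACGT", "ACGA", max_mismatch = 1)
#' find_motif("AAAT", "TAA", circular = TRUE)   # wraps: start 4, end 6
#' @export
find_motif <- function(sequence, pattern, max_mismatch = 0L,
                       strands = "+", circular = FALSE) {
  L <- nchar(sequence); m <- nchar(pattern)
  if (m < 1L || m > L) {
    stop_data("pattern length %d outside 1..%d (sequence length)", m, L)
  }
  if (max_mismatch >= m) {
    stop_data("max_mismatch (%d) must be below the pattern length (%d)",
              max_mismatch, m)
  }
  strands <- match.arg(strands, c("+", "-", "both"))
  sb <- seq_bits(sequence, "sequence")
  if (circular && m > 1L) sb <- c(sb, sb[seq_len(m - 1L)])
  hits <- list()
  if (strands %in% c("+", "both")) {
    hits[["+"]] <- scan_windows(sb, seq_bits(pattern, "pattern", allow_gap = FALSE),
                                max_mismatch)
  }
  if (strands %in% c("-", "both")) {
    rc <- revcomp(pattern)
    hits[["-"]] <- scan_windows(sb, seq_bits(rc, "pattern", allow_gap = FALSE),
                                max_mismatch)
  }
  out <- do.call(rbind, lapply(names(hits), function(st) {
    h <- hits[[st]]
    if (!nrow(h)) return(NULL)
    data.frame(start = h$start, end = h$start + m - 1L, strand = st,
               mismatches = h$mismatches, pattern = pattern,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(), strand = character(),
                      mismatches = integer(), pattern = character(),
                      stringsAsFactors = FALSE)
  }
  if (circular) out <- out[out$start <= L, , drop = FALSE]
  out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# count mismatching positions for every window; vectorized over windows
scan_windows <- function(subject_bits, pattern_bits, max_mismatch) {
  m <- length(pattern_bits)
  nwin <- length(subject_bits) - m + 1L
  if (nwin < 1L) return(data.frame(start = integer(), mismatches = integer()))
  mm <- integer(nwin)
  for (j in seq_len(m)) {
    sb <- subject_bits[j:(j + nwin - 1L)]
    mm <- mm + !(bitwAnd(pattern_bits[j], sb) == sb & sb != 16L)
  }
  keep <- which(mm <= max_mismatch)
  data.frame(start = keep, mismatches = mm[keep])
}

#' Filter records by name or sequence motif
#'
#' Name mode (default) matches patterns against record ids — exact
#' string equality, or regular expressions with `use_regex = TRUE`.
#' Sequence mode (`by_seq = TRUE`) keeps records where [find_motif()]
#' reports at least one hit for any pattern.  A pattern beginning with
#' `>` or `@` triggers a warning (those characters mark FASTA/FASTQ
#' headers and are not part of sequence identifiers) but is still
#' matched as given.
#'
#' @param records list of [seq_record()]s.
#' @param patterns character vector of queries (at least one).
#' @param by_seq match against sequences instead of ids.
#' @param use_regex treat name patterns as regular expressions.
#' @param invert emit the non-matching records instead.
#' @inheritParams find_motif
#' @return list of matching records, in input order.
#' @export
grep_records <- function(records, patterns, by_seq = FALSE, use_regex = FALSE,
                         invert = FALSE, max_mismatch = 0L, strands = "+",
                         circular = FALSE) {
  if (!length(patterns)) stop_usage("grep: at least one pattern is required")
  pfx <- substr(patterns, 1L, 1L)
  if (any(pfx %in% c(">", "@"))) {
    warning("pattern(s) starting with '>' or '@': these characters are ",
            "not a part of sequence identifiers", call. = FALSE)
  }
  keep <- vapply(records, function(rec) {
    if (by_seq) {
      any(vapply(patterns, function(p) {
        nchar(p) <= nchar(rec$seq) &&
          nrow(find_motif(rec$seq, p, max_mismatch, strands, circular)) > 0L
      }, logical(1L)))
    } else if (use_regex) {
      any(vapply(patterns, grepl, logical(1L), x = rec$id))
    } else {
      rec$id %in% patterns
    }
  }, logical(1L))
  if (invert) keep <- !keep
  records[keep]
}

#' Locate every motif occurrence across records
#'
#' @inheritParams grep_records
#' @return data.frame with one row per hit: `seqID`, `pattern`,
#'   `strand`, `start`, `end`, `mismatches`.  Rows are grouped by record
#'   in input order; within a record hits are sorted by (start, strand).
#' @export
locate_records <- function(records, patterns, max_mismatch = 0L,
                           strands = "+", circular = FALSE) {
  rows <- lapply(records, function(rec) {
    per_pat <- lapply(patterns, function(p) {
      if (nchar(p) > nchar(rec$seq)) return(NULL)
      h <- find_motif(rec$seq, p, max_mismatch, strands, circular)
      if (!nrow(h)) return(NULL)
      data.frame(seqID = rec$id, pattern = p, strand = h$strand,
                 start = h$start, end = h$end, mismatches = h$mismatches,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, per_pat)
    if (!is.null(out)) {
      out <- out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
    }
    out
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seqID = character(), pattern = character(),
                      strand = character(), start = integer(), end = integer(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
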