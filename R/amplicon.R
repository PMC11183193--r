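# Amplicon discovery and extraction.  A primer pair is given as the
# forward and reverse oligos, both written 5'->3' as synthesized; the
# reverse primer's binding site on the template plus strand is its
# reverse complement.  A valid plus-strand pairing places the forward
# site strictly upstream of (and not overlapping) the reverse site.

#' Construct a primer pair
#'
#' @param forward forward primer, 5'->3', binds the plus strand.
#' @param reverse reverse primer, 5'->3' as synthesized; the tool
#'   reverse-complements it internally to locate its template site.
#' @param max_mismatch mismatch budget per primer site; must be below
#'   the shorter primer's length.
#' @return object of class `primer_pair`.
#' @export
primer_pair <- function(forward, reverse, max_mismatch = 0L) {
  if (!nzchar(forward) || !nzchar(reverse)) {
    stop_usage("both primers must be nonempty")
  }
  if (max_mismatch >= min(nchar(forward), nchar(reverse))) {
    stop_usage("max_mismatch (%d) must be below the shorter primer length",
               max_mismatch)
  }
  seq_bits(forward, "forward primer", allow_gap = FALSE)
  seq_bits(reverse, "reverse primer", allow_gap = FALSE)
  structure(list(forward = forward, reverse = reverse,
                 max_mismatch = as.integer(max_mismatch)),
            class = "primer_pair")
}

#' Find all amplicons delimited by a primer pair
#'
#' Forward sites are located with [find_motif()] on the template;
#' reverse sites by searching for the reverse complement of the reverse
#' primer.  Every non-overlapping pairing (forward site ending before
#' the reverse site starts) is reported.  Minus-strand amplicons come
#' from running the same procedure on the reverse-complemented template
#' and mapping coordinates back to the plus strand.
#'
#' @param record a [seq_record()] or plain sequence string.
#' @param pair a [primer_pair()].
#' @param strands `"+"`, `"-"`, or `"both"`.
#' @param circular treat the template as circular; junction-spanning
#'   sites carry wrapped coordinates (`end` beyond the template length).
#' @param first_only keep only the leftmost-outermost pairing (minimal
#'   `f_start`, then maximal `r_end`).
#' @return data.frame sorted by (f_start, r_end): columns `f_start`,
#'   `f_end` (forward primer site), `r_start`, `r_end` (reverse primer
#'   binding site), `amp_start`, `amp_end` (the amplicon interval on
#'   the strand searched), `strand`, `mismatches` (sum over the two
#'   sites).  For minus-strand rows the coordinates refer to the
#'   reverse-complemented template; `amp_*` positions map back to plus
#'   strand as `L - x + 1`.
#' @export
find_amplicons <- function(record, pair, strands = "+", circular = FALSE,
                           first_only = FALSE) {
  sq <- if (inherits(record, "seq_record")) record$seq else record
  strands <- match.arg(strands, c("+", "-", "both"))
  L <- nchar(sq)
  if (L < nchar(pair$forward) + nchar(pair$reverse)) {
    return(empty_pairings())
  }
  out <- list()
  if (strands %in% c("+", "both")) {
    out[["+"]] <- pair_sites(sq, pair, circular, "+")
  }
  if (strands %in% c("-", "both")) {
    out[["-"]] <- pair_sites(revcomp(sq), pair, circular, "-")
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty_pairings())
  out <- out[order(out$f_start, -out$r_end,
                   match(out$strand, c("+", "-"))), , drop = FALSE]
  if (first_only) out <- out[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_sites <- function(sq, pair, circular, strand) {
  L <- nchar(sq)
  fh <- find_motif(sq, pair$forward, pair$max_mismatch, "+", circular)
  if (!nrow(fh)) return(NULL)
  rh <- find_motif(sq, revcomp(pair$reverse), pair$max_mismatch, "+", circular)
  if (!nrow(rh)) return(NULL)
  if (circular) {
    # a reverse site upstream of the forward site is reachable around
    # the junction; represent it with coordinates shifted by one turn
    shifted <- rh
    shifted$start <- shifted$start + L
    shifted$end <- shifted$end + L
    rh <- rbind(rh, shifted)
  }
  combos <- expand.grid(fi = seq_len(nrow(fh)), ri = seq_len(nrow(rh)))
  keep <- fh$end[combos$fi] < rh$start[combos$ri] &
    (rh$end[combos$ri] - fh$start[combos$fi] + 1L) <= L
  combos <- combos[keep, , drop = FALSE]
  if (!nrow(combos)) return(NULL)
  data.frame(f_start = fh$start[combos$fi], f_end = fh$end[combos$fi],
             r_start = rh$start[combos$ri], r_end = rh$end[combos$ri],
             amp_start = fh$start[combos$fi], amp_end = rh$end[combos$ri],
             strand = strand,
             mismatches = fh$mismatches[combos$fi] + rh$mismatches[combos$ri],
             stringsAsFactors = FALSE)
}

empty_pairings <- function() {
  data.frame(f_start = integer(), f_end = integer(), r_start = integer(),
             r_end = integer(), amp_start = integer(), amp_end = integer(),
             strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Extract an amplicon (or a region relative to it) from a template
#'
#' The region spec uses signed 1-based coordinates relative to the
#' amplicon with primers included: +1 is the first base of the forward
#' primer and -1 the last base of the reverse primer site, so
#' `c(1, -1)` returns the full amplicon.  Negative k resolves to
#' `A + k + 1` where A is the amplicon length.  With `flanking = TRUE`
#' the resolved interval may extend beyond the amplicon into the
#' template; requests beyond the template itself are an error, never
#' clipped.
#'
#' @param record the template [seq_record()].
#' @param pairing one row of [find_amplicons()] output.
#' @param spec integer vector `c(begin, end)`, both nonzero.
#' @param flanking allow the resolved interval to leave the amplicon.
#' @param circular the template is circular (wrapped pairings are
#'   linearized across the junction).
#' @return a [seq_record()] whose description records the template
#'   coordinates and strand; quality is sliced in parallel when present.
#' @export
extract_amplicon <- function(record, pairing, spec = c(1L, -1L),
                             flanking = FALSE, circular = FALSE) {
  if (is.data.frame(pairing)) {
    stopifnot(nrow(pairing) == 1L)
    pairing <- as.list(pairing)
  }
  if (any(spec == 0L)) stop_usage("amplicon region spec must be nonzero")
  L <- nchar(record$seq)
  minus <- identical(pairing$strand, "-")
  sq <- if (minus) revcomp(record$seq) else record$seq
  ql <- record$qual
  if (minus && !is.null(ql)) {
    ql <- intToUtf8(rev(utf8ToInt(ql)))
  }
  A <- pairing$amp_end - pairing$amp_start + 1L
  b <- if (spec[1L] < 0L) A + spec[1L] + 1L else spec[1L]
  e <- if (spec[2L] < 0L) A + spec[2L] + 1L else spec[2L]
  if (b > e) stop_region("amplicon spec %d..%d resolves to an empty interval",
                         spec[1L], spec[2L])
  if (!flanking && (b < 1L || e > A)) {
    stop_region("amplicon spec %d..%d leaves the amplicon (length %d); use flanking mode",
                spec[1L], spec[2L], A)
  }
  tb <- pairing$amp_start + b - 1L
  te <- pairing$amp_start + e - 1L
  if (tb < 1L || te > (if (circular) 2L * L else L)) {
    stop_region("amplicon spec %d..%d maps outside the template", spec[1L], spec[2L])
  }
  seq_out <- slice_maybe_circular(sq, tb, te, L)
  qual_out <- if (!is.null(ql)) slice_maybe_circular(ql, tb, te, L) else NULL
  # report the covered interval in plus-strand template coordinates
  if (minus) {
    pb <- L - ((te - 1L) %% L + 1L) + 1L
    pe <- L - ((tb - 1L) %% L + 1L) + 1L
  } else {
    pb <- tb; pe <- te
  }
  desc <- sprintf("%s:%d-%d strand=%s mismatches=%d",
                  record$id, pb, pe, pairing$strand, pairing$mismatches)
  seq_record(record$id, seq_out, desc = desc, qual = qual_out)
}

slice_maybe_circular <- function(sq, b, e, L) {
  if (e <= L) return(substr(sq, b, e))
  substr(paste0(sq, sq), b, e)
}
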