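# IUPAC nucleotide alphabet: bitmask encoding and elementary operations.
#
# Each base letter maps to the set of unambiguous bases it denotes,
# encoded as a 4-bit mask (A=1, C=2, G=4, T=8).  U is a synonym for T.
# Gap characters '-' and '.' are tolerated by revcomp (they complement
# to themselves) but never match any pattern base.

.base_bits <- local({
  bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
            R = 5L,  # A/G
            Y = 10L, # C/T
            S = 6L,  # C/G
            W = 9L,  # A/T
            K = 12L, # G/T
            M = 3L,  # A/C
            B = 14L, # C/G/T
            D = 13L, # A/G/T
            H = 11L, # A/C/T
            V = 7L,  # A/C/G
            N = 15L)
  tab <- rep(NA_integer_, 256L)
  idx <- utf8ToInt(paste(names(bits), collapse = ""))
  tab[idx + 1L] <- unname(bits)
  tab[utf8ToInt(paste(tolower(names(bits)), collapse = "")) + 1L] <- unname(bits)
  # gaps: sentinel bit outside the 4-base universe, matches nothing
  tab[utf8ToInt("-") + 1L] <- 16L
  tab[utf8ToInt(".") + 1L] <- 16L
  tab
})

.comp_from <- "ACGTURYSWKMBDHVNacgturyswkmbdhvn"
.comp_to   <- "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn"

#' Convert a sequence string to IUPAC bitmasks
#'
#' @param x single sequence string.
#' @param what label used in error messages.
#' @param allow_gap keep gap characters (as a non-matching sentinel mask)
#'   instead of raising an alphabet error.
#' @return integer vector of 4-bit base-set masks, one per character.
#' @keywords internal
seq_bits <- function(x, what = "sequence", allow_gap = TRUE) {
  ints <- utf8ToInt(x)
  bits <- .base_bits[ints + 1L]
  bad <- which(is.na(bits) | (!allow_gap & bits == 16L))
  if (length(bad)) {
    stop_alphabet("non-IUPAC character '%s' at position %d of %s",
                  intToUtf8(ints[bad[1L]]), bad[1L], what)
  }
  bits
}

#' Reverse complement of an IUPAC nucleotide sequence
#'
#' Applies the IUPAC complement table (A<->T, C<->G, R<->Y, S<->S, W<->W,
#' K<->M, B<->V, D<->H, N<->N, U->A) and reverses.  Case of every base is
#' preserved; gap characters `-` and `.` map to themselves.
#'
#' @param x single sequence string over the IUPAC alphabet (any case),
#'   possibly containing gaps.
#' @return the reverse complement, same length as `x`.
#' @examples
#' revcomp("ACGT")   # "ACGT" (palindrome)
#' revcomp("ATGN")   # "NCAT"
#' revcomp("acGT-")  # "-ACgt"
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) return(x)
  seq_bits(x, what = "sequence")  # validates; gaps allowed
  comp <- chartr(.comp_from, .comp_to, x)
  intToUtf8(rev(utf8ToInt(comp)))
}

#' GC fraction of a sequence
#'
#' Counts G, C and S (the G/C ambiguity code) in the numerator; the
#' denominator is the count of unambiguous A/C/G/T/U plus S.  All other
#' ambiguity codes and gaps are excluded from both.  Case-insensitive.
#' Returns 0 when the denominator is 0 (e.g. an all-N sequence).
#'
#' @param x nonempty sequence string.
#' @return fraction in \[0, 1\].
#' @examples
#' gc_fraction("ATGC")  # 0.5
#' gc_fraction("GCNN")  # 1: N excluded from the denominator
#' @export
gc_fraction <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(x)) stop_data("gc_fraction: empty sequence")
  cnt <- gc_counts(x)
  if (cnt[["den"]] == 0) return(0)
  cnt[["num"]] / cnt[["den"]]
}

# numerator/denominator counts so callers can pool across records
gc_counts <- function(x) {
  ints <- utf8ToInt(toupper(x))
  num <- sum(ints == 71L | ints == 67L | ints == 83L)          # G C S
  den <- num + sum(ints == 65L | ints == 84L | ints == 85L)    # + A T U
  c(num = num, den = den)
}

#' Test one IUPAC pattern base against one subject base
#'
#' Containment semantics: the subject's base set must be a subset of the
#' pattern's base set.  A degenerate pattern base (`R`, `N`, ...) matches
#' the unambiguous bases it denotes; an ambiguous subject base matches
#' only a pattern base at least as degenerate.  `N` in the pattern
#' matches everything; `N` in the subject matches only pattern `N`.
#' Case-insensitive.  Vectorized over equal-length inputs.
#'
#' @param pattern_base,subject_base IUPAC code characters.
#' @return logical vector.
#' @examples
#' base_match("R", "A")  # TRUE:  A in {A,G}
#' base_match("A", "R")  # FALSE: {A,G} not within {A}
#' @export
base_match <- function(pattern_base, subject_base) {
  pb <- seq_bits(paste(pattern_base, collapse = ""), "pattern", allow_gap = FALSE)
  sb <- seq_bits(paste(subject_base, collapse = ""), "subject", allow_gap = FALSE)
  bitwAnd(pb, sb) == sb
}

# vectorized helpers on precomputed masks (gap sentinel never matches)
mask_match <- function(pattern_bits, subject_bits) {
  bitwAnd(pattern_bits, subject_bits) == subject_bits & subject_bits != 16L
}

strip_gaps <- function(x) gsub("[-.]", "", x)
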