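# Order-invariant content digests.  Each record contributes a 128-bit
# MD5 of its canonical sequence (uppercased, gap-stripped, optionally
# rotated to Booth's least rotation for circular molecules, optionally
# strand-canonicalized); the file digest is the modular 128-bit SUM of
# record digests, so it is invariant to record order but — unlike an
# XOR combiner — still sensitive to duplicated records (multiset
# semantics).  Digests are comparable only within the algorithm tag.

DIGEST_TAG <- "md5sum128-v1"

#' Booth's least-rotation offset
#'
#' Returns the smallest 0-based rotation offset `r` such that rotating
#' the string left by `r` yields its lexicographically minimal rotation
#' (ties from periodic strings break to the smallest `r`).  Runs in
#' linear time.
#'
#' @param x nonempty string.
#' @return integer offset in `0..nchar(x)-1`.
#' @examples
#' least_rotation("BAA")   # 1 ("AAB")
#' least_rotation("AAAA")  # 0
#' @export
least_rotation <- function(x) {
  n <- nchar(x)
  if (n == 0L) stop_data("least_rotation: empty sequence")
  if (n == 1L) return(0L)
  s <- utf8ToInt(x)
  s <- c(s, s)                       # doubled, 1-based
  f <- rep.int(-1L, 2L * n)          # failure function, 0-based values
  k <- 0L                            # candidate rotation, 0-based
  for (j in 1L:(2L * n - 1L)) {      # 0-based index j over s[j+1]
    sj <- s[j + 1L]
    i <- f[j - k]                    # f[(j-k-1)+1]
    while (i != -1L && sj != s[k + i + 2L]) {
      if (sj < s[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != s[k + i + 2L]) {
      if (sj < s[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k
}

rotate_left <- function(x, r) {
  n <- nchar(x)
  r <- r %% n
  if (r == 0L) return(x)
  paste0(substr(x, r + 1L, n), substr(x, 1L, r))
}

#' Canonical form of a sequence for digesting
#'
#' Uppercases the sequence; for circular molecules rotates it to its
#' least rotation; with `both_strands` takes the lexicographic minimum
#' of the canonicalized sequence and the canonicalized reverse
#' complement, making the result strand-independent.
#'
#' @param x nonempty sequence string.
#' @param circular canonicalize rotation.
#' @param both_strands canonicalize strand.
#' @return canonical string.
#' @examples
#' canonical_form("GCAT", circular = TRUE)   # "ATGC"
#' @export
canonical_form <- function(x, circular = FALSE, both_strands = FALSE) {
  if (!nzchar(x)) stop_data("canonical_form: empty sequence")
  canon1 <- function(s) {
    s <- toupper(s)
    if (circular) rotate_left(s, least_rotation(s)) else s
  }
  a <- canon1(x)
  if (!both_strands) return(a)
  b <- canon1(toupper(revcomp(x)))
  if (b < a) b else a
}

#' 128-bit digest of one record's content
#'
#' Hashes the canonical sequence (identifiers and descriptions never
#' contribute); at level `"seq+qual"` the raw quality string is appended
#' after a separator byte.  Gap characters are stripped before
#' canonicalization.
#'
#' @param record a [seq_record()].
#' @param level `"seq"` or `"seq+qual"` (the latter requires quality).
#' @inheritParams canonical_form
#' @return 32-character lowercase hex string (128 bits).
#' @export
record_digest <- function(record, level = "seq", circular = FALSE,
                          both_strands = FALSE) {
  level <- match.arg(level, c("seq", "seq+qual"))
  canon <- canonical_form(strip_gaps(record$seq), circular, both_strands)
  if (level == "seq+qual") {
    if (!is_fastq_record(record)) {
      stop_usage("digest level seq+qual requires quality (FASTQ) records")
    }
    canon <- paste0(canon, "\n", record$qual)
  }
  digest::digest(canon, algo = "md5", serialize = FALSE)
}

#' Order-invariant digest of a record set
#'
#' @param records list of [seq_record()]s (possibly empty).
#' @inheritParams record_digest
#' @return list of class `digest_result`: `file_digest` (32 hex chars),
#'   `n_records`, `level`, `circular`, `both_strands`, `algorithm_tag`.
#' @examples
#' r <- list(seq_record("a", "ACGT"), seq_record("b", "GGCC"))
#' identical(file_digest(r)$file_digest, file_digest(rev(r))$file_digest)
#' @export
file_digest <- function(records, level = "seq", circular = FALSE,
                        both_strands = FALSE) {
  acc <- rep.int(0, 4)  # four 32-bit limbs, most significant first
  for (rec in records) {
    acc <- hex128_add(acc, hex_to_limbs(
      record_digest(rec, level, circular, both_strands)))
  }
  structure(list(file_digest = limbs_to_hex(acc),
                 n_records = length(records),
                 level = level, circular = circular,
                 both_strands = both_strands,
                 algorithm_tag = DIGEST_TAG),
            class = "digest_result")
}

#' @export
print.digest_result <- function(x, ...) {
  cat(sprintf("%s  %s  %d\n", x$file_digest, x$algorithm_tag, x$n_records))
  invisible(x)
}

format_digest_line <- function(dr, path) {
  sprintf("%s\t%s\t%d\t%s", dr$file_digest, dr$algorithm_tag, dr$n_records, path)
}

# ---- 128-bit arithmetic on 32-bit limbs held in doubles -------------

hex_to_limbs <- function(hex) {
  stopifnot(nchar(hex) == 32L)
  starts <- c(1L, 9L, 17L, 25L)
  vapply(starts, function(s) {
    hi <- strtoi(substr(hex, s, s + 3L), base = 16L)
    lo <- strtoi(substr(hex, s + 4L, s + 7L), base = 16L)
    hi * 65536 + lo
  }, numeric(1L))
}

limbs_to_hex <- function(limbs) {
  paste(vapply(limbs, function(v) {
    sprintf("%04x%04x", as.integer(v %/% 65536), as.integer(v %% 65536))
  }, ""), collapse = "")
}

# addition modulo 2^128 (each limb < 2^32; sums stay exact in doubles)
hex128_add <- function(a, b) {
  out <- numeric(4L)
  carry <- 0
  for (i in 4:1) {
    v <- a[i] + b[i] + carry
    carry <- if (v >= 4294967296) 1 else 0
    out[i] <- v - carry * 4294967296
  }
  out
}
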