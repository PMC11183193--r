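# Deterministic synthetic-data and corruption-fixture generation.  All
# generators are pure functions of their seed (the caller's RNG state
# is saved and restored), so the same arguments always yield the same
# records, byte for byte.

#' Generate synthetic sequence records
#'
#' Records are named `r1..rN`.  The default quality model draws uniform
#' Phred scores in 30–40 (a typical range for modern short-read data)
#' and default lengths are 100–150 nt.
#'
#' @param n number of records.
#' @param seed integer seed; identical arguments give identical records.
#' @param length_range integer `c(min, max)` record length in bases.
#' @param alphabet `"ACGT"` or `"IUPAC"` (all 16 codes, ambiguity codes
#'   drawn at low frequency).
#' @param format `"fastq"` (with quality) or `"fasta"`.
#' @param quality integer `c(min, max)` Phred range, or one value for
#'   constant quality.  Ignored for FASTA.
#' @return list of [seq_record()]s.
#' @examples
#' synth_records(3, seed = 7, length_range = c(10, 10))
#' @export
synth_records <- function(n, seed = 1L, length_range = c(100L, 150L),
                          alphabet = c("ACGT", "IUPAC"), format = c("fastq", "fasta"),
                          quality = c(30L, 40L)) {
  alphabet <- match.arg(alphabet)
  format <- match.arg(format)
  if (n < 0L) stop_usage("synth: n must be >= 0")
  if (length_range[1L] < 1L || length_range[2L] < length_range[1L]) {
    stop_usage("synth: invalid length range")
  }
  if (length(quality) == 1L) quality <- c(quality, quality)
  lens_pool <- length_range[1L]:length_range[2L]
  qual_pool <- quality[1L]:quality[2L]
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(k) {
      len <- lens_pool[sample.int(length(lens_pool), 1L)]
      sq <- random_sequence(len, alphabet)
      ql <- if (format == "fastq") {
        intToUtf8(qual_pool[sample.int(length(qual_pool), len, replace = TRUE)] + 33L)
      } else NULL
      seq_record(paste0("r", k), sq, qual = ql)
    })
  })
}

random_sequence <- function(len, alphabet = "ACGT") {
  if (alphabet == "IUPAC") {
    letters <- strsplit("ACGTRYSWKMBDHVN", "")[[1L]]
    prob <- c(rep(1, 4), rep(0.02, 11))  # ambiguity codes are rare
  } else {
    letters <- c("A", "C", "G", "T")
    prob <- rep(1, 4)
  }
  paste(sample(letters, len, replace = TRUE, prob = prob), collapse = "")
}

#' Introduce one structural defect into clean 4-line FASTQ text
#'
#' Exactly the named damage is applied at the target record; all other
#' records' bytes are untouched.  Modes: `truncate_qual` shortens the
#' quality line; `drop_separator` deletes the `+` line; `garbage_block`
#' replaces the record's four lines with non-FASTQ bytes; `cut_tail`
#' truncates the file inside the target record.
#'
#' @param text clean FASTQ content: a character vector of lines or one
#'   string with embedded newlines.
#' @param mode one of `"truncate_qual"`, `"drop_separator"`,
#'   `"garbage_block"`, `"cut_tail"`.
#' @param target_record 1-based ordinal(s) of the record(s) to damage.
#'   `cut_tail` uses only the smallest target (everything after the cut
#'   is gone anyway).
#' @param seed seed for the damage randomness.
#' @return corrupted text as a character vector of lines.
#' @export
corrupt_fastq <- function(text, mode, target_record, seed = 1L) {
  mode <- match.arg(mode, c("truncate_qual", "drop_separator",
                            "garbage_block", "cut_tail"))
  lines <- source_lines(NULL, text)
  lines <- sub("\r$", "", lines)
  n_rec <- length(lines) %/% 4L
  if (length(lines) %% 4L != 0L || any(target_record < 1L) ||
      any(target_record > n_rec)) {
    stop_data("corrupt_fastq: need clean 4-line FASTQ with targets in 1..%d", n_rec)
  }
  # descending order: line numbers of lower-ordinal records stay valid
  targets <- sort(unique(as.integer(target_record)), decreasing = TRUE)
  if (mode == "cut_tail") targets <- min(targets)
  withr::with_seed(as.integer(seed), {
    for (tr in targets) {
      base <- (tr - 1L) * 4L
      lines <- switch(mode,
        truncate_qual = {
          q <- lines[base + 4L]
          cut <- sample(seq_len(max(nchar(q) - 1L, 1L)), 1L)
          lines[base + 4L] <- substr(q, 1L, cut - 1L)
          lines
        },
        drop_separator = lines[-(base + 3L)],
        garbage_block = {
          lines[base + 1:4] <- vapply(1:4, function(i) {
            strrep("#", sample(5:30, 1L))
          }, "")
          lines
        },
        cut_tail = lines[seq_len(base + sample(1:3, 1L))]  # end mid-record
      )
      if (mode == "cut_tail") break  # only the smallest target matters
    }
    lines
  })
}

#' Plant a primer pair in a random template, returning the truth
#'
#' Builds `flank + F' + insert + revcomp(R)' + flank` where `F'` and
#' `revcomp(R)'` carry a total of `n_mismatches` planted substitutions
#' (each substitution changes the base to one the original primer base
#' does not match), and returns the template together with the true
#' site coordinates and the amplicon the primers should recover.
#'
#' @param seed integer seed.
#' @param flank_len random flank length on each side.
#' @param insert_len length of the random insert between primer sites.
#' @param forward,reverse primer sequences, 5'->3' as synthesized.
#' @param n_mismatches substitutions planted inside one primer site
#'   (which of the two is chosen at random); must be below the shorter
#'   primer's length.
#' @return list: `record` (the template [seq_record()]), `truth` with
#'   `f_start`, `f_end`, `r_start`, `r_end`, `amplicon`, `n_mismatches`.
#' @export
plant_amplicon <- function(seed, flank_len, insert_len, forward, reverse,
                           n_mismatches = 0L) {
  if (n_mismatches >= min(nchar(forward), nchar(reverse))) {
    stop_usage("plant_amplicon: n_mismatches must be below the shorter primer")
  }
  flank_len <- as.integer(flank_len)
  insert_len <- as.integer(insert_len)
  n_mismatches <- as.integer(n_mismatches)
  withr::with_seed(as.integer(seed), {
    # all substitutions land in one primer site (chosen at random), so a
    # search budget of n_mismatches-1 is guaranteed to miss that site
    in_forward <- sample(c(TRUE, FALSE), 1L)
    k1 <- if (in_forward) n_mismatches else 0L
    k2 <- n_mismatches - k1
    f_site <- mutate_outside_pattern(forward, toupper(forward), k1)
    r_site <- mutate_outside_pattern(revcomp(reverse), toupper(revcomp(reverse)), k2)
    left <- random_sequence(flank_len)
    insert <- random_sequence(insert_len)
    right <- random_sequence(flank_len)
    template <- paste0(left, f_site, insert, r_site, right)
    f_start <- flank_len + 1L
    f_end <- f_start + nchar(forward) - 1L
    r_start <- f_end + insert_len + 1L
    r_end <- r_start + nchar(reverse) - 1L
    list(record = seq_record("tmpl", template),
         truth = list(f_start = f_start, f_end = f_end,
                      r_start = r_start, r_end = r_end,
                      amplicon = paste0(f_site, insert, r_site),
                      n_mismatches = k1 + k2))
  })
}

# substitute k positions of `site` with bases that fail base_match
# against the corresponding `pattern` base (so each substitution costs
# exactly one mismatch under the search model)
mutate_outside_pattern <- function(site, pattern, k) {
  if (k == 0L) return(site)
  chars <- strsplit(site, "")[[1L]]
  pat <- strsplit(pattern, "")[[1L]]
  pos <- sample(length(chars), k)
  for (p in pos) {
    options <- setdiff(c("A", "C", "G", "T"),
                       c("A", "C", "G", "T")[base_match(rep(pat[p], 4L),
                                                        c("A", "C", "G", "T"))])
    if (!length(options)) options <- c("A", "C", "G", "T")  # pattern N: any base matches
    chars[p] <- sample(options, 1L)
  }
  paste(chars, collapse = "")
}
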