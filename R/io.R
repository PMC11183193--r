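# FASTA/FASTQ reading and writing.  Format is auto-detected from the
# first non-blank character ('>' FASTA, '@' FASTQ).  Multiline records
# are supported in both formats; in FASTQ the quality block terminates
# when its accumulated length reaches the sequence length — never by
# line prefix, since '@' and '+' are legal quality characters.  CRLF is
# tolerated on input; output is LF-only.

#' Read sequence records from a FASTA/FASTQ source
#'
#' The source may be plain or gzip/bzip2/xz/zstandard compressed
#' (detected by magic bytes).  An empty source yields an empty list
#' without error.
#'
#' @param path file path, or `"-"` for standard input.
#' @param text alternative to `path`: a character vector of lines or a
#'   single string with embedded newlines.
#' @param strict raise a parse error (with line number) on malformed
#'   input.  With `strict = FALSE` a FASTQ source is run through
#'   [sana()] recovery instead and only the intact records returned.
#' @return list of [seq_record()] objects in file order.
#' @examples
#' read_seqs(text = ">a x\nAC\nGT\n")
#' read_seqs(text = "@r\nACGT\n+\nIIII\n")
#' @export
read_seqs <- function(path = NULL, text = NULL, strict = TRUE) {
  lines <- source_lines(path, text)
  lines <- sub("\r$", "", lines)
  first <- lines[nzchar(lines)][1L]
  if (is.na(first)) return(list())
  marker <- substr(first, 1L, 1L)
  if (marker == ">") {
    parse_fasta(lines)
  } else if (marker == "@") {
    if (strict) parse_fastq(lines) else sana(text = lines)$records
  } else {
    stop_parse("line %d: expected '>' or '@' at start of record, got '%s'",
               which(nzchar(lines))[1L], marker)
  }
}

source_lines <- function(path, text) {
  if (!is.null(text)) {
    if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
      text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
    }
    return(text)
  }
  if (is.null(path)) stop_usage("read_seqs: either path or text is required")
  read_source_lines(path)
}

parse_fasta <- function(lines) {
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(list())
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop_parse("line %d: sequence data before first FASTA header", lineno[1L])
  }
  grp <- cumsum(is_hdr)
  headers <- substring(lines[is_hdr], 2L)
  seqs <- vapply(split(lines[!is_hdr], grp[!is_hdr]),
                 paste, collapse = "", FUN.VALUE = "")
  full <- character(sum(is_hdr))
  names(full) <- as.character(seq_along(full))
  full[names(seqs)] <- seqs
  lapply(seq_along(headers), function(k) {
    h <- split_header(headers[k])
    seq_record(h$id, full[[k]], desc = h$desc)
  })
}

parse_fastq <- function(lines) {
  # drop leading blanks; interior blank lines between records tolerated
  n <- length(lines)
  # fast path: canonical 4-line records
  if (n %% 4L == 0L && n > 0L && all(nzchar(lines))) {
    h <- seq.int(1L, n, by = 4L)
    if (all(startsWith(lines[h], "@")) && all(startsWith(lines[h + 2L], "+")) &&
        all(nchar(lines[h + 1L]) == nchar(lines[h + 3L]))) {
      return(fastq_build(substring(lines[h], 2L), lines[h + 1L], lines[h + 3L], h))
    }
  }
  recs <- list(); i <- 1L
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (!startsWith(lines[i], "@")) {
      stop_parse("line %d: expected '@' record header", i)
    }
    hdr <- substring(lines[i], 2L)
    i <- i + 1L
    sq <- character();
    while (i <= n && !startsWith(lines[i], "+")) {
      sq <- c(sq, lines[i]); i <- i + 1L
    }
    if (i > n) stop_parse("line %d: truncated record '%s' (missing '+' separator)", n, hdr)
    sq <- paste(sq, collapse = "")
    i <- i + 1L  # '+' separator
    ql <- ""; slen <- nchar(sq)
    while (i <= n && nchar(ql) < slen) {
      ql <- paste0(ql, lines[i]); i <- i + 1L
    }
    if (nchar(ql) != slen) {
      stop_parse("line %d: record '%s' quality length %d != sequence length %d",
                 min(i, n), hdr, nchar(ql), slen)
    }
    if (grepl("[-.]", sq)) {
      stop_parse("record '%s': gap characters are not allowed in FASTQ", hdr)
    }
    h <- split_header(hdr)
    recs[[length(recs) + 1L]] <- seq_record(h$id, sq, desc = h$desc, qual = ql)
  }
  recs
}

fastq_build <- function(headers, seqs, quals, lineno) {
  bad <- grep("[-.]", seqs)
  if (length(bad)) {
    stop_parse("line %d: gap characters are not allowed in FASTQ", lineno[bad[1L]] + 1L)
  }
  lapply(seq_along(headers), function(k) {
    h <- split_header(headers[k])
    seq_record(h$id, seqs[k], desc = h$desc, qual = quals[k])
  })
}

#' Write sequence records to FASTA/FASTQ
#'
#' Output compression is chosen from the destination filename extension
#' (`.gz`, `.bz2`, `.xz`, `.zst`).  Records carrying quality are written
#' in 4-line FASTQ form (never wrapped); records without quality are
#' written as FASTA, wrapped at `wrap` bases per line.
#'
#' @param records list of [seq_record()] objects.
#' @param path destination path, `"-"` for standard output, or an open
#'   connection.
#' @param wrap FASTA bases per line; 0 disables wrapping.
#' @return number of records written, invisibly.
#' @export
write_seqs <- function(records, path = "-", wrap = 0L) {
  write_dest_lines(format_records(records, wrap = wrap), path)
  invisible(length(records))
}

#' Serialize records to FASTA/FASTQ lines in memory
#'
#' @inheritParams write_seqs
#' @return character vector of output lines (no terminators).
#' @export
format_records <- function(records, wrap = 0L) {
  out <- lapply(records, function(rec) {
    if (is_fastq_record(rec)) {
      c(paste0("@", record_header(rec)), rec$seq, "+", rec$qual)
    } else {
      c(paste0(">", record_header(rec)), wrap_seq(rec$seq, wrap))
    }
  })
  as.character(unlist(out, use.names = FALSE))
}

wrap_seq <- function(seq, wrap) {
  n <- nchar(seq)
  if (wrap <= 0L || n <= wrap) return(seq)
  starts <- seq.int(1L, n, by = wrap)
  substring(seq, starts, pmin(starts + wrap - 1L, n))
}

#' Error-tolerant FASTQ recovery
#'
#' Scans a possibly corrupted FASTQ stream (truncated lines, deleted
#' separators, foreign byte blocks), emits every structurally valid
#' record and resynchronizes after damage at the next line starting with
#' `@` that heads a fully valid 4-line record: line 3 starts with `+`,
#' the quality length equals the sequence length, and the sequence is
#' over the IUPAC alphabet.  Nothing is ever raised; problems are
#' counted in the report.
#'
#' @inheritParams read_seqs
#' @return a list with elements `records` (the recovered [seq_record()]s)
#'   and `report`: `records_emitted`, `records_discarded` (number of
#'   contiguous damaged regions skipped), `first_error_line` (line
#'   number of the first skipped line, or `NA`).
#' @export
sana <- function(path = NULL, text = NULL) {
  lines <- sub("\r$", "", source_lines(path, text))
  n <- length(lines)
  recs <- list()
  discarded <- 0L
  first_err <- NA_integer_
  i <- 1L
  in_bad <- FALSE
  while (i <= n) {
    if (!nzchar(lines[i])) { i <- i + 1L; next }
    if (sana_valid_at(lines, i)) {
      h <- split_header(substring(lines[i], 2L))
      recs[[length(recs) + 1L]] <-
        seq_record(h$id, lines[i + 1L], desc = h$desc, qual = lines[i + 3L])
      i <- i + 4L
      in_bad <- FALSE
    } else {
      if (!in_bad) {
        discarded <- discarded + 1L
        if (is.na(first_err)) first_err <- i
        in_bad <- TRUE
      }
      i <- i + 1L
    }
  }
  list(records = recs,
       report = list(records_emitted = length(recs),
                     records_discarded = discarded,
                     first_error_line = first_err))
}

sana_valid_at <- function(lines, i) {
  n <- length(lines)
  if (i + 3L > n) return(FALSE)
  if (!startsWith(lines[i], "@") || nchar(lines[i]) < 2L) return(FALSE)
  if (grepl("[[:space:]]", substr(lines[i], 2L, 2L))) return(FALSE)
  sq <- lines[i + 1L]
  if (!nzchar(sq)) return(FALSE)
  if (!startsWith(lines[i + 2L], "+")) return(FALSE)
  if (nchar(lines[i + 3L]) != nchar(sq)) return(FALSE)
  ints <- utf8ToInt(sq)
  bits <- .base_bits[ints + 1L]
  !anyNA(bits) && all(bits != 16L)
}
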