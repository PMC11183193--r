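# samtools-compatible FASTA indexing and random-access region fetch.
# The .fai format is 5 tab-separated columns per record: name, length
# (bases), offset (byte offset of the first sequence byte), linebases
# (bases per full sequence line), linewidth (bytes per full line,
# terminator included).  CRLF files index with linewidth = linebases+2.

#' Build a samtools-style .fai index for a plain FASTA file
#'
#' @param path path to an uncompressed FASTA file.
#' @param write also write the index next to the input as `<path>.fai`.
#' @return data.frame with columns name, length, offset, linebases,
#'   linewidth (one row per record, file order), plus a `descriptions`
#'   attribute carrying each record's header description.
#' @export
build_fai <- function(path, write = TRUE) {
  if (detect_compression(path) != "plain") {
    stop_data("faidx requires uncompressed FASTA: %s", path)
  }
  bytes <- readBin(path, "raw", n = file.size(path))
  nl <- which(bytes == as.raw(0x0a))
  if (length(bytes) && (length(nl) == 0L || nl[length(nl)] != length(bytes))) {
    nl <- c(nl, length(bytes) + 1L)  # tolerate missing final newline
  }
  line_start <- c(1L, nl[-length(nl)] + 1L)
  line_end <- nl  # position of LF (or one past EOF)
  n_lines <- length(line_start)

  entries <- list(); descs <- character()
  rec <- NULL
  flush <- function(rec) {
    if (is.null(rec)) return()
    if (is.na(rec$entry$linebases)) {  # zero-length record
      rec$entry$linebases <- 0L
      rec$entry$linewidth <- 1L
    }
    entries[[length(entries) + 1L]] <<- rec$entry
    descs[length(descs) + 1L] <<- rec$desc
  }
  for (k in seq_len(n_lines)) {
    s <- line_start[k]; e <- line_end[k]
    raw_line <- if (e - 1L >= s) bytes[s:(e - 1L)] else raw()
    has_cr <- length(raw_line) && raw_line[length(raw_line)] == as.raw(0x0d)
    content <- if (has_cr) raw_line[-length(raw_line)] else raw_line
    txt <- rawToChar(content)
    if (startsWith(txt, ">")) {
      flush(rec)
      h <- split_header(substring(txt, 2L))
      # offset of first sequence byte (0-based) = 1-based position of the
      # header line's LF
      rec <- list(entry = list(name = h$id, length = 0L, offset = e,
                               linebases = NA_integer_, linewidth = NA_integer_),
                  desc = h$desc, last_short = FALSE)
    } else if (!nzchar(txt)) {
      next
    } else {
      if (is.null(rec)) stop_data("line %d: sequence before first header", k)
      lb <- nchar(txt)
      lw <- (e - s) + 1L  # bytes incl terminator
      if (is.na(rec$entry$linebases)) {
        rec$entry$linebases <- lb
        rec$entry$linewidth <- lw
      } else {
        if (rec$last_short) {
          stop_data("faidx: record '%s' has ragged sequence line lengths", rec$entry$name)
        }
        if (lb > rec$entry$linebases) {
          stop_data("faidx: record '%s' has ragged sequence line lengths", rec$entry$name)
        }
      }
      if (lb < rec$entry$linebases) rec$last_short <- TRUE
      rec$entry$length <- rec$entry$length + lb
    }
  }
  flush(rec)
  fai <- do.call(rbind, lapply(entries, as.data.frame))
  if (is.null(fai)) {
    fai <- data.frame(name = character(), length = integer(), offset = numeric(),
                      linebases = integer(), linewidth = integer())
  }
  rownames(fai) <- NULL
  attr(fai, "descriptions") <- stats::setNames(descs, fai$name)
  if (write) write_fai(fai, paste0(path, ".fai"))
  fai
}

write_fai <- function(fai, path) {
  utils::write.table(fai[, c("name", "length", "offset", "linebases", "linewidth")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a .fai index file
#'
#' @param path path to a 5-column .fai file.
#' @return data.frame as produced by [build_fai()] (no descriptions).
#' @export
read_fai <- function(path) {
  fai <- utils::read.table(path, sep = "\t", col.names = c(
    "name", "length", "offset", "linebases", "linewidth"),
    colClasses = c("character", "integer", "numeric", "integer", "integer"))
  fai
}

# load (or build) the index for a FASTA, honouring staleness by size
fai_for <- function(path, fai = NULL) {
  if (!is.null(fai)) return(fai)
  idx_path <- paste0(path, ".fai")
  if (file.exists(idx_path)) {
    fai <- read_fai(idx_path)
    # stale-index heuristic: total indexed bytes must not exceed file size
    if (!nrow(fai) || max(fai$offset) < file.size(path)) return(fai)
  }
  build_fai(path, write = TRUE)
}

#' Fetch a region from an indexed FASTA by random access
#'
#' Coordinates are 1-based inclusive; negative values count from the
#' end of the sequence (-1 = last base).  Only the bytes covering the
#' requested interval are read, using the index's offset arithmetic.
#'
#' @param path FASTA file path.
#' @param reg a [region()] or region string such as `"s1:2-5"`,
#'   `"s1:-4--1"`, or `"s1"` (whole sequence).
#' @param fai optional prebuilt index from [build_fai()]; built (or
#'   loaded from `<path>.fai`) when missing.
#' @param do_revcomp reverse-complement the extracted sequence.
#' @param full_header carry the record's original description into the
#'   output header.
#' @return a [seq_record()]; its id is `"name:begin-end"` for a proper
#'   subregion, or the record name for a whole-sequence fetch.
#' @export
fetch_region <- function(path, reg, fai = NULL, do_revcomp = FALSE,
                         full_header = FALSE) {
  if (is.character(reg)) reg <- parse_region(reg)
  fai <- fai_for(path, fai)
  row <- match(reg$name, fai$name)
  if (is.na(row)) stop_data("sequence '%s' not found in index", reg$name)
  L <- fai$length[row]
  be <- resolve_region(reg$begin, reg$end, L)
  b <- be[1L]; e <- be[2L]
  sq <- read_fasta_slice(path, fai[row, ], b, e)
  if (do_revcomp) sq <- revcomp(sq)
  id <- if (b == 1L && e == L) reg$name else sprintf("%s:%d-%d", reg$name, b, e)
  desc <- ""
  if (full_header) {
    descs <- attr(fai, "descriptions")
    if (is.null(descs)) descs <- scan_fasta_descriptions(path)
    desc <- descs[[reg$name]] %||% ""
    if (is.na(desc)) desc <- ""
  }
  if (do_revcomp) desc <- paste(desc, "(reverse complement)")
  seq_record(id, sq, desc = trimws(desc))
}

read_fasta_slice <- function(path, entry, b, e) {
  lb <- entry$linebases; lw <- entry$linewidth
  start_byte <- entry$offset + ((b - 1L) %/% lb) * lw + (b - 1L) %% lb
  n_breaks <- (e - 1L) %/% lb - (b - 1L) %/% lb
  n_bytes <- (e - b + 1L) + n_breaks * (lw - lb)
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, where = start_byte)
  chunk <- readBin(con, "raw", n = n_bytes)
  chunk <- chunk[chunk != as.raw(0x0a) & chunk != as.raw(0x0d)]
  rawToChar(chunk)
}

scan_fasta_descriptions <- function(path) {
  lines <- read_source_lines(path)
  hdr <- sub("\r$", "", lines[startsWith(lines, ">")])
  parts <- lapply(substring(hdr, 2L), split_header)
  stats::setNames(vapply(parts, `[[`, "", "desc"),
                  vapply(parts, `[[`, "", "id"))
}

#' Fetch multiple regions listed in a file
#'
#' @param path FASTA file path.
#' @param region_file text file of region strings, one per line; blank
#'   lines and `#` comments are ignored.
#' @inheritParams fetch_region
#' @return list of [seq_record()]s in file order.
#' @export
fetch_regions_file <- function(path, region_file, fai = NULL,
                               do_revcomp = FALSE, full_header = FALSE) {
  specs <- readLines(region_file, warn = FALSE)
  specs <- trimws(sub("\r$", "", specs))
  specs <- specs[nzchar(specs) & !startsWith(specs, "#")]
  fai <- fai_for(path, fai)
  lapply(specs, fetch_region, path = path, fai = fai,
         do_revcomp = do_revcomp, full_header = full_header)
}
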