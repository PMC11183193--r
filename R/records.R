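# SeqRecord: one FASTA/FASTQ record.  Plain S3 list with fields
# id (first whitespace-delimited token of the header), desc (remainder,
# possibly ""), seq, and qual (NULL for FASTA).  Collections of records
# are ordinary R lists, in file order.

#' Construct a sequence record
#'
#' @param id identifier token; must contain no whitespace.
#' @param seq sequence string (IUPAC alphabet; gaps allowed in FASTA).
#' @param desc free-text description (the rest of the header line).
#' @param qual optional Phred+33 quality string; when present its length
#'   must equal the sequence length and the record is treated as FASTQ.
#' @return object of class `seq_record`.
#' @examples
#' seq_record("read1", "ACGT", qual = "IIII")
#' @export
seq_record <- function(id, seq, desc = "", qual = NULL) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  if (grepl("[[:space:]]", id)) {
    stop_data("record id '%s' contains whitespace", id)
  }
  if (!is.null(qual)) {
    stopifnot(is.character(qual), length(qual) == 1L)
    if (nchar(qual) != nchar(seq)) {
      stop_data("record '%s': quality length %d != sequence length %d",
                id, nchar(qual), nchar(seq))
    }
  }
  structure(list(id = id, desc = desc %||% "", seq = seq, qual = qual),
            class = "seq_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.seq_record <- function(x, ...) {
  n <- nchar(x$seq)
  kind <- if (is.null(x$qual)) "FASTA" else "FASTQ"
  cat(sprintf("<seq_record %s> %s%s  (%d bp)\n", kind, x$id,
              if (nzchar(x$desc)) paste0(" ", x$desc) else "", n))
  shown <- if (n > 60) paste0(substr(x$seq, 1, 57), "...") else x$seq
  cat(" ", shown, "\n")
  invisible(x)
}

# header text without the leading '>'/'@'; round-trips byte-exactly
record_header <- function(rec) {
  if (nzchar(rec$desc)) paste(rec$id, rec$desc) else rec$id
}

# split a header line (sans marker) into id + desc at first whitespace
split_header <- function(header) {
  header <- sub("[[:space:]]+$", "", header)
  m <- regexpr("[[:space:]]", header)
  if (m == -1L) list(id = header, desc = "")
  else list(id = substr(header, 1L, m - 1L),
            desc = sub("^[[:space:]]+", "", substr(header, m + 1L, nchar(header))))
}

is_fastq_record <- function(rec) !is.null(rec$qual)

# Phred+33 decode
quality_scores <- function(qual) utf8ToInt(qual) - 33L
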