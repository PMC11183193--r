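# Record-set manipulations: range, concat, common (with embedded mode),
# header replacement, and summary statistics.

#' Select a consecutive range of records by ordinal
#'
#' @param records list of [seq_record()]s.
#' @param begin,end signed nonzero ordinals; negative counts from the
#'   end of the set (-1 = last record).
#' @return the records whose 1-based ordinal lies in the resolved
#'   interval; an interval that resolves empty yields an empty list
#'   (not an error).
#' @examples
#' # range_records(recs, 1, -1) is the identity
#' @export
range_records <- function(records, begin, end) {
  if (begin == 0L || end == 0L) stop_usage("range: ordinals must be nonzero")
  n <- length(records)
  if (n == 0L) return(records)
  b <- if (begin < 0L) n + begin + 1L else begin
  e <- if (end < 0L) n + end + 1L else end
  b <- max(1L, b); e <- min(n, e)
  if (b > e) return(list())
  records[b:e]
}

#' Concatenate same-id sequences across files
#'
#' For each id in the first input's order, outputs one record whose
#' sequence (and quality, when every input is FASTQ) is the
#' concatenation of that id's sequence from each input, in input order.
#' Ids absent from any input are skipped and counted (default) or raise
#' an error under `strict`.
#'
#' @param inputs list of record lists, or a character vector of file
#'   paths (read with [read_seqs()]).
#' @param strict error on ids missing from some input instead of
#'   skipping them.
#' @return list of records; attribute `skipped` counts dropped ids.
#' @export
concat_seqs <- function(inputs, strict = FALSE) {
  sets <- load_inputs(inputs, min_files = 2L, what = "concat")
  maps <- lapply(seq_along(sets), function(k) {
    ids <- vapply(sets[[k]], `[[`, "", "id")
    dup <- ids[duplicated(ids)]
    if (length(dup)) {
      stop_data("concat: duplicate id '%s' within input %d", dup[1L], k)
    }
    stats::setNames(seq_along(sets[[k]]), ids)
  })
  all_fastq <- all(vapply(sets, function(s) {
    all(vapply(s, is_fastq_record, logical(1L)))
  }, logical(1L)))
  if (!all_fastq && any(vapply(sets, function(s) {
    any(vapply(s, is_fastq_record, logical(1L)))
  }, logical(1L)))) {
    warning("concat: mixed FASTA/FASTQ inputs; quality dropped", call. = FALSE)
  }
  skipped <- 0L
  out <- list()
  for (rec in sets[[1L]]) {
    idx <- vapply(maps, function(m) m[rec$id] %||% NA_integer_, integer(1L))
    if (anyNA(idx)) {
      if (strict) stop_data("concat: id '%s' missing from input %d",
                            rec$id, which(is.na(idx))[1L])
      skipped <- skipped + 1L
      next
    }
    seqs <- vapply(seq_along(sets), function(k) sets[[k]][[idx[k]]]$seq, "")
    qual <- if (all_fastq) {
      paste(vapply(seq_along(sets), function(k) sets[[k]][[idx[k]]]$qual, ""),
            collapse = "")
    } else NULL
    out[[length(out) + 1L]] <- seq_record(rec$id, paste(seqs, collapse = ""),
                                          desc = rec$desc, qual = qual)
  }
  if (skipped) message(sprintf("concat: skipped %d id(s) missing from some input",
                               skipped))
  attr(out, "skipped") <- skipped
  out
}

load_inputs <- function(inputs, min_files = 2L, what = "operation") {
  if (is.character(inputs)) inputs <- lapply(inputs, read_seqs)
  if (!is.list(inputs) || length(inputs) < min_files) {
    stop_usage("%s requires at least %d inputs", what, min_files)
  }
  inputs
}

#' Records common to every input
#'
#' Default mode keeps records of the first input whose key — the id, or
#' the uppercased sequence when `by_seq` — occurs in every other input
#' (membership is tested through a hash table, never by pairwise string
#' scans).  Embedded mode (`by_seq` required) keeps a first-input record
#' when, for every other input, some sequence there contains it as a
#' substring or it contains some sequence there (containment in either
#' direction, case-insensitive).
#'
#' @inheritParams concat_seqs
#' @param by_seq compare sequences instead of ids.
#' @param embedded substring containment instead of exact equality.
#' @return list of records from the first input, in its order.
#' @export
common_records <- function(inputs, by_seq = FALSE, embedded = FALSE) {
  if (embedded && !by_seq) stop_usage("common: embedded mode requires by_seq")
  sets <- load_inputs(inputs, min_files = 2L, what = "common")
  key_of <- function(rec) if (by_seq) toupper(rec$seq) else rec$id
  if (!embedded) {
    tables <- lapply(sets[-1L], function(s) {
      env <- new.env(hash = TRUE, parent = emptyenv())
      for (rec in s) assign(key_of(rec), TRUE, envir = env)
      env
    })
    keep <- vapply(sets[[1L]], function(rec) {
      k <- key_of(rec)
      all(vapply(tables, function(env) !is.null(env[[k]]), logical(1L)))
    }, logical(1L))
  } else {
    others <- lapply(sets[-1L], function(s) toupper(vapply(s, `[[`, "", "seq")))
    keep <- vapply(sets[[1L]], function(rec) {
      sq <- toupper(rec$seq)
      all(vapply(others, function(pool) {
        any(vapply(pool, function(o) {
          grepl(sq, o, fixed = TRUE) || grepl(o, sq, fixed = TRUE)
        }, logical(1L)))
      }, logical(1L)))
    }, logical(1L))
  }
  sets[[1L]][keep]
}

#' Rewrite record headers with a pattern and template
#'
#' Applies `pattern` (a regular expression) to each full header
#' (id plus description) and substitutes `replacement`, which may
#' contain backreferences (`\\1`), the placeholder `{nr}` (the record's
#' 1-based ordinal, zero-padded to `nr_width` digits), and `{kv}` (the
#' value looked up in `kv_table` under the key captured by the first
#' group).
#'
#' @param records list of [seq_record()]s.
#' @param pattern regular expression matched against the header.
#' @param replacement template string.
#' @param kv_table named character vector, or a 2-column key/value
#'   data.frame; required when `{kv}` is used.
#' @param missing_key `"keep"` (leave the header unchanged) or `"drop"`
#'   (drop the record) when a `{kv}` key has no table entry.
#' @param nr_width zero-pad width for `{nr}` (0 = no padding).
#' @return list of records with rewritten headers.
#' @export
replace_headers <- function(records, pattern, replacement, kv_table = NULL,
                            missing_key = c("keep", "drop"), nr_width = 0L) {
  missing_key <- match.arg(missing_key)
  ok <- tryCatch({ grepl(pattern, ""); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_usage("replace: malformed regular expression '%s'", pattern)
  uses_kv <- grepl("{kv}", replacement, fixed = TRUE)
  if (uses_kv) {
    if (is.null(kv_table)) stop_usage("replace: {kv} requires a key-value table")
    if (is.data.frame(kv_table)) {
      kv_table <- stats::setNames(as.character(kv_table[[2L]]),
                                  as.character(kv_table[[1L]]))
    }
    if (!grepl("\\(", pattern)) {
      stop_usage("replace: {kv} requires a capture group in the pattern")
    }
  }
  out <- list()
  for (k in seq_along(records)) {
    rec <- records[[k]]
    hdr <- record_header(rec)
    if (!grepl(pattern, hdr)) {
      out[[length(out) + 1L]] <- rec
      next
    }
    repl <- replacement
    if (grepl("{nr}", repl, fixed = TRUE)) {
      nr <- if (nr_width > 0L) formatC(k, width = nr_width, flag = "0")
            else as.character(k)
      repl <- gsub("{nr}", nr, repl, fixed = TRUE)
    }
    if (uses_kv) {
      key <- regmatches(hdr, regexec(pattern, hdr))[[1L]][2L]
      val <- kv_table[key]
      if (is.na(val)) {
        if (missing_key == "drop") next
        out[[length(out) + 1L]] <- rec
        next
      }
      repl <- gsub("{kv}", val, repl, fixed = TRUE)
    }
    new_hdr <- sub(pattern, repl, hdr)
    h <- split_header(new_hdr)
    out[[length(out) + 1L]] <- seq_record(h$id, rec$seq, desc = h$desc,
                                          qual = rec$qual)
  }
  out
}

#' Summary statistics of a record set
#'
#' N50 is the length at which the cumulative sum over records sorted by
#' decreasing length first reaches at least half of the total bases.
#' GC% pools base counts over all records (see [gc_fraction()] for the
#' treatment of ambiguity codes).  Q20%/Q30% are the percentage of
#' bases with Phred quality >= 20 / >= 30, over all bases (FASTQ only,
#' NA otherwise).
#'
#' @param records list of [seq_record()]s (possibly empty).
#' @return list of class `seq_stats`: format, n_seqs, sum_len, min_len,
#'   avg_len, max_len, n50, gc_pct, q20_pct, q30_pct.
#' @examples
#' compute_stats(list(seq_record("a", "ACGT", qual = "!!II")))
#' @export
compute_stats <- function(records) {
  n <- length(records)
  fastq <- n > 0L && all(vapply(records, is_fastq_record, logical(1L)))
  if (n == 0L) {
    return(structure(list(format = "FASTA", n_seqs = 0L, sum_len = 0,
                          min_len = 0L, avg_len = 0, max_len = 0L, n50 = 0L,
                          gc_pct = 0, q20_pct = NA_real_, q30_pct = NA_real_),
                     class = "seq_stats"))
  }
  lens <- vapply(records, function(r) nchar(r$seq), integer(1L))
  total <- sum(as.numeric(lens))
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(as.numeric(sorted)) >= total / 2)[1L]]
  gc <- rowSums(vapply(records, function(r) gc_counts(r$seq), numeric(2L)))
  q20 <- q30 <- NA_real_
  if (fastq) {
    scores <- unlist(lapply(records, function(r) quality_scores(r$qual)),
                     use.names = FALSE)
    q20 <- 100 * mean(scores >= 20L)
    q30 <- 100 * mean(scores >= 30L)
  }
  structure(list(format = if (fastq) "FASTQ" else "FASTA",
                 n_seqs = n, sum_len = total,
                 min_len = min(lens), avg_len = total / n, max_len = max(lens),
                 n50 = n50,
                 gc_pct = if (gc[["den"]] > 0) 100 * gc[["num"]] / gc[["den"]] else 0,
                 q20_pct = q20, q30_pct = q30),
            class = "seq_stats")
}

#' @export
print.seq_stats <- function(x, ...) {
  print(stats_row(x, file = "-"), row.names = FALSE)
  invisible(x)
}

stats_row <- function(st, file) {
  data.frame(file = file, format = st$format, type = "DNA",
             num_seqs = st$n_seqs, sum_len = st$sum_len,
             min_len = st$min_len, avg_len = round(st$avg_len, 1),
             max_len = st$max_len, N50 = st$n50,
             `GC(%)` = round(st$gc_pct, 2),
             `Q20(%)` = round(st$q20_pct, 2),
             `Q30(%)` = round(st$q30_pct, 2),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' Statistics table for one or more files
#'
#' @param paths FASTA/FASTQ file paths (any supported compression).
#' @return data.frame with one row per file and the columns file,
#'   format, type, num_seqs, sum_len, min_len, avg_len, max_len, N50,
#'   GC(%), Q20(%), Q30(%).
#' @export
stats_table <- function(paths) {
  do.call(rbind, lapply(paths, function(p) {
    stats_row(compute_stats(read_seqs(p)), file = p)
  }))
}
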