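# Independent brute-force oracles.  These deliberately avoid the
# package's bitmask/byte-offset machinery: matching goes through
# explicit IUPAC character sets, rotation through full enumeration,
# stats through textbook definitions, and .fai entries through a
# separate line-by-line byte count.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_base_match <- function(p, s) {
  ps <- oracle_iupac[[toupper(p)]]
  ss <- oracle_iupac[[toupper(s)]]
  if (is.null(ps) || is.null(ss)) return(FALSE)
  all(ss %in% ps)
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N")
  chars <- rev(strsplit(toupper(x), "")[[1L]])
  paste(comp[chars], collapse = "")
}

# every window on the requested strands of the (optionally doubled)
# sequence, counting per-position set-containment failures
oracle_find_motif <- function(sq, pat, mm, strands = "+", circular = FALSE) {
  L <- nchar(sq); m <- nchar(pat)
  subject <- if (circular) paste0(sq, sq) else sq
  max_start <- if (circular) L else L - m + 1L
  pats <- list(`+` = pat)
  if (strands %in% c("-", "both")) pats[["-"]] <- oracle_revcomp(pat)
  if (strands == "-") pats[["+"]] <- NULL
  rows <- list()
  for (st in names(pats)) {
    pc <- strsplit(pats[[st]], "")[[1L]]
    for (s in seq_len(max_start)) {
      win <- strsplit(substr(subject, s, s + m - 1L), "")[[1L]]
      if (length(win) < m) next
      bad <- sum(!mapply(oracle_base_match, pc, win))
      if (bad <= mm) {
        rows[[length(rows) + 1L]] <-
          data.frame(start = s, end = s + m - 1L, strand = st,
                     mismatches = bad, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, match(out$strand, c("+", "-"))), , drop = FALSE]
}

oracle_least_rotation <- function(x) {
  n <- nchar(x)
  rots <- vapply(0:(n - 1L), function(r) {
    paste0(substr(x, r + 1L, n), substr(x, 1L, r))
  }, "")
  which(rots == min(rots))[1L] - 1L
}

oracle_stats <- function(records) {
  lens <- sapply(records, function(r) nchar(r$seq))
  total <- sum(lens)
  dec <- sort(lens, decreasing = TRUE)
  n50 <- NA_integer_
  acc <- 0
  for (l in dec) {
    acc <- acc + l
    if (acc >= total / 2) { n50 <- l; break }
  }
  chars <- strsplit(toupper(paste(sapply(records, `[[`, "seq"), collapse = "")), "")[[1L]]
  num <- sum(chars %in% c("G", "C", "S"))
  den <- sum(chars %in% c("A", "C", "G", "T", "U", "S"))
  quals <- unlist(lapply(records, function(r) {
    if (is.null(r$qual)) integer() else utf8ToInt(r$qual) - 33L
  }))
  list(n_seqs = length(records), sum_len = total,
       min_len = min(lens), avg_len = total / length(records),
       max_len = max(lens), n50 = n50,
       gc_pct = if (den > 0) 100 * num / den else 0,
       q20_pct = if (length(quals)) 100 * sum(quals >= 20) / length(quals) else NA_real_,
       q30_pct = if (length(quals)) 100 * sum(quals >= 30) / length(quals) else NA_real_)
}

# independent .fai: split raw bytes on LF, count bases per line
oracle_fai <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  txt <- rawToChar(bytes)
  # keep track of byte offsets by re-walking the text line by line
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  # terminator counted on every line (a missing final LF is treated as
  # present, matching the linewidth >= linebases + 1 invariant); the
  # final line's byte_len never feeds any offset
  byte_len <- nchar(lines, type = "bytes") + 1L
  offsets <- cumsum(c(0L, byte_len))[seq_along(lines)]
  entries <- list()
  cur <- NULL
  for (k in seq_along(lines)) {
    ln <- sub("\r$", "", lines[k])
    if (startsWith(ln, ">")) {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
      nm <- strsplit(substring(ln, 2L), "[[:space:]]+")[[1L]][1L]
      cur <- list(name = nm, length = 0L,
                  offset = offsets[k] + byte_len[k],
                  linebases = NA_integer_, linewidth = NA_integer_)
    } else if (nzchar(ln)) {
      if (is.na(cur$linebases)) {
        cur$linebases <- nchar(ln)
        cur$linewidth <- byte_len[k]
      }
      cur$length <- cur$length + nchar(ln)
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- cur
  do.call(rbind, lapply(entries, as.data.frame))
}

random_iupac_string <- function(len, p_ambig = 0.15) {
  core <- c("A", "C", "G", "T")
  # U omitted: it complements to A (never back to U), so involution-style
  # properties hold only on the U-free alphabet; U handling is tested
  # explicitly where it matters
  ambig <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  paste(ifelse(stats::runif(len) < p_ambig,
               sample(ambig, len, replace = TRUE),
               sample(core, len, replace = TRUE)), collapse = "")
}

records_equal <- function(a, b) {
  identical(lapply(a, unclass), lapply(b, unclass))
}
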