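# Transparent compression: format detected by magic bytes on read,
# chosen by file extension on write.  gzip/bzip2/xz go through base R
# connections (which read multi-member streams to completion); zstandard
# goes through arrow's compressed streams.

.magic <- list(
  gzip  = as.raw(c(0x1f, 0x8b)),
  bzip2 = as.raw(c(0x42, 0x5a, 0x68)),
  xz    = as.raw(c(0xfd, 0x37, 0x7a, 0x58, 0x5a, 0x00)),
  zstd  = as.raw(c(0x28, 0xb5, 0x2f, 0xfd))
)

#' Detect the compression format of a byte prefix or file
#'
#' gzip, bzip2, xz and zstandard are recognized by their magic bytes;
#' anything else (including streams shorter than the longest magic) is
#' reported as plain text.
#'
#' @param x a raw vector (the first bytes of a stream) or a file path.
#' @return one of `"plain"`, `"gzip"`, `"bzip2"`, `"xz"`, `"zstd"`.
#' @export
detect_compression <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) stop_data("no such file: %s", x)
    x <- readBin(x, "raw", n = 6L)
  }
  stopifnot(is.raw(x))
  for (fmt in names(.magic)) {
    m <- .magic[[fmt]]
    if (length(x) >= length(m) && identical(x[seq_along(m)], m)) return(fmt)
  }
  "plain"
}

compression_from_ext <- function(path) {
  switch(tolower(tools::file_ext(path)),
         gz = "gzip", bz2 = "bzip2", xz = "xz", zst = "zstd", "plain")
}

# read a (possibly compressed) text source fully, as a character vector
# of lines with terminators removed; "-" reads standard input (assumed
# uncompressed text)
read_source_lines <- function(path) {
  if (identical(path, "-")) {
    return(readLines(file("stdin"), warn = FALSE))
  }
  fmt <- detect_compression(path)
  if (fmt == "zstd") {
    txt <- rawToChar(zstd_read_raw(path))
    if (!nzchar(txt)) return(character())
    return(strsplit(txt, "\n", fixed = TRUE)[[1L]])
  }
  con <- switch(fmt,
                gzip  = gzfile(path, "rt"),
                bzip2 = bzfile(path, "rt"),
                xz    = xzfile(path, "rt"),
                file(path, "rt"))
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

zstd_read_raw <- function(path) {
  src <- arrow::ReadableFile$create(path)
  cis <- arrow::CompressedInputStream$create(src, codec = "zstd")
  on.exit(cis$close())
  chunks <- list()
  repeat {
    buf <- cis$Read(1048576L)$data()
    if (length(buf) == 0L) break
    chunks[[length(chunks) + 1L]] <- buf
  }
  if (!length(chunks)) raw() else do.call(c, chunks)
}

# write lines (LF-terminated) to a destination path, compressing by
# extension; path "-" or a connection writes plain text
write_dest_lines <- function(lines, path) {
  if (inherits(path, "connection")) {
    writeLines(lines, path)
    return(invisible(NULL))
  }
  if (identical(path, "-")) {
    writeLines(lines, stdout())
    return(invisible(NULL))
  }
  fmt <- compression_from_ext(path)
  if (fmt == "zstd") {
    sink_ <- arrow::FileOutputStream$create(path)
    cos <- arrow::CompressedOutputStream$create(sink_, codec = "zstd")
    if (length(lines)) cos$write(charToRaw(paste0(paste(lines, collapse = "\n"), "\n")))
    cos$close()
    return(invisible(NULL))
  }
  con <- switch(fmt,
                gzip  = gzfile(path, "wb"),
                bzip2 = bzfile(path, "wb"),
                xz    = xzfile(path, "wb"),
                file(path, "wb"))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(NULL)
}
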