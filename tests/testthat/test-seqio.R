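test_that("compression formats are detected by magic bytes", {
  expect_identical(detect_compression(as.raw(c(0x1f, 0x8b, 0x08, 0x00))), "gzip")
  expect_identical(detect_compression(as.raw(c(0x42, 0x5a, 0x68, 0x39))), "bzip2")
  expect_identical(detect_compression(as.raw(c(0xfd, 0x37, 0x7a, 0x58, 0x5a, 0x00))), "xz")
  expect_identical(detect_compression(as.raw(c(0x28, 0xb5, 0x2f, 0xfd))), "zstd")
  expect_identical(detect_compression(charToRaw(">se")), "plain")
  expect_identical(detect_compression(raw(0)), "plain")
})

test_that("records round-trip through every compression format", {
  recs <- synth_records(40, seed = 101)
  for (ext in c(".fq", ".fq.gz", ".fq.bz2", ".fq.xz", ".fq.zst")) {
    path <- withr::local_tempfile(fileext = ext)
    write_seqs(recs, path)
    expect_true(records_equal(read_seqs(path), recs), label = ext)
  }
  fa <- synth_records(20, seed = 102, format = "fasta")
  for (wrap in c(0, 7, 60)) {
    path <- withr::local_tempfile(fileext = ".fa.zst")
    write_seqs(fa, path, wrap = wrap)
    expect_true(records_equal(read_seqs(path), fa),
                label = paste("wrap", wrap))
  }
})

test_that("FASTA writing wraps sequence bodies at the requested width", {
  rec <- seq_record("s", strrep("A", 10))
  lines <- format_records(list(rec), wrap = 4)
  expect_identical(lines, c(">s", "AAAA", "AAAA", "AA"))
})

test_that("multiline FASTA and FASTQ parse; quality ends by length, not prefix", {
  r <- read_seqs(text = ">a x\nAC\nGT\n")
  expect_identical(r[[1]]$seq, "ACGT")
  expect_identical(r[[1]]$desc, "x")
  # quality lines legally start with '@' and '+'; sequence is split too
  txt <- "@r1 d\nACGTAC\nGT\n+\n@+II\nII@+\n@r2\nAC\n+\n!~\n"
  r <- read_seqs(text = txt)
  expect_length(r, 2)
  expect_identical(r[[1]]$seq, "ACGTACGT")
  expect_identical(r[[1]]$qual, "@+IIII@+")
  expect_identical(r[[2]]$id, "r2")
})

test_that("CRLF input is tolerated and empty input yields zero records", {
  r <- read_seqs(text = ">a\r\nACGT\r\n")
  expect_identical(r[[1]]$seq, "ACGT")
  expect_identical(read_seqs(text = character()), list())
  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_identical(read_seqs(empty), list())
})

test_that("strict parsing reports malformed FASTQ with a line number", {
  expect_error(read_seqs(text = "@r\nACGT\n+\nIII\n"),
               class = "seqmate_parse_error")
  expect_error(read_seqs(text = "@r\nACGT\n"), class = "seqmate_parse_error")
  err <- expect_error(read_seqs(text = "@r1\nACGT\n+\nIIII\n@r2\nACGT\n+\nII\n"),
                      class = "seqmate_parse_error")
  expect_match(conditionMessage(err), "line")
  expect_error(read_seqs(text = "@r\nAC-T\n+\nIIII\n"),
               class = "seqmate_parse_error")  # gaps forbidden in FASTQ
  expect_silent(read_seqs(text = ">r\nAC-T.\n"))  # but fine in FASTA
})

test_that("multi-member gzip and bzip2 streams read to completion", {
  recs <- synth_records(6, seed = 55)
  for (maker in list(gzfile, bzfile)) {
    part <- function(rs) {
      f <- tempfile()
      on.exit(unlink(f))
      con <- maker(f, "wb"); writeLines(format_records(rs), con); close(con)
      readBin(f, "raw", file.size(f))
    }
    combined <- withr::local_tempfile()
    writeBin(c(part(recs[1:3]), part(recs[4:6])), combined)
    expect_true(records_equal(read_seqs(combined), recs))
  }
})

test_that("FASTA parsing agrees with Biostrings", {
  skip_if_not_installed("Biostrings")
  recs <- synth_records(25, seed = 77, format = "fasta")
  path <- withr::local_tempfile(fileext = ".fa")
  write_seqs(recs, path, wrap = 13)
  ref <- Biostrings::readDNAStringSet(path)
  got <- read_seqs(path)
  expect_identical(vapply(got, `[[`, "", "id"), unname(names(ref)))
  expect_identical(vapply(got, `[[`, "", "seq"), unname(as.character(ref)))
})

test_that("sana equals strict parsing on clean input", {
  txt <- format_records(synth_records(10, seed = 5))
  res <- sana(text = txt)
  expect_identical(res$report$records_discarded, 0L)
  expect_true(records_equal(res$records, read_seqs(text = txt)))
})

test_that("sana resynchronizes around each corruption mode", {
  recs <- synth_records(10, seed = 6)
  txt <- format_records(recs)
  for (mode in c("truncate_qual", "drop_separator", "garbage_block")) {
    bad <- corrupt_fastq(txt, mode, target_record = 5, seed = 1)
    expect_error(read_seqs(text = bad), class = "seqmate_parse_error")
    res <- sana(text = bad)
    expect_identical(vapply(res$records, `[[`, "", "id"),
                     paste0("r", c(1:4, 6:10)), label = mode)
    expect_gte(res$report$records_discarded, 1L)
    expect_identical(res$report$first_error_line, 17L)
  }
  bad <- corrupt_fastq(txt, "cut_tail", target_record = 10, seed = 2)
  expect_error(read_seqs(text = bad), class = "seqmate_parse_error")
  res <- sana(text = bad)
  expect_identical(res$report$records_emitted, 9L)
})

test_that("sana emits nothing (and no error) on pure garbage", {
  res <- sana(text = c("not fastq", "#### 1234", "@@", ""))
  expect_identical(res$report$records_emitted, 0L)
  expect_gte(res$report$records_discarded, 1L)
})
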