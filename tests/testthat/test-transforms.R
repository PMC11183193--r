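make_recs <- function(ids, seqs, quals = NULL) {
  lapply(seq_along(ids), function(k) {
    seq_record(ids[k], seqs[k], qual = quals[k])
  })
}

test_that("range selects ordinals with negative-from-end semantics", {
  recs <- synth_records(10, seed = 301)
  ids <- function(x) vapply(x, `[[`, "", "id")
  expect_identical(ids(range_records(recs, 3, 5)), paste0("r", 3:5))
  expect_identical(ids(range_records(recs, -2, -1)), c("r9", "r10"))
  expect_true(records_equal(range_records(recs, 1, -1), recs))
  expect_identical(range_records(recs, 8, 3), list())  # empty, not an error
  expect_error(range_records(recs, 0, 5), class = "seqmate_usage_error")
})

test_that("concat joins same-id sequences (and qualities) in file order", {
  f1 <- make_recs(c("A", "B"), c("AAA", "CCC"), c("III", "JJJ"))
  f2 <- make_recs("A", "TTT", "KKK")
  expect_message(out <- concat_seqs(list(f1, f2)), "skipped 1")
  expect_length(out, 1)
  expect_identical(out[[1]]$seq, "AAATTT")
  expect_identical(out[[1]]$qual, "IIIKKK")
  expect_identical(attr(out, "skipped"), 1L)
  expect_error(concat_seqs(list(f1, f2), strict = TRUE),
               class = "seqmate_data_error")
  # three inputs concatenate in order
  f3 <- make_recs("A", "GG", "LL")
  out <- suppressMessages(concat_seqs(list(f1, f2, f3)))
  expect_identical(out[[1]]$seq, "AAATTTGG")
  # duplicate ids within one input are an error
  expect_error(concat_seqs(list(make_recs(c("A", "A"), c("T", "G")), f2)),
               class = "seqmate_data_error")
  # mixed FASTA/FASTQ drops quality with a warning
  expect_warning(out <- concat_seqs(list(f1, make_recs(c("A", "B"), c("T", "G")))),
                 "quality dropped")
  expect_null(out[[1]]$qual)
  expect_error(concat_seqs(list(f1)), class = "seqmate_usage_error")
})

test_that("common keeps first-file records present in every other input", {
  f1 <- make_recs(c("a", "b"), c("ACGT", "GGGG"))
  f2 <- make_recs(c("b", "c"), c("TTTT", "CCCC"))
  out <- common_records(list(f1, f2))
  expect_identical(vapply(out, `[[`, "", "id"), "b")
  # sequence mode is case-insensitive
  out <- common_records(list(make_recs("x", "ACGT"), make_recs("y", "acgt")),
                        by_seq = TRUE)
  expect_length(out, 1)
  # embedded: containment in either direction
  out <- common_records(list(make_recs("x", "ACGTACGT"), make_recs("y", "GTAC")),
                        by_seq = TRUE, embedded = TRUE)
  expect_length(out, 1)
  out <- common_records(list(make_recs("x", "GTAC"), make_recs("y", "ACGTACGT")),
                        by_seq = TRUE, embedded = TRUE)
  expect_length(out, 1)
  out <- common_records(list(make_recs("x", "AAAA"), make_recs("y", "CCCC")),
                        by_seq = TRUE, embedded = TRUE)
  expect_length(out, 0)
  expect_error(common_records(list(f1)), class = "seqmate_usage_error")
  expect_error(common_records(list(f1, f2), embedded = TRUE),
               class = "seqmate_usage_error")
})

test_that("exact by_seq common matches the same set regardless of file order", {
  withr::with_seed(33, {
    f1 <- synth_records(30, seed = 41, format = "fasta", length_range = c(5, 8))
    f2 <- synth_records(30, seed = 42, format = "fasta", length_range = c(5, 8))
    ab <- common_records(list(f1, f2), by_seq = TRUE)
    ba <- common_records(list(f2, f1), by_seq = TRUE)
    expect_setequal(toupper(vapply(ab, `[[`, "", "seq")),
                    toupper(vapply(ba, `[[`, "", "seq")))
  })
})

test_that("replace rewrites headers with {nr} and {kv} placeholders", {
  recs <- make_recs(c("a", "b", "c"), c("A", "C", "G"))
  out <- replace_headers(recs, ".+", "seq_{nr}")
  expect_identical(vapply(out, `[[`, "", "id"), paste0("seq_", 1:3))
  out <- replace_headers(recs, ".+", "seq_{nr}", nr_width = 3)
  expect_identical(out[[2]]$id, "seq_002")
  out <- replace_headers(recs, "^(\\S+)", "{kv}", kv_table = c(a = "alpha"))
  expect_identical(vapply(out, `[[`, "", "id"), c("alpha", "b", "c"))
  out <- replace_headers(recs, "^(\\S+)", "{kv}", kv_table = c(a = "alpha"),
                         missing_key = "drop")
  expect_identical(vapply(out, `[[`, "", "id"), "alpha")
  # identity rewrite and error paths
  out <- replace_headers(recs, "^(.*)$", "\\1")
  expect_true(records_equal(out, recs))
  expect_error(replace_headers(recs, "([", "x"), class = "seqmate_usage_error")
  expect_error(replace_headers(recs, ".+", "{kv}"), class = "seqmate_usage_error")
  expect_error(replace_headers(recs, ".+", "{kv}", kv_table = c(a = "z")),
               class = "seqmate_usage_error")  # no capture group
})

test_that("stats reproduce the textbook N50/Q20/Q30 definitions", {
  st <- compute_stats(make_recs(paste0("s", 1:5), vapply(c(2, 3, 4, 5, 6), function(l)
    strrep("A", l), "")))
  expect_identical(st$n50, 5L)
  expect_identical(st$sum_len, 20)
  st <- compute_stats(make_recs("one", strrep("C", 7)))
  expect_identical(c(st$min_len, st$max_len, st$n50), c(7L, 7L, 7L))
  expect_identical(st$avg_len, 7)
  st <- compute_stats(make_recs("q", "ACGT", "!!II"))
  expect_identical(st$q20_pct, 50)
  expect_identical(st$q30_pct, 50)
  st <- compute_stats(list())
  expect_identical(st$n_seqs, 0L)
})

test_that("stats agree with a brute-force reference on random record sets", {
  withr::with_seed(34, {
    for (i in 1:40) {
      n <- sample(1:30, 1)
      recs <- synth_records(n, seed = sample(1e6, 1),
                            length_range = sort(sample(1:60, 2)))
      if (i %% 5 == 0) {  # all-equal-length edge case
        recs <- synth_records(n, seed = sample(1e6, 1),
                              length_range = c(20, 20))
      }
      got <- compute_stats(recs)
      ref <- oracle_stats(recs)
      for (f in names(ref)) {
        expect_equal(got[[f]], ref[[f]], label = f, expected.label = "oracle")
      }
    }
  })
})

test_that("stats_table emits one row per file with the documented columns", {
  f1 <- withr::local_tempfile(fileext = ".fq")
  f2 <- withr::local_tempfile(fileext = ".fa.gz")
  write_seqs(synth_records(5, seed = 35), f1)
  write_seqs(synth_records(3, seed = 36, format = "fasta"), f2)
  df <- stats_table(c(f1, f2))
  expect_identical(nrow(df), 2L)
  expect_identical(names(df), c("file", "format", "type", "num_seqs", "sum_len",
                                "min_len", "avg_len", "max_len", "N50",
                                "GC(%)", "Q20(%)", "Q30(%)"))
  expect_identical(df$format, c("FASTQ", "FASTA"))
  expect_true(is.na(df$`Q20(%)`[2]))
})
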