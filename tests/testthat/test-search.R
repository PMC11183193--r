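test_that("base matching is set containment, not symmetry", {
  expect_true(base_match("R", "A"))
  expect_false(base_match("A", "R"))
  expect_true(base_match("N", "Y"))
  expect_false(base_match("Y", "N"))
  expect_true(base_match("n", "n"))
  expect_true(base_match("r", "G"))
  expect_error(base_match("Z", "A"), class = "seqmate_alphabet_error")
  # exhaustive agreement with the character-set oracle
  codes <- strsplit("ACGTURYSWKMBDHVN", "")[[1]]
  for (p in codes) for (s in codes) {
    expect_identical(base_match(p, s), oracle_base_match(p, s),
                     label = paste(p, s))
  }
})

test_that("find_motif handles mismatches, degeneracy and circular wrap", {
  h <- find_motif("ACGTACGT", "ACGA", max_mismatch = 1)
  expect_identical(h$start, c(1L, 5L))
  expect_identical(h$mismatches, c(1L, 1L))
  h <- find_motif("AAAT", "TAA", circular = TRUE)
  expect_identical(unlist(h[, c("start", "end")], use.names = FALSE), c(4L, 6L))
  h <- find_motif("AGT", "ARN")
  expect_identical(h$start, 1L)
  expect_identical(h$mismatches, 0L)
  expect_error(find_motif("ACG", "ACGT"), class = "seqmate_data_error")
  expect_error(find_motif("ACGT", "ACG", max_mismatch = 3),
               class = "seqmate_data_error")
})

test_that("hit geometry invariants hold", {
  withr::with_seed(11, {
    for (i in 1:30) {
      sq <- random_iupac_string(sample(10:50, 1), p_ambig = 0.05)
      pat <- random_iupac_string(sample(2:6, 1), p_ambig = 0.2)
      circ <- sample(c(TRUE, FALSE), 1)
      h <- find_motif(sq, pat, max_mismatch = 1, strands = "both",
                      circular = circ)
      if (!nrow(h)) next
      expect_true(all(h$end - h$start + 1 == nchar(pat)))
      expect_true(all(h$start >= 1 & h$start <= nchar(sq)))
      expect_true(all(h$mismatches <= 1))
      if (!circ) expect_true(all(h$end <= nchar(sq)))
    }
  })
})

test_that("exact linear search equals a naive substring scan", {
  withr::with_seed(12, {
    for (i in 1:200) {
      sq <- paste(sample(c("A", "C", "G", "T"), sample(8:64, 1), replace = TRUE),
                  collapse = "")
      m <- sample(1:min(8, nchar(sq)), 1)
      pat <- substr(random_iupac_string(8, p_ambig = 0), 1, m)
      got <- find_motif(sq, pat)$start
      naive <- integer()
      for (s in 1:(nchar(sq) - m + 1)) {
        if (substr(sq, s, s + m - 1) == pat) naive <- c(naive, s)
      }
      expect_identical(got, naive)
    }
  })
})

test_that("search agrees with the all-windows oracle across modes", {
  withr::with_seed(13, {
    for (i in 1:100) {
      sq <- random_iupac_string(sample(5:64, 1), p_ambig = 0.1)
      pat <- random_iupac_string(sample(1:min(8, nchar(sq)), 1), p_ambig = 0.25)
      mm <- sample(0:min(2, nchar(pat) - 1), 1)
      for (circ in c(FALSE, TRUE)) for (st in c("+", "both")) {
        got <- find_motif(sq, pat, mm, strands = st, circular = circ)
        ref <- oracle_find_motif(sq, pat, mm, strands = st, circular = circ)
        expect_equal(got[, c("start", "end", "strand", "mismatches")], ref,
                     ignore_attr = TRUE,
                     label = sprintf("case %d circ=%s st=%s", i, circ, st))
      }
    }
  })
})

test_that("both-strand hits are the union of plus scans of both patterns", {
  withr::with_seed(14, {
    for (i in 1:25) {
      sq <- random_iupac_string(sample(10:60, 1), p_ambig = 0.05)
      pat <- random_iupac_string(4, p_ambig = 0.1)
      both <- find_motif(sq, pat, 1, strands = "both")
      plus <- find_motif(sq, pat, 1, strands = "+")
      minus <- find_motif(sq, revcomp(pat), 1, strands = "+")
      expect_identical(both$start[both$strand == "+"], plus$start)
      expect_identical(both$start[both$strand == "-"], minus$start)
    }
  })
})

test_that("junction-spanning occurrences need circular mode, and are unique", {
  sq <- "CCGGAATT"        # "TTCC" occurs only across the junction
  expect_identical(nrow(find_motif(sq, "TTCC")), 0L)
  h <- find_motif(sq, "TTCC", circular = TRUE)
  expect_identical(nrow(h), 1L)
  expect_identical(h$start, 7L)
  expect_identical(h$end, 10L)   # wrapped: end beyond L documents the wrap
})

test_that("grep selects by id, inverts, and warns on '>'/'@' patterns", {
  recs <- list(seq_record("a", "AAAA"), seq_record("b", "CCCC"),
               seq_record("c", "GGGG"))
  expect_identical(vapply(grep_records(recs, "b"), `[[`, "", "id"), "b")
  expect_identical(vapply(grep_records(recs, "b", invert = TRUE), `[[`, "", "id"),
                   c("a", "c"))
  expect_warning(out <- grep_records(recs, ">b"), "not a part")
  expect_length(out, 0)
  expect_identical(vapply(grep_records(recs, "^[ab]$", use_regex = TRUE),
                          `[[`, "", "id"), c("a", "b"))
  expect_error(grep_records(recs, character()), class = "seqmate_usage_error")
})

test_that("grep by sequence honours mismatches and strands", {
  recs <- list(seq_record("x", "TTACGTTT"), seq_record("y", "TTTTTTTT"))
  expect_identical(vapply(grep_records(recs, "ACGT", by_seq = TRUE), `[[`, "", "id"),
                   "x")
  # revcomp("ACGT") present in y only via mismatch
  expect_identical(vapply(grep_records(recs, "ACGA", by_seq = TRUE,
                                       max_mismatch = 1), `[[`, "", "id"),
                   "x")
})

test_that("locate emits one sorted row per hit with strand labels", {
  recs <- list(seq_record("s", "AAACGTAA"))
  df <- locate_records(recs, "ACGT", strands = "both")
  expect_identical(nrow(df), 2L)            # palindrome: both strands
  expect_identical(df$start, c(3L, 3L))
  expect_identical(df$strand, c("+", "-"))
  expect_identical(names(df),
                   c("seqID", "pattern", "strand", "start", "end", "mismatches"))
  df <- locate_records(list(seq_record("s", "AAAT")), "TAA", circular = TRUE)
  expect_identical(df$end, 6L)
})
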