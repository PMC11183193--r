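---
title: "seqmate: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqmate: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqmate)
```

This vignette records how the toolkit's procedures are defined, which
knobs matter, and where the design was genuinely open — so that results
are interpretable and the package's choices are auditable.

## Records, alphabet, and coordinates

A record is (id, description, sequence, optional quality).  The id is
the first whitespace-delimited token of the header; reconstruction of
`>`/`@` + id + description round-trips byte-exactly.  Sequences are
over the IUPAC nucleotide alphabet; `U` is treated as `T` for
complementation and matching so RNA input is tolerated, with one
deliberate asymmetry: the complement of `U` is `A`, and `A`
complements back to `T`, so double reverse-complementation normalizes
`U` to `T` rather than restoring it.  Gap characters `-` and `.` are
legal in FASTA (they complement to themselves and never match any
pattern base) and rejected in FASTQ.  Quality is always Phred+33;
Phred+64 is intentionally not auto-detected — silent misdetection on
modern data would be worse than a loud, fixed convention.  All
user-facing coordinates are 1-based inclusive; a negative coordinate k
counts from the end as L + k + 1 (−1 is the last base).

GC content needed a decision for ambiguity codes, which different tools
make differently: here `S` (G or C) counts in both numerator and
denominator, all other ambiguity codes and gaps count in neither.  An
all-ambiguous sequence has GC 0 by convention rather than NaN.

## Parsing and compression

Format is detected from the first non-blank character, compression from
magic bytes on read and from the filename extension on write
(`.gz`, `.bz2`, `.xz`, `.zst`).  gzip/bzip2/xz go through base R
connections, which read multi-member (concatenated) streams to
completion; zstandard streams go through `arrow`.  Multiline FASTA and
FASTQ are supported; in FASTQ the quality block ends when its
accumulated length reaches the sequence length — never on a line
prefix, because `@` and `+` are legal quality characters.  CRLF input
is tolerated and stripped; output is always LF.  Files are read
whole-and-then-parsed rather than through record-at-a-time iterators:
at the desk scale this package targets (up to millions of lines) this
is the idiomatic R trade-off, and only `watch` makes a true
bounded-memory claim (its state is O(bins), independent of stream
length).

`sana`, the recovery parser, scans damaged FASTQ and resynchronizes at
the next line starting with `@` that heads a fully valid 4-line record:
line 3 starts with `+`, quality length equals sequence length, and the
sequence is over the IUPAC alphabet.  The 4-line validity rule is this
package's choice of heuristic; its practical consequence is that
*multiline* FASTQ is repaired only to the extent that intact records
happen to be 4-line.  Every problem is counted (`records_discarded` is
the number of contiguous damaged regions), never raised.

`.fai` indexing follows the samtools five-column layout: name, length
in bases, byte offset of the first sequence byte, bases per full line,
bytes per full line including the terminator (so CRLF files index with
linewidth = linebases + 2, and a missing final newline is counted as if
terminated, keeping linewidth ≥ linebases + 1 uniform).  Region fetch
seeks directly using offset arithmetic and reads only the covering
bytes.  Staleness is judged by file-size consistency only — a
same-size in-place edit defeats it, which matches the cheap convention
of the field rather than hashing whole files.

## Degenerate search model

Matching is case-insensitive set containment: pattern base *p* matches
subject base *s* iff the base set of *s* is a subset of that of *p*.
The asymmetry is intentional: a degenerate *pattern* position accepts
the bases it denotes, but an ambiguous *subject* base (an `N` in a
read) matches only a pattern at least as degenerate, so low-quality
N-runs cannot fake primer sites.  Whether to make this symmetric was an
open call; containment was chosen because the asymmetric failure mode
(spurious hits in N-rich reads) is the damaging one in practice.

Mismatches are Hamming — substitutions only, no indels; search with
indels is alignment, which is out of scope.  Minus-strand search scans
the plus strand with the reverse-complemented pattern and reports
plus-strand coordinates (start < end always).  Circular search scans
the first L + |p| − 1 positions of the doubled sequence and keeps hits
with start ≤ L: every physical window, including junction-spanning
ones, is reported exactly once, with end > L encoding the wrap.  All
overlapping hits are reported; the scan is the naive O(L·|p|) one,
vectorized over windows — adequate at desk scale and trivially
auditable against the brute-force oracle the tests carry.

## Amplicons

The reverse primer is supplied 5'→3' as synthesized (wet-lab
convention); the tool reverse-complements it internally.  A pairing
requires the forward site to end strictly before the reverse site
starts; all pairings are reported, sorted by (f_start, then outermost
r_end), and `first_only` selects the leftmost-outermost one.  Each
primer site independently honours the pair's `max_mismatch` budget.
Minus-strand amplicons run the identical procedure on the
reverse-complemented template; extraction therefore always reads the
amplicon 5'→3' on the strand the primers define, and the record
description carries the plus-strand template interval and strand.

The region spec for partial/flanking extraction is relative to the
amplicon with primers included: +1 is the first base of the forward
site, −1 the last base of the reverse site, negative k resolving to
A + k + 1 against the amplicon length A.  Coordinates resolving outside
[1, A] are allowed only in flanking mode and map into the template;
requests beyond the template raise an error rather than clip — silent
clipping would corrupt downstream length assumptions.  On circular
templates, pairings may wrap the junction (coordinates beyond L,
sequence linearized across the origin), including the case where the
reverse site sits upstream of the forward site in the arbitrary
linearization.

## Digests

Each record contributes a 128-bit MD5 of its canonical sequence;
identifiers and descriptions never contribute.  Canonicalization
uppercases and strips gaps; with `circular` it rotates to the
lexicographically least rotation, computed by Booth's linear-time
algorithm (ties on periodic strings break to the smallest offset); with
`both_strands` it takes the lexicographic minimum over the two strands.
`circular` and `both_strands` are independent flags, both off by
default — whether strand should be canonicalized for a circular genome
is a question about the data, so it is exposed rather than guessed.

The file digest is the sum of record digests modulo 2^128 (32-bit limb
arithmetic held exactly in doubles).  Modular addition rather than XOR
is deliberate: XOR would cancel duplicated records pairwise, while the
sum gives true multiset semantics — order-invariant, duplication- and
deletion-sensitive.  The `md5sum128-v1` tag is embedded in every output
line; digests are comparable only within a tag, and byte-compatibility
with any other tool's digest is a non-goal.  MD5 here is a content
fingerprint, not a security boundary.

## Statistics and the stream monitor

N50 is the length at which the cumulative sum over records sorted by
decreasing length first reaches *at least* half the total (≥, not >,
on descending lengths — conventions differ, so the choice is stated).
Q20/Q30 are percentages of bases at Phred ≥ 20/≥ 30 over all bases;
GC% pools counts over records under the rule above.  An empty input
yields a zero row, not an error.

`watch` tallies one value per record — length, GC, or per-read mean
quality defined as −10·log₁₀ of the mean error probability
10^(−Q/10); averaging probabilities rather than scores makes one
terrible base dominate, which reflects the read's actual expected
error rate.  Bin edges are fixed up front from (min, max) defaults of
0–10,000 for length, 0–60 for mean quality and 0–1 for GC; values
outside clamp into the end bins.  Fixed edges and clamping are what
true online operation requires — re-binning would need the stream
again — and keep sum(counts) = n exactly.  Rendering every k records
affects display only; final tallies are invariant to the period.
Time-based flushing is deliberately absent (record-count periodicity is
deterministic and testable).

## Synthetic data

The generator is a pure function of its seed (the caller's RNG state is
saved and restored).  Defaults emulate a modern short-read set: 100–150
nt reads, uniform base composition, uniform Phred 30–40 quality.  It
does *not* emulate position-dependent error profiles, adapter
contamination, chimeras, or realistic quality correlation — so passing
tests demonstrate structural correctness of parsing, search, and
accounting, not robustness to every real-world artefact.
`corrupt_fastq` introduces exactly one named structural defect per
target record (shortened quality, deleted separator, replaced garbage
block, truncated tail), leaving all other bytes untouched, so recovery
tests can assert exact survivor sets.  `plant_amplicon` places all of
its planted substitutions in one randomly chosen primer site: since the
search budget applies per primer, this guarantees a budget of n − 1
misses the site, making the recovery-threshold property sharp.

## Problem sizes and verification

The test suite checks each operation against an independent brute-force
oracle written in terms of explicit character sets and textbook
definitions: all-windows scans for search (200 random cases across
linear/circular × strand modes), full rotation enumeration for Booth's
algorithm (1,000 strings including periodic ones), an independent
byte-offset scan for `.fai` (20 layout variants covering CRLF, missing
final newline, wrap widths 1–500), and a reference implementation for
statistics (100 random record sets).  Digest invariances use a
500-record file with 100 shuffles, 100 rotations and 100 point
mutations; recovery uses 10 damaged records per corruption mode in a
500-record file; round-trips use 1,000 records through all five
compression formats.  These sizes were chosen to exercise boundary
structure (junctions, ties, clamps, empty inputs) while keeping the
whole suite fast enough to run habitually.

## Known limitations

No random access into compressed files or FASTQ (no bgzf virtual
offsets); no protein alphabet; no indel-tolerant search; no
Phred+64; `sana` repairs FASTQ only; `--threads` is accepted for
interface compatibility but execution is serial — the contract here is
correctness and composability, not parallel throughput.
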