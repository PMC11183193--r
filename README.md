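# seqmate

Day-to-day sequence work — subsetting reads, hunting primer sites,
comparing shuffled FASTQ files, indexing references — is dominated not by
alignment but by robust plumbing: files arrive gzip/bzip2/xz/zstd
compressed, records wrap across lines, transfers truncate reads
mid-record, primers carry IUPAC degeneracy, and plasmid assemblies start
at arbitrary origins.  `seqmate` is an R toolkit (library + subcommand
CLI) for exactly this layer of analysis, aimed at bioinformaticians who
live in pipelines and at R users who want these operations scriptable
without leaving the language.

## What it computes

**Degenerate motif search.** A window of the subject matches a pattern
position-wise under set containment: pattern base *p* matches subject
base *s* iff set(*s*) ⊆ set(*p*) (so `R` in a primer accepts `A` or `G`,
but an `N` in a read never spuriously matches a specific primer base).
Matches allow up to *m* Hamming mismatches (substitutions only), on
either strand (minus-strand hits are plus-strand scans of the
reverse-complemented pattern), and on circular sequences by scanning the
first *L* + |*p*| − 1 windows of the doubled sequence — each physical
site, including junction-spanning ones, is reported exactly once, with
`end > L` marking the wrap.

**Amplicon extraction.** Given primers F and R (both 5'→3' as
synthesized), the template is scanned for F and for revcomp(R); every
non-overlapping pairing with the forward site upstream delimits an
amplicon, extracted whole or via signed coordinates relative to it
(+1 = first base of F's site, −1 = last base of R's site).

**Order/rotation-invariant digests.** Each record contributes
MD5(canonical sequence), where canonicalization uppercases, strips gaps,
optionally rotates to Booth's lexicographically least rotation (O(L),
for circular molecules) and optionally takes the lexicographic minimum
over strands.  The file digest is the sum of record digests modulo
2^128 — invariant to record order, but (unlike XOR) still sensitive to
duplicated records.  Two FASTQ files with the same reads in any order,
or two rotations of the same plasmid, digest identically.

**Error-tolerant FASTQ recovery (`sana`).** On malformed input the
parser resynchronizes at the next `@` line heading a structurally valid
4-line record (line 3 starts `+`, |qual| = |seq|, sequence over the
IUPAC alphabet), emitting every intact record and counting damaged
regions instead of aborting.

**The rest of the toolbox:** samtools-compatible `.fai` indexing with
random-access region fetch (negative coordinates count from the
sequence end), record `range`/`concat`/`common`(incl. substring
"embedded" mode)/`replace`(with `{nr}` and `{kv}` templates), summary
statistics (N50 = length where the descending cumulative sum first
reaches half the total; Q20/Q30 = % of bases with Phred ≥ 20/30; GC%
with `S` counted and other ambiguity codes excluded), and a streaming
`watch` histogram whose memory is bounded by its bin count, using
per-read mean quality −10·log₁₀(mean 10^(−Q/10)).

## Worked example

```r
library(seqmate)

reads <- synth_records(1000, seed = 42)      # 1,000 synthetic 100-150 nt reads
write_seqs(reads, "reads.fq.gz")             # compression chosen by extension
stats_table("reads.fq.gz")
#>         file format type num_seqs sum_len min_len avg_len max_len N50 GC(%) Q20(%) Q30(%)
#>  reads.fq.gz  FASTQ  DNA     1000  125722     100   125.7     150 129 50.13    100    100

locate_records(reads[1:3], "GGTAGG", max_mismatch = 1, strands = "both")
#>  seqID pattern strand start end mismatches
#>     r1  GGTAGG      +     9  14          1
#>     r1  GGTAGG      +   116 121          1
#>     r2  GGTAGG      -     1   6          1
#>     r2  GGTAGG      +    79  84          1
```

N50 = 129 means half of the 125,722 sequenced bases sit in reads of
129 nt or longer; each `locate` row is one mismatch-tolerant hit in
plus-strand coordinates (the `-` row is a site whose reverse complement
matches the query).

Shuffling a file does not change its digest:

```r
file_digest(reads)
#> 88f43828f2fd39aa705e070d7e9b7f77  md5sum128-v1  1000
file_digest(sample(reads))
#> 88f43828f2fd39aa705e070d7e9b7f77  md5sum128-v1  1000
```

Recovering a planted 16S-style amplicon with one primer mismatch:

```r
tpl <- plant_amplicon(seed = 7, flank_len = 60, insert_len = 120,
                      forward = "GTGCCAGCAGCCGCGGTAA",
                      reverse = "GGACTACGAGGGTATCTAAT", n_mismatches = 1)
pair <- primer_pair("GTGCCAGCAGCCGCGGTAA", "GGACTACGAGGGTATCTAAT",
                    max_mismatch = 1)
p <- find_amplicons(tpl$record, pair, first_only = TRUE)
p
#>  f_start f_end r_start r_end amp_start amp_end strand mismatches
#>       61    79     200   219        61     219      +          1
extract_amplicon(tpl$record, p, c(1, -1))
#> <seq_record FASTA> tmpl tmpl:61-219 strand=+ mismatches=1  (159 bp)
#>   GTGCCAGCAGCCGCGGTAATTTGGGGGTATCTGGTAAACTGCCAGGGCACTTTGACG...
```

The 159 bp extract is exactly forward primer + 120 nt insert + reverse
primer site (19 + 120 + 20).

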