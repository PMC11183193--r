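Package: seqmate
Title: Streaming FASTA/FASTQ Toolkit with Degenerate Motif Search,
    Amplicon Extraction, and Order-Invariant Digests
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Read and write FASTA/FASTQ in plain, gzip, bzip2, xz and
    zstandard form, with multiline records supported; recover intact
    records from corrupted FASTQ streams; search motifs and primers using
    IUPAC degenerate codes with mismatches, on both strands of linear or
    circular sequences; extract amplicons delimited by primer pairs;
    compute order- and rotation-invariant content digests for comparing
    shuffled read files and re-linearized circular assemblies; index
    FASTA files for random access (samtools .fai compatible); transform
    record sets (range, concat, common, replace) and summarize them (N50,
    GC percent, Q20/Q30); and monitor read properties online in a stream
    with memory bounded by the histogram size.  A subcommand-style
    command line interface mirrors the library functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    digest,
    stats,
    tools,
    utils,
    withr
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
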