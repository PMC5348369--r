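Package: backsplicer
Title: Detection and Cohort Analysis of Circular RNA Back-Splice Junctions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies circular RNAs (circRNAs) from the unmapped fraction of
    aligned RNA-seq libraries. Unmapped reads are split into terminal 20-mer
    anchors that are realigned exactly against the reference genome; anchor
    pairs mapping in head-to-tail (3' to 5') orientation seed back-splice
    junction candidates whose breakpoints are refined against canonical AG/GT
    splice signals. Candidates are filtered by junction-read support, genomic
    size, and genomic uniqueness of the junction flanks, then annotated with
    gene context (intra-gene, inter-gene) and exon-boundary status against
    Ensembl-style gene models. Cohort-level utilities count unique circRNAs
    across samples, call tumor-specific circRNAs by interval containment
    against matched normal tissue, normalize counts by unmapped library size,
    and relate per-sample circRNA numbers to an 11-gene proliferation score.
    A deterministic simulator generates genomes with planted circRNAs, reads,
    gene models, and cohorts for download-free testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    rtracklayer,
    IRanges,
    S4Vectors,
    GenomicRanges,
    jsonlite,
    parallel,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
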