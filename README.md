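# backsplicer

Circular RNAs (circRNAs) are covalently closed transcripts formed when a
downstream splice donor joins back to an upstream splice acceptor. The
head-to-tail (back-splice) junction they create does not exist in the
linear genome, so RNA-seq reads spanning it fail normal alignment and land
in the unmapped fraction of the library. **backsplicer** mines that
fraction: it detects back-splice junctions by terminal-anchor realignment,
filters them, annotates them against gene models, and provides
cohort-level circRNA statistics — all backed by a deterministic simulator
so every property is testable without external data.

The package is aimed at transcriptomics researchers who already have
aligned RNA-seq BAM/SAM files (with unmapped reads retained) plus a
reference FASTA and an Ensembl-style GTF, and who want a reproducible,
configurable circRNA catalog per sample and across a cohort.

## Method at a glance

For each unmapped read of length *L*, the terminal 20-mers are realigned
exactly against the genome. A read seeds a junction candidate when both
anchors map uniquely to the same chromosome and strand with the 5' anchor
*downstream* of the 3' anchor (the reverse of collinear order) within a
span cap (default 100 kb). The breakpoint *b* is refined so that
read[1..b] matches the genome ending at the circle end *e* and
read[b+1..L] matches starting at the circle start *s*, with zero
mismatches, accepting only breakpoints flanked by canonical splice
signals: `AG` at *s*−2..*s*−1 and `GT` at *e*+1..*e*+2 (plus strand; `AC`/
`CT` on the plus-strand genome for minus-strand circles). Supporting reads
are merged per junction, and three filters are applied:

1. **expression** — ≥ 5 supporting junction reads (configurable);
2. **genomic size** — inclusive span *e* − *s* + 1 ≥ 6 bases;
3. **validation** — 50-base head and tail flanks must each occur exactly
   once genome-wide (internal exact mode, or external BLAT).

Final candidates are annotated as `intra_gene` / `inter_gene` /
`unannotated` and `exon_exon_boundary` / `within_exon` / `other`, and
written as a TSV report plus a junction FASTA whose 50-base sequences
center the fusion at position 25|26. Cohort utilities count unique
circRNAs across samples, call tumor-specific circles by interval
containment against normal tissue, normalize counts per million unmapped
reads, and correlate per-sample circRNA numbers with an 11-gene
proliferation score (mean z across BIRC5, CCNB1, CDC20, CEP55, MKI67,
NDC80, NUF2, PTTG1, RRM2, TYMS, UBE2C).

See `vignettes/circrna-detection-methods.Rmd` for the full model,
parameter rationale, and design notes.

## Worked example

Simulate a fixture (2 × 100 kb genome, 10 planted circles, 1,000 linear
decoy reads) and run detection on it:

```r
library(backsplicer)

fix_dir <- tempfile("demo")
cmd_simulate(fix_dir, seed = 7, n_chroms = 2, chrom_len = 100000,
             n_circles = 10, linear_n = 1000)

cfg <- run_config(genome_path    = file.path(fix_dir, "genome.fa"),
                  gtf_path       = file.path(fix_dir, "genes.gtf"),
                  alignment_path = file.path(fix_dir, "reads.sam"),
                  out_dir        = file.path(fix_dir, "out"),
                  sample_id      = "demo")
res <- cmd_detect(cfg)
res
#> sample_result 'demo': 10 circRNA(s), 1117 unmapped reads
res$records[, 1:7]
```

```
 chrom start   end strand n_reads size  gene_class
  chr1  6395  9708      +      18 3314  intra_gene
  chr1 32779 37524      -      12 4746  inter_gene
  chr1 53302 57114      +      19 3813  intra_gene
  chr1 76274 77610      -      11 1337  inter_gene
  chr1 80875 83880      -       9 3006  intra_gene
  chr2 11868 13688      -      11 1821  intra_gene
  chr2 27146 29883      -       7 2738 unannotated
  chr2 49089 50402      -      10 1314  intra_gene
  chr2 64700 68520      +       6 3821 unannotated
  chr2 89768 90693      +      14  926  intra_gene
```

All 10 planted junctions are recovered at their exact coordinates with
exact supporting-read counts; the per-stage log shows every one of the
1,000 linear decoys rejected before seeding:

```r
res$log
#> n_unmapped  n_short  n_with_n  n_multi_mapping  n_not_head_to_tail  n_no_breakpoint  n_junction_reads
#>       1117        0         0                0                1000                0               117
```

The output directory contains `demo_report.tsv` (the table above, with
gene names and exon-boundary classes), `demo_junctions.fa` (50-base fused
junction sequences, e.g. `>chr1:6395-9708:+`), and `demo_params.json`
(the exact run configuration). Multi-sample cohorts are analyzed with
`cmd_cohort()`, which writes a per-group summary (totals, unique counts,
unique-to-samples ratio, 10% recurrence, tumor-specific counts), a
tumor-specific coordinate table, and a statistics JSON. A thin shell
wrapper with `detect` / `cohort` / `simulate` subcommands is installed at
`inst/scripts/backsplicer`.

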