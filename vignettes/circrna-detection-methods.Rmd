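---
title: "Detecting circular RNAs from unmapped reads: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circular RNAs from unmapped reads: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(backsplicer)
```

## The problem

Circular RNAs (circRNAs) arise when a downstream splice donor is joined
back to an upstream splice acceptor, producing a covalently closed
transcript. The resulting head-to-tail (back-splice) junction sequence does
not exist in the linear genome, so RNA-seq reads that span it fail ordinary
alignment and accumulate in the unmapped fraction of the library. That
failure is the signal this package exploits: the unmapped pile is mined for
reads whose two ends map in the "wrong" (3'-to-5') order.

## Detection model

For each unmapped read the first and last `anchor_len` bases (default
20 nt) are taken as anchors and realigned exactly (zero mismatches, both
strands) against the reference via a precomputed constant-width dictionary
(`Biostrings::PDict`). A read seeds a candidate only when

* both anchors map **uniquely** (exactly one genomic hit each),
* to the same chromosome and strand,
* with the read-5' anchor strictly *downstream* of the read-3' anchor on
  the transcribed strand (the reverse of collinear order), and
* an implied genomic span of at most `max_span` (default 100,000 bases).

The breakpoint is then refined: for each split position `b` between
`anchor_len` and `read_len - anchor_len`, the read prefix of length `b`
must match the genome ending at a putative circle end `e` and the suffix
must match starting at a putative circle start `s`, with zero mismatches
over the whole read. A breakpoint is accepted only when the canonical
splice signals flank the circle: `AG` immediately upstream of `s` (the
acceptor) and `GT` immediately downstream of `e` (the donor). For a
minus-strand circle the same signals, read on the transcribed strand,
appear on the plus-strand genome as `AC` at `s-2..s-1` and `CT` at
`e+1..e+2`; minus-strand reads are reverse-complemented into
forward-genome orientation before extension, and the breakpoint index `b`
is counted on that orientation. If several breakpoints qualify — possible
when a short motif repeats across the junction — the smallest `b` is
chosen, a deterministic tie-break. Candidates with no signal-flanked
breakpoint are dropped entirely, so every reported junction carries the
canonical signal.

Reads supporting identical `(chrom, start, end, strand)` junctions are then
merged; a read identifier counts once per junction even when both mates of
a pair support it. Coordinates are 1-based inclusive throughout, with
conversion to other conventions confined to file-format boundaries.

### Why exact matching

The anchor realignment and breakpoint extension are exact rather than
mismatch-tolerant. This makes every desk-scale result reproducible against
a brute-force enumeration (the test suite checks anchor alignment against a
naive substring scan and breakpoint choice against exhaustive enumeration),
and it makes the unique-anchor requirement meaningful. The cost is
sensitivity on error-containing reads: the simulator has a sequencing-error
option, but errored reads are simply lost to detection, which is the
documented behaviour, and the option defaults to 0.

## The three filters

* **Expression filter** — keep junctions with at least `min_reads`
  supporting reads (default 5).
* **Genomic size filter** — keep junctions whose tail-to-head genomic
  distance is at least `min_size` bases (default 6). The distance is the
  inclusive span `end - start + 1`, consistent with the 1-based inclusive
  coordinates used everywhere; at the default threshold the inclusive and
  exclusive conventions differ only for 5–6-base spans.
* **Validation (uniqueness) filter** — keep junctions whose 50-base
  (`flank_len`) head flank (starting at `start`) and tail flank (ending at
  `end`) each occur exactly once genome-wide, counting both strands and
  truncating at chromosome edges. The default `internal` mode counts exact
  occurrences; an `external_blat` mode shells out to a BLAT executable for
  near-match sensitivity on real genomes, where repetitive regions are
  rarely exact copies. `flank_len` must be at least the anchor length; 50
  was chosen to match the junction-FASTA scale.

Each filter's predicate is per-candidate, so the final set is invariant to
filter order (tested). Note one interaction worth knowing: a junction whose
flank is *exactly* duplicated elsewhere also has duplicated anchor 20-mers,
so its reads are usually discarded earlier by the unique-anchor rule. The
uniqueness filter still matters for real data, where BLAT-level similarity
is broader than exact 20-mer identity, and the test suite exercises it
directly on candidates built from the planted truth.

## Annotation

Gene context is assigned from the circle's two boundary positions against
gene spans (strand-agnostic, since the targeted library protocols are
typically unstranded): one gene containing both ends is `intra_gene`; two
or more distinct genes hit is `inter_gene`; no gene hit is `unannotated`.
A junction with exactly one genic end is reported `unannotated` with no
gene listed — it is neither a clean single-gene product nor evidence of a
multi-gene fusion; gene-level spans (not transcript isoforms) are used.
Exon-boundary status is exact-coordinate: `exon_exon_boundary` when the
start equals some annotated exon start *and* the end equals some exon end;
`within_exon` when both ends are strictly inside exons; `other` otherwise.
The `other` category is deliberate: intronic or intergenic ends are common
enough that the two named categories do not partition real candidates.

## Outputs

The per-sample report is a TSV with location, support, size, and the two
annotation classes. The junction FASTA gives each circle a
`total_len`-base sequence (default 50) built as the last 25 bases of the
circle followed by its first 25, so the fusion sits exactly between
positions 25 and 26 — a symmetric split that centers the junction for
primer design or motif scanning. Circles smaller than 25 bases contribute
`min(span, 25)` per side with no wrap-around; wrap-around would duplicate
sequence, so truncation is explicit. Minus-strand records are
reverse-complemented into transcript orientation, which preserves the
junction's position at the midpoint.

## Cohort analysis

Across samples, a *unique* circRNA is a distinct `(chrom, start, end)`
coordinate counted once regardless of how many samples carry it; strand is
ignored for cross-sample identity. The per-group summary reports totals,
unique counts, the unrounded unique-to-samples ratio, and recurrence (a
circle seen in at least 10% of samples, inclusive at the boundary).

Tumor-specific calling uses strict interval containment: a tumor circle
identical to, or fully inside, a normal circle on the same chromosome is
*common* (smaller circles within a normal circle's genomic region are
assumed to share its regulatory context); everything else is
tumor-specific. Containment, rather than any overlap, is the minimal
reading of "smaller circles in the same region" and is verifiable against
an O(n·m) brute-force check, which the tests do up to 1000×1000 intervals.

Counts are normalized per million unmapped reads — the unmapped total, not
the library total, because the unmapped fraction is the substrate the
detector actually sees; the scale constant is configurable.

The proliferation axis is an 11-gene panel (BIRC5, CCNB1, CDC20, CEP55,
MKI67, NDC80, NUF2, PTTG1, RRM2, TYMS, UBE2C). The per-sample score is the
mean across panel genes of each gene's z-score over the cohort — a
documented proxy that preserves the structure of risk-of-relapse
proliferation scoring (a single proliferation scalar per sample) without
published per-gene coefficients. A zero-variance gene contributes zero with
a warning. Group comparisons use the paired t-test on matched tumor/normal
pairs and Welch's unequal-variance t-test otherwise, both two-sided;
identical paired vectors return statistic 0 and p = 1, while constant
nonzero differences are a zero-variance error rather than a spurious
infinity.

## What the simulator emulates — and what it does not

The generator plants circles into an i.i.d. random genome (default GC
0.41), writes the strand-appropriate splice signals at their boundaries,
assigns support counts, and builds gene models so planted circles cycle
through the four annotation categories. Reads are 50 nt, the back-splice
fusion offset is uniform over interior positions at least one anchor
length from each read end (so both anchors always map and planted recovery
can be exact), and linear decoy reads are contiguous genome substrings.
Default study conditions for the end-to-end fixture: 2 chromosomes ×
100 kb, 10 circles with spans 60–5,000 bases and support 5–20 reads, mixed
strands, 1,000 linear decoys.

The cohort generator draws proliferation scores from a standard normal
(standardized exactly across the cohort, so the panel reproduces them to
machine precision), and circRNA counts as
`round(mean_group + r·sd·score + eps)` with `eps ~ N(0, sd·sqrt(1-r²))`,
giving population correlation `r` within each group. Defaults — tumor mean
20, normal-adjacent mean 25, count SD 8, target r −0.22, unmapped library
sizes uniform over 5–22 million — are on the scale of per-sample circRNA
counts and library sizes reported for breast RNA-seq cohorts and cell
lines.

What passing tests on this substrate show: the detection geometry, signal
logic, filters, annotations, and cohort statistics are implemented
correctly and deterministically. What they do not show: performance on real
libraries, where reads carry errors, anchors multi-map in repeat families,
splice signals deviate from GT–AG, expression is isoform-structured, and
coverage is uneven. The simulator makes no attempt at GC bias, quality
modeling, or isoform reconstruction.

## Numerical and degenerate-input choices

* All randomness flows through one seeded generator per operation; every
  seeded command is byte-reproducible, and multi-sample runs are
  embarrassingly parallel with serial-identical outputs (tested).
* Reads shorter than `2 × anchor_len` are skipped and counted; anchors
  containing `N` yield no alignments; `N` in the genome matches nothing
  (exact matching over A/C/G/T only).
* Ties among valid breakpoints: smallest offset in forward-genome read
  orientation.
* `start = end` circles are legal intervals of size 1 (and are removed by
  the default size filter).
* Degenerate statistics (zero variance, n < 2) are errors at the function
  level; the cohort driver records the message in its statistics output
  instead of aborting a whole run.

## Problem sizes used by the test suite

The suite runs entirely on generated data: the end-to-end fixture above
(about 1,120 unmapped reads), 100 random 1.5-kb genomes for the
uniqueness-filter oracle comparison, 1000×1000 random interval sets for
the containment oracle, cohorts of 500 + 500 samples for correlation
recovery, and 1,000 replicate 20+20 cohorts for the paired-t type-I-error
check. These sizes keep every property exactly checkable by brute force
while exercising the same code paths a full-scale run uses.

## Limitations

Exact-match detection is deliberately conservative; inter-chromosomal
(fusion) junctions, gapped or mismatched anchors, linear splice discovery,
and UMI handling are out of scope. Gene annotation is gene-span based;
transcript-isoform-aware exon numbering is not attempted. The uniqueness
filter's internal mode is exact and therefore stricter than BLAT on real
repeats; use the external mode when a BLAT binary is available.
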