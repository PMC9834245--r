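---
title: "Methods: simulating and processing dual-barcoded long-read single-cell libraries"
author: "lrcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and processing dual-barcoded long-read single-cell libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrcell)
```

## The problem

Full-length single-cell RNA-seq on long-read (Nanopore-class) platforms
labels each cell with a *pair* of barcodes: a 3' barcode attached to the
oligo-dT primer during reverse transcription, and a 24-nt 5' barcode added
with the PCR primer after pooling. With N RT barcodes and M PCR barcodes
the combinatorial space addresses N x M cells per run (32 x 96 = 3072 with
the default whitelists). Every molecule additionally carries a unique
molecular identifier (UMI) so that amplification duplicates can be
collapsed into molecule counts.

The difficulty is the error rate of the platform: several percent of
bases are wrong, so none of the fixed-sequence landmarks of a read can be
found by exact matching. `lrcell` approaches the whole pipeline through
bounded edit distance: barcodes live on a whitelist with a guaranteed
minimum pairwise Levenshtein distance (11 for the default 96 x 24-nt
design), reads are anchored by semi-global alignment of their terminal
adapters, and UMIs are deduplicated by count-aware single-edit
clustering. Because a real run of this protocol is far too large to ship
with a package, the simulator is a first-class module: it generates
whitelists, a toy multi-isoform transcriptome, spike-ins, and
error-corrupted reads with a complete truth table, and every downstream
module is validated against that truth.

## Read model and simulator

A library read is a declarative chain of segments
(`read_layout()`). The default, modeled on oligo-dT–UMI–barcode RT primer
designs, is

```
5'-[adapter 22nt]-[PCR barcode 24nt]-[cDNA insert]-[polyA 20nt]-
   [UMI 8nt]-[RT barcode 24nt]-[adapter 22nt]-3'
```

with every length and both adapter literals configurable, so the exact
architecture of a particular kit can be dropped in (the first and last
segments must be adapters, because they are the anchors). The RT barcode
length (24 nt) and UMI length (8 nt) are design defaults of this package;
real kits vary and both are parameters.

Per-cell gene molecule counts are negative binomial with log-normal
per-gene means (`expression_model()`, mean 2 molecules/gene/cell,
dispersion 0.5), isoform identity is drawn from per-gene Dirichlet
proportions (concentration 1.5), and spike-in molecules are
Poisson(capture efficiency x concentration). Each molecule receives a
uniform random UMI and `1 + Poisson(1)` reads, emulating amplification
duplicates. Reads are corrupted by an independent per-base error model
(defaults 3% substitution, 2% insertion, 2% deletion — Nanopore-era error
behavior; substitutions never re-emit the original base), optionally
end-truncated, and reverse-complemented with probability 1/2. A
configurable fraction of reads drops one structural segment (an adapter
or the polyA) to emulate incomplete library structures; these are flagged
in the truth table. The simulator does not model signal-level artifacts
(homopolymer-specific error, realistic quality strings) or chimeric
reads; conclusions about those failure modes cannot be drawn from passing
tests here.

The spike-in panel is synthetic: 50 species, concentrations log-uniform
over 0.1–1000 relative molarity (four orders of magnitude, the dynamic
range of commercial panels), sequence lengths 300–800 nt. At capture
efficiency 0.05 and 100 cells this yields a desk-scale library of a few
tens of thousands of reads.

## Demultiplexing

Orientation is decided by aligning both terminal adapters against both
strands (semi-global, i.e. the whole adapter against any substring of the
read end) and taking the strand with the smaller summed edit distance;
a read with no adapter within distance 6 on either strand is
undetermined. Adapters are searched only in 150-nt end windows, which
keeps parsing linear in read length.

Barcode and UMI windows are then derived arithmetically from the anchor
coordinates. Because indels shift those windows, barcode assignment
aligns each whitelist barcode semi-globally against the extracted window
plus 4 flanking bases on each side. A barcode is accepted iff the best
whitelist hit is within `max_dist = 5` *and* beats the runner-up by
`min_margin = 2`. The defaults leave headroom: observed per-barcode error
counts at these error rates are below 3 in the median, while the
whitelist guarantees distance >= 11 between entries, so a unique nearest
neighbor is guaranteed up to 5 errors. The polyA tail is detected as a
run of >= 15 A with at most one interruption within the 150 nt adjacent
to its expected position — tolerant of a single basecall error inside
the tail. Every read lands in exactly one bucket (assigned / ambiguous /
too-distant / incomplete / malformed); ambiguous and too-distant reads
are written to a reject file rather than dropped.

The package reports completeness on simulated data slightly below
`1 - broken fraction` at default error rates, because a polyA hit by two
or more interior errors legitimately fails detection; with an error-free
model the equality is exact, which is how the round-trip identity is
tested.

## UMI deduplication and quantification

Deduplication is *directional* clustering at edit distance 1 (the
standard count-aware scheme): connect u -> v when dist(u, v) <= 1 and
count(u) >= 2 count(v) - 1, and grow clusters from count maxima by
directed reachability. Naive single-linkage at long-read error rates
chains distinct molecules together; the count ratio rule prevents that
while still absorbing error copies of abundant UMIs. With `max_dist = 0`
the scheme degenerates to counting distinct sequences, which is the
contract used for exact round-trip tests. Gene-level counting
deduplicates per cell x gene and transcript-level per cell x transcript;
totals can differ when isoform assignment is ambiguous, which is why the
level is explicit in `count_molecules()` inputs.

Spike-in accuracy is summarized as the Pearson correlation between
log10 concentration and log10 mean UMI count per cell, excluding
spike-ins with zero mean (no pseudocount; a linear variant is provided
because the choice of transform is a convention, not a result).
Sensitivity is summarized by a saturation curve: subsample each cell's
reads without replacement on a depth grid, re-deduplicate, and report
median genes/transcripts detected.

## Transcript classification

Models are classified against the reference by junction chains:
FSM (chain identical to a reference transcript), ISM (contiguous
sub-chain), NIC (all donors/acceptors known at the locus, chain novel),
NNC (>= 1 novel splice site), plus genic / antisense / fusion /
intergenic — the SQANTI-standard eight categories. NIC splits into CJ
(every junction pair known), CS (novel pairing of known sites) and IR
(an exon spanning a reference intron); IR is tested first. Single-exon
models are genic unless they span a reference intron (NIC/IR) or fall
within a single-exon reference transcript (FSM by containment) — the
containment rule exists so that an annotation classified against itself
is FSM everywhere, including single-exon pseudogenes. Junction
canonicity reads strand-corrected intron-terminal dinucleotides from the
genome; GT..AG, GC..AG and AT..AC count as canonical. The generator
writes canonical motifs at every genomic intron, so generated
annotations audit at exactly 1.0 and engineered fixtures carry known
fractions.

## QC analyses

Species mixing: each cell is labeled by its majority species at purity
threshold 0.9 (inclusive) given >= 100 reads; below that coverage the
cell is `low_coverage` rather than force-called. Both thresholds are
package defaults, exposed as parameters.

Pseudogene/parent resolution assigns a read to the candidate with
strictly fewer mismatches (ties ambiguous); the simulator generates
pairs at an exact, configurable divergence (default 2 substitutions over
the parent's mature sequence, the near-identity regime of processed
pseudogenes) so resolution accuracy can be measured against truth.
Pair co-expression uses Spearman correlation across cells (robust to
count skew; Pearson available), BH correction, and sign-consistent
classification at adjusted p < 0.05. Note that under BH the expected
null classification rate is far below the nominal alpha; the raw
p-values carry the ~5% null rate.

## Differential statistics

DE uses the two-tailed Wilcoxon rank-sum test per gene on
counts-per-10k, log1p-normalized values: exact p-values when both groups
have <= 8 cells and ties permit, otherwise the normal approximation with
tie correction. DTU is a chi-square homogeneity test on the isoform x
group table of aggregated counts, with Fisher's exact fallback for
sparse 2x2 tables — a deliberately minimal stand-in isolated behind its
own interface so a richer model can be swapped in. Consequences of a
significant DTU event compare dominant isoforms per group:
a coding -> non-coding (e.g. nonsense-mediated-decay biotype) switch is a
coding-potential change; a switch between coding isoforms with different
CDS identity keys (the annotated CDS exon chain; no ORF prediction) is a
protein alteration.

## Numerical and design choices

* Edit distances are unit-cost Levenshtein throughout (`utils::adist`
  for global, a small compiled kernel for semi-global anchoring and
  whitelist search, with early abandoning once a candidate provably
  cannot beat the runner-up). Both kernels are tested against a plain
  quadratic DP oracle.
* Whitelist generation is seeded rejection sampling with a retry cap of
  1e6; at 96 barcodes x 24 nt x distance 11 random candidates almost
  always pass, so the cap is never approached.
* Ties: barcode assignment treats a tie for best hit as ambiguous;
  dedup orders UMIs by count then lexicographically; dominant-isoform
  ties resolve to the first transcript in gene order.
* Degenerate inputs return empty, typed results (empty FASTQ, empty UMI
  set) or explicit errors (zero-variance spike-ins, < 3 usable
  spike-ins, single-barcode audits).
* Regression sizes used by the suite: 10,000-read parses for barcode
  error audits, 100-cell/50-spike full pipelines for spike-in accuracy,
  2,000-gene null DE and 1,000-gene null DTU calibrations. These are the
  package's chosen desk-scale study conditions; they are small enough to
  run anywhere yet large enough for the stated tolerances.

## Known limitations

The simulator's independence assumptions (i.i.d. per-base errors,
uniform UMIs, no ambient RNA, no doublets, no strand bias) make the
round-trip tests necessary but not sufficient evidence for real-data
behavior. Alignment and reference-guided assembly are delegated to
external tools; the BAM ingestion path assumes CB/UB tags are present.
The DTU test models aggregated counts, not per-cell overdispersion, and
will be anticonservative for strongly correlated cells; treat its
calibration as holding under the stated simulation model.
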