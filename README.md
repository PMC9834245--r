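# lrcell

Processing toolkit for **combinatorially barcoded full-length long-read
single-cell RNA-seq**.

In this library design, each cell's cDNA carries a 3' barcode attached
during reverse transcription and a 24-nt 5' barcode added during PCR
after pooling, so N RT barcodes × M PCR barcodes address N × M cells in
one sequencing run (32 × 96 = 3072 with the default whitelists), and
every molecule carries an 8-nt unique molecular identifier (UMI). On a
long-read platform with percent-level base error, none of these
landmarks can be found by exact matching. `lrcell` treats the whole
pipeline as a bounded-edit-distance problem:

* **Whitelist design** — barcode sets with a guaranteed minimum pairwise
  Levenshtein distance *d* (default 96 × 24 nt at *d* ≥ 11), so that a
  read barcode with *e* < *d*/2 errors has a unique nearest whitelist
  entry.
* **Demultiplexing** — semi-global alignment anchors the terminal
  adapters; barcode/UMI windows are derived from the anchors; a barcode
  is assigned iff its best whitelist hit is within `max_dist = 5` and
  beats the runner-up by `min_margin = 2`.
* **Quantification** — directional UMI clustering at edit distance 1
  (merge *u* → *v* when `count(u) ≥ 2·count(v) − 1`), sparse
  feature × cell matrices, spike-in concentration/count correlation, UMI
  set matching, saturation curves.
* **Classification** — transcript models vs a reference annotation into
  FSM / ISM / NIC (CJ, CS, IR) / NNC / genic / antisense / fusion /
  intergenic, plus GT..AG-family splice-junction canonicity audits.
* **QC** — dual-species (barnyard) contamination calls, whitelist
  distance audits, pseudogene/parent read resolution by mismatch count,
  pseudogene–parent co-expression.
* **Differential statistics** — Wilcoxon rank-sum differential
  expression, chi-square differential transcript usage (DTU), and
  protein-consequence calls for significant DTU events (isoform switch
  vs coding→NMD switch).

A full **simulator** with configurable read layout, Nanopore-like error
model and complete truth tables is part of the package, so every stage
is testable without any external data.

## Worked example

Simulate a 100-cell spike-in library, demultiplex it, deduplicate UMIs
and measure quantification accuracy:

```r
library(lrcell)

rt  <- generate_whitelist(32, 24, 11, seed = 101, name = "rt",  id_prefix = "rt")
pcr <- generate_whitelist(96, 24, 11, seed = 102, name = "pcr", id_prefix = "pcr")
pcr
#> <barcode_whitelist 'pcr'> 96 barcodes of 24 nt, min pairwise distance >= 11

audit <- whitelist_distance_audit(pcr)
audit$min        # 11  (over all 4560 pairs)

sp  <- spikein_panel(n = 50, seed = 11)       # 0.1-1000 relative molarity
sim <- simulate_reads(100, rt, pcr, spikeins = sp,
                      capture_efficiency = 0.05, seed = 11)
length(sim$reads)
#> 27494

dm <- demultiplex(sim$reads, default_layout(), rt, pcr)
round(dm$stats$fractions, 4)
#>    assigned   ambiguous too_distant  incomplete
#>      0.9007      0.0001      0.0055      0.0937

reads <- assign_reads_truth(dm$assignments, sim$truth)
mol   <- count_molecules(reads, max_dist = 1)
mat   <- build_count_matrix(mol, kind = "spikein")
dim(mat); sum(mat)
#> 47 spike-ins x 100 cells; 21823 molecules

ercc_correlation(mat, sp$panel)$r
#> 0.983
```

Reading the numbers: at default error rates (3% substitution, 2%
insertion, 2% deletion) 90% of reads demultiplex to the correct cell
(the ~9% incomplete reads are mostly polyA tails disrupted by two or
more errors), and after directional UMI deduplication the mean molecule
count per spike-in tracks its true concentration with Pearson r = 0.98
on log10 scales — comfortably above the 0.85 working threshold for an
accurate UMI-based protocol. Three of the 50 spike-ins sit below the
capture limit at this depth and are excluded as zero-count.

A thin command-line front end over the same functions is installed with
the package (`inst/cli/lrcell`): subcommands `simulate`, `demux`,
`quantify`, `classify`, `qc-whitelist` and `diff`.

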