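Package: lrcell
Title: Processing Toolkit for Combinatorially Barcoded Long-Read Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of full-length long-read single-cell
    RNA-seq libraries that label cells with a combinatorial pair of
    reverse-transcription and PCR barcodes. Provides a read simulator with a
    configurable library layout and Nanopore-like error model, structure-aware
    demultiplexing by bounded edit distance, directional UMI deduplication and
    sparse count-matrix construction, spike-in accuracy and saturation
    metrics, transcript-model classification against a reference annotation
    (FSM/ISM/NIC/NNC with NIC subtypes) with splice-junction canonicity
    auditing, dual-species contamination and pseudogene/parent QC, and
    differential expression / differential transcript usage statistics with
    protein-consequence calling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Matrix,
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    Rsamtools,
    GenomicAlignments,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
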