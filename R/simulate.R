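#' Expression model for simulated cells
#'
#' Minimal standard single-cell model: per-cell per-gene molecule counts are
#' negative binomial with a per-gene mean (drawn log-normal around
#' `mean_molecules`) and common dispersion; within a gene, molecules are
#' distributed over isoforms by per-gene Dirichlet proportions.
#'
#' @param mean_molecules Mean molecules per gene per cell (scale of the
#'   log-normal gene means).
#' @param gene_mean_sdlog Log-sd of per-gene means.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param isoform_alpha Dirichlet concentration for isoform proportions.
#' @param duplication_mean Mean extra reads per molecule (Poisson); each
#'   molecule yields 1 + Pois(duplication_mean) reads, emulating
#'   amplification duplicates that UMI deduplication must collapse.
#' @return Object of class `expression_model`.
#' @export
expression_model <- function(mean_molecules = 2, gene_mean_sdlog = 1,
                             dispersion = 0.5, isoform_alpha = 1.5,
                             duplication_mean = 1) {
  stopifnot(mean_molecules > 0, dispersion > 0, isoform_alpha > 0,
            duplication_mean >= 0)
  structure(list(mean_molecules = mean_molecules,
                 gene_mean_sdlog = gene_mean_sdlog,
                 dispersion = dispersion, isoform_alpha = isoform_alpha,
                 duplication_mean = duplication_mean),
            class = "expression_model")
}

#' Simulate a combinatorially barcoded full-length long-read library
#'
#' Every cell receives a unique (RT barcode, PCR barcode) pair, so the
#' addressable space is |RT whitelist| x |PCR whitelist| cells (e.g.
#' 32 x 96 = 3072) and larger requests are rejected. Per-cell gene
#' molecule counts follow the expression model; spike-in molecule counts
#' are Poisson(capture_efficiency x concentration). Each molecule gets a
#' random UMI and 1 + Poisson(duplication) reads; each read is the layout
#' concatenation of its segments, independently corrupted under the error
#' model, and reverse-complemented with probability 1/2 when the layout is
#' strandable. A configurable fraction of reads is structurally broken
#' (one anchor/polyA segment dropped) and flagged incomplete in the truth
#' table.
#'
#' @param cells Number of cells (<= combinatorial barcode space).
#' @param rt_whitelist,pcr_whitelist [barcode_whitelist] objects.
#' @param layout A [read_layout]; segment lengths must match the whitelists
#'   and UMI length.
#' @param transcriptome Optional result of [generate_transcriptome()].
#' @param expression An [expression_model] (used when a transcriptome is
#'   given).
#' @param spikeins Optional result of [spikein_panel()].
#' @param capture_efficiency Fraction of spike-in molecules captured.
#' @param error_model An [error_model].
#' @param broken_fraction Fraction of reads with a dropped structural
#'   segment (5'/3' adapter or polyA), hence incomplete library structure.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `reads` (named character vector) and `truth` (data
#'   frame: read_id, cell_id, rt_barcode_id, pcr_barcode_id, umi_sequence,
#'   source_feature_id, gene_id, is_spikein, structure_complete).
#' @export
simulate_reads <- function(cells, rt_whitelist, pcr_whitelist,
                           layout = default_layout(),
                           transcriptome = NULL,
                           expression = expression_model(),
                           spikeins = NULL, capture_efficiency = 0.05,
                           error_model = lrcell::error_model(),
                           broken_fraction = 0, seed = NULL) {
  stopifnot(inherits(rt_whitelist, "barcode_whitelist"),
            inherits(pcr_whitelist, "barcode_whitelist"),
            inherits(layout, "read_layout"),
            broken_fraction >= 0, broken_fraction <= 1)
  n_rt <- length(rt_whitelist); n_pcr <- length(pcr_whitelist)
  space <- n_rt * n_pcr
  if (cells > space)
    stop(sprintf(
      "cells (%d) exceeds the combinatorial barcode space of %d (%d RT x %d PCR)",
      cells, space, n_rt, n_pcr))
  if (is.null(transcriptome) && is.null(spikeins))
    stop("provide a transcriptome, a spike-in panel, or both")
  seg <- layout$segments
  for (kind in c("rt_barcode", "pcr_barcode")) {
    wl <- if (kind == "rt_barcode") rt_whitelist else pcr_whitelist
    if (kind %in% seg$kind && seg$length[seg$kind == kind][1] != wl$length)
      stop(sprintf("layout %s length does not match the whitelist", kind))
  }
  if (!is.null(seed)) set.seed(seed)

  # cells fill RT positions first (32 cells pooled per PCR tube)
  rt_idx <- ((seq_len(cells) - 1L) %% n_rt) + 1L
  pcr_idx <- ((seq_len(cells) - 1L) %/% n_rt) + 1L
  rt_ids <- names(rt_whitelist$barcodes)[rt_idx]
  pcr_ids <- names(pcr_whitelist$barcodes)[pcr_idx]
  cell_ids <- paste(rt_ids, pcr_ids, sep = "_")

  mol <- list()
  if (!is.null(transcriptome)) {
    tinfo <- transcriptome$transcript_info
    genes <- unique(tinfo$gene_id)
    gmeans <- stats::rlnorm(length(genes),
                            meanlog = log(expression$mean_molecules),
                            sdlog = expression$gene_mean_sdlog)
    iso_props <- lapply(genes, function(g) {
      tx <- tinfo$transcript_id[tinfo$gene_id == g]
      setNames(rdirichlet1(rep(expression$isoform_alpha, length(tx))), tx)
    })
    names(iso_props) <- genes
    counts <- matrix(
      rnbinom(length(genes) * cells, mu = rep(gmeans, cells),
              size = 1 / expression$dispersion),
      nrow = length(genes))
    nz <- which(counts > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      tx_of <- mapply(function(g, k) {
        pr <- iso_props[[g]]
        list(sample(names(pr), k, replace = TRUE, prob = pr))
      }, genes[nz[, 1]], counts[nz], SIMPLIFY = TRUE)
      mol$tx <- data.frame(
        cell = rep(nz[, 2], counts[nz]),
        feature = unlist(tx_of, use.names = FALSE),
        stringsAsFactors = FALSE)
      mol$tx$gene <- tinfo$gene_id[match(mol$tx$feature, tinfo$transcript_id)]
      mol$tx$spike <- FALSE
    }
  }
  if (!is.null(spikeins)) {
    panel <- spikeins$panel
    lam <- capture_efficiency * panel$concentration
    k <- rpois(nrow(panel) * cells, rep(lam, cells))
    idx <- which(k > 0)
    if (length(idx)) {
      sp <- ((idx - 1L) %% nrow(panel)) + 1L
      cl <- ((idx - 1L) %/% nrow(panel)) + 1L
      mol$sp <- data.frame(cell = rep(cl, k[idx]),
                           feature = rep(panel$spike_id[sp], k[idx]),
                           gene = rep(panel$spike_id[sp], k[idx]),
                           spike = TRUE, stringsAsFactors = FALSE)
    }
  }
  molecules <- do.call(rbind, mol)
  if (is.null(molecules) || nrow(molecules) == 0L)
    stop("no molecules were generated; increase expression or capture rates")

  umi_len <- seg$length[seg$kind == "umi"][1]
  if (is.na(umi_len)) umi_len <- 8L
  molecules$umi <- random_dna(nrow(molecules), umi_len)

  # amplification duplicates
  nreads <- 1L + rpois(nrow(molecules), expression$duplication_mean)
  ridx <- rep.int(seq_len(nrow(molecules)), nreads)
  reads <- molecules[ridx, , drop = FALSE]
  n <- nrow(reads)
  read_ids <- sprintf("read%07d", seq_len(n))

  feature_seq <- character(0)
  if (!is.null(transcriptome))
    feature_seq <- c(feature_seq, setNames(
      as.character(transcriptome$transcripts),
      names(transcriptome$transcripts)))
  if (!is.null(spikeins))
    feature_seq <- c(feature_seq, setNames(
      as.character(spikeins$sequences), names(spikeins$sequences)))

  seg_strings <- function(rows) {
    parts <- lapply(seq_len(nrow(seg))[rows], function(i) {
      switch(seg$kind[i],
        fixed_adapter = rep(seg$sequence[i], n),
        pcr_barcode = unname(
          pcr_whitelist$barcodes[pcr_ids])[pcr_of_read],
        rt_barcode = unname(rt_whitelist$barcodes[rt_ids])[rt_of_read],
        umi = reads$umi,
        polyA = rep(strrep("A", seg$length[i]), n),
        insert = unname(feature_seq[reads$feature]))
    })
    parts
  }
  cell_of_read <- reads$cell
  rt_of_read <- cell_of_read   # index into per-cell vectors
  pcr_of_read <- cell_of_read
  parts <- seg_strings(rep(TRUE, nrow(seg)))

  # structurally broken reads: drop one anchor or polyA segment
  broken <- rep(FALSE, n)
  if (broken_fraction > 0) {
    broken[sample(n, round(broken_fraction * n))] <- TRUE
    droppable <- which(seg$kind %in% c("fixed_adapter", "polyA"))
    drop_seg <- sample(droppable, sum(broken), replace = TRUE)
    for (s in unique(drop_seg)) {
      hit <- broken
      hit[broken] <- drop_seg == s
      parts[[s]][hit] <- ""
    }
  }
  raw <- do.call(paste0, parts)
  out <- corrupt_sequences(raw, error_model)
  if (layout$strandable) {
    flip <- runif(n) < 0.5
    if (any(flip)) out[flip] <- revcomp(out[flip])
  }
  names(out) <- read_ids

  truth <- data.frame(
    read_id = read_ids,
    cell_id = cell_ids[cell_of_read],
    rt_barcode_id = rt_ids[cell_of_read],
    pcr_barcode_id = pcr_ids[cell_of_read],
    umi_sequence = reads$umi,
    source_feature_id = reads$feature,
    gene_id = reads$gene,
    is_spikein = reads$spike,
    structure_complete = !broken,
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(reads = out, truth = truth)
}

#' Write a simulated run to disk
#'
#' Writes `reads.fastq.gz`, `truth.tsv`, both whitelists, and (when given)
#' the spike-in table.
#'
#' @param sim Result of [simulate_reads()].
#' @param dir Output directory.
#' @param rt_whitelist,pcr_whitelist,spikeins Optional objects to write
#'   alongside the reads.
#' @export
write_simulation <- function(sim, dir, rt_whitelist = NULL,
                             pcr_whitelist = NULL, spikeins = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$reads, file.path(dir, "reads.fastq.gz"))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(rt_whitelist))
    write_whitelist(rt_whitelist, file.path(dir, "rt_whitelist.tsv"))
  if (!is.null(pcr_whitelist))
    write_whitelist(pcr_whitelist, file.path(dir, "pcr_whitelist.tsv"))
  if (!is.null(spikeins))
    write_spikeins(spikeins$panel, file.path(dir, "spikeins.tsv"))
  invisible(dir)
}
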