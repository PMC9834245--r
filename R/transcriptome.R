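#' Generate a toy multi-isoform transcriptome with pseudogene/parent pairs
#'
#' Lays out multi-exon genes along a single synthetic contig, draws one or
#' more isoforms per gene by exon skipping, and optionally appends
#' processed-pseudogene copies: a pseudogene is the parent's mature
#' (spliced) sequence carrying exactly `pseudogene_divergence` substitutions,
#' placed as a distinct single-exon gene at a distinct locus — the
#' near-identity regime (e.g. 2 substitutions over a ~400-bp stretch) that
#' makes pseudogene reads hard to resolve from parent reads. All genomic
#' introns are written with canonical GT..AG motifs (strand-corrected), so
#' junction-canonicity audits of the generated annotation are exact.
#' Isoform biotypes are labeled `protein_coding` or
#' `nonsense_mediated_decay` to support DTU consequence calling; coding
#' isoforms carry CDS records spanning their exons.
#'
#' @param n_genes Number of multi-exon genes (>= 1).
#' @param isoforms_per_gene Integer range `c(min, max)` (or scalar) of
#'   isoform counts drawn per gene; extra isoforms skip internal exons.
#' @param pseudogene_pairs Number of pseudogene/parent pairs (parents are
#'   the first genes).
#' @param pseudogene_divergence Exact substitution count separating each
#'   pseudogene from its parent's mature sequence; must be >= 1.
#' @param seed Integer seed (NULL to use the current RNG state).
#' @param exon_count_range,exon_len_range,intron_len_range Structural
#'   ranges (bases).
#' @param nmd_fraction Probability that a non-primary isoform is annotated
#'   nonsense_mediated_decay rather than protein_coding.
#' @param minus_strand_fraction Fraction of genes on the minus strand.
#' @param spacer Intergenic gap in bases.
#' @param contig Contig name.
#' @return List with `annotation` (GRanges in GTF row layout), `genome`
#'   (DNAStringSet), `transcripts` (DNAStringSet of mature sequences),
#'   `transcript_info` (data frame: transcript_id, gene_id, biotype,
#'   cds_key), and `pseudogene_pairs` (data frame).
#' @export
generate_transcriptome <- function(n_genes = 20, isoforms_per_gene = c(1, 3),
                                   pseudogene_pairs = 0,
                                   pseudogene_divergence = 2, seed = NULL,
                                   exon_count_range = c(3, 6),
                                   exon_len_range = c(100, 300),
                                   intron_len_range = c(80, 300),
                                   nmd_fraction = 0.25,
                                   minus_strand_fraction = 0.3,
                                   spacer = 500L, contig = "chrS") {
  stopifnot(n_genes >= 1)
  if (pseudogene_pairs > 0 && pseudogene_divergence < 1)
    stop("pseudogene_divergence must be >= 1 (0 would make the pair indistinguishable)")
  if (pseudogene_pairs > n_genes)
    stop("pseudogene_pairs cannot exceed n_genes")
  if (!is.null(seed)) set.seed(seed)
  if (length(isoforms_per_gene) == 1L)
    isoforms_per_gene <- rep(isoforms_per_gene, 2L)

  sample_range <- function(rng, n = 1L)
    if (rng[1] == rng[2]) rep(rng[1], n) else
      sample(seq(rng[1], rng[2]), n, replace = TRUE)

  genes <- vector("list", n_genes)
  cursor <- spacer + 1L
  for (g in seq_len(n_genes)) {
    ne <- sample_range(exon_count_range)
    elen <- sample_range(exon_len_range, ne)
    ilen <- if (ne > 1) sample_range(intron_len_range, ne - 1L) else integer(0)
    starts <- integer(ne); ends <- integer(ne)
    pos <- cursor
    for (i in seq_len(ne)) {
      starts[i] <- pos
      ends[i] <- pos + elen[i] - 1L
      pos <- ends[i] + (if (i < ne) ilen[i] else 0L) + 1L
    }
    strand <- if (runif(1) < minus_strand_fraction) "-" else "+"
    # isoform exon subsets: isoform 1 keeps all exons, others skip internal
    n_iso <- sample_range(isoforms_per_gene)
    chains <- list(seq_len(ne))
    if (n_iso > 1 && ne >= 3) {
      internal <- seq(2L, ne - 1L)
      tries <- 0L
      while (length(chains) < n_iso && tries < 50L) {
        tries <- tries + 1L
        k <- sample(seq_along(internal), 1L)
        drop <- sort(sample(internal, k))
        cand <- setdiff(seq_len(ne), drop)
        if (!any(vapply(chains, identical, logical(1), y = cand)))
          chains <- c(chains, list(cand))
      }
    }
    genes[[g]] <- list(gene_id = sprintf("G%03d", g), strand = strand,
                       starts = starts, ends = ends, chains = chains,
                       biotype = "protein_coding")
    cursor <- ends[ne] + spacer + 1L
  }

  # reserve pseudogene loci (single exon, length = parent mature length)
  parents <- if (pseudogene_pairs > 0) seq_len(pseudogene_pairs) else integer(0)
  pseudo <- vector("list", length(parents))
  for (k in seq_along(parents)) {
    p <- genes[[parents[k]]]
    mat_len <- sum(p$ends - p$starts + 1L)
    pseudo[[k]] <- list(gene_id = sprintf("PSG%03d", k),
                        parent_id = p$gene_id, start = cursor,
                        end = cursor + mat_len - 1L)
    cursor <- cursor + mat_len + spacer
  }
  genome_len <- cursor + spacer

  gchars <- sample(DNA_BASES, genome_len, replace = TRUE)

  # canonical splice motifs on every genomic intron (strand-corrected)
  for (g in genes) {
    ne <- length(g$starts)
    if (ne < 2) next
    for (i in seq_len(ne - 1L)) {
      is <- g$ends[i] + 1L; ie <- g$starts[i + 1L] - 1L
      if (g$strand == "+") {
        gchars[is:(is + 1L)] <- c("G", "T"); gchars[(ie - 1L):ie] <- c("A", "G")
      } else {
        gchars[is:(is + 1L)] <- c("C", "T"); gchars[(ie - 1L):ie] <- c("A", "C")
      }
    }
  }

  splice <- function(g, chain) {
    pieces <- vapply(chain, function(i)
      paste0(gchars[g$starts[i]:g$ends[i]], collapse = ""), character(1))
    s <- paste0(pieces, collapse = "")
    if (g$strand == "-") revcomp(s) else s
  }

  # pseudogene sequences: parent mature + exactly `divergence` substitutions
  pg_pairs <- data.frame(pseudogene_id = character(0), parent_id = character(0),
                         divergence = integer(0))
  for (k in seq_along(pseudo)) {
    pg <- pseudo[[k]]
    par <- genes[[parents[k]]]
    mature <- splice(par, par$chains[[1]])
    if (nchar(mature) < pseudogene_divergence)
      stop("parent mature sequence shorter than requested divergence")
    ch <- strsplit(mature, "")[[1]]
    at <- sample(length(ch), pseudogene_divergence)
    shift <- sample.int(3L, pseudogene_divergence, replace = TRUE)
    ch[at] <- DNA_BASES[((match(ch[at], DNA_BASES) - 1L + shift) %% 4L) + 1L]
    gchars[pg$start:pg$end] <- ch
    pg_pairs <- rbind(pg_pairs, data.frame(
      pseudogene_id = pg$gene_id, parent_id = pg$parent_id,
      divergence = as.integer(pseudogene_divergence)))
  }

  # assemble annotation rows + sequences
  rows <- list(); seqs <- character(0); info <- list()
  add_row <- function(type, start, end, strand, gene_id, tx_id = NA,
                      exon_number = NA, gene_biotype, tx_biotype = NA) {
    GenomicRanges::GRanges(contig, IRanges::IRanges(start, end),
      strand = strand, type = type, gene_id = gene_id,
      transcript_id = tx_id, exon_number = exon_number,
      gene_biotype = gene_biotype, transcript_biotype = tx_biotype,
      phase = if (type == "CDS") 0L else NA_integer_)
  }
  for (g in genes) {
    rows[[length(rows) + 1L]] <- add_row("gene", min(g$starts), max(g$ends),
      g$strand, g$gene_id, gene_biotype = "protein_coding")
    for (j in seq_along(g$chains)) {
      chain <- g$chains[[j]]
      tx_id <- sprintf("%s.t%d", g$gene_id, j)
      biotype <- if (j == 1L || runif(1) >= nmd_fraction) "protein_coding"
                 else "nonsense_mediated_decay"
      tstart <- g$starts[chain[1]]; tend <- g$ends[chain[length(chain)]]
      rows[[length(rows) + 1L]] <- add_row("transcript", tstart, tend,
        g$strand, g$gene_id, tx_id, gene_biotype = "protein_coding",
        tx_biotype = biotype)
      exord <- if (g$strand == "-") rev(chain) else chain
      for (i in seq_along(exord)) {
        e <- exord[i]
        rows[[length(rows) + 1L]] <- add_row("exon", g$starts[e], g$ends[e],
          g$strand, g$gene_id, tx_id, i, "protein_coding", biotype)
        if (biotype == "protein_coding")
          rows[[length(rows) + 1L]] <- add_row("CDS", g$starts[e], g$ends[e],
            g$strand, g$gene_id, tx_id, i, "protein_coding", biotype)
      }
      seqs[tx_id] <- splice(g, chain)
      info[[tx_id]] <- data.frame(
        transcript_id = tx_id, gene_id = g$gene_id, biotype = biotype,
        cds_key = if (biotype == "protein_coding")
          paste0(contig, g$strand, paste(g$starts[chain], g$ends[chain],
                                         sep = "-", collapse = ";"))
          else NA_character_)
    }
  }
  for (pg in pseudo) {
    tx_id <- paste0(pg$gene_id, ".t1")
    rows[[length(rows) + 1L]] <- add_row("gene", pg$start, pg$end, "+",
      pg$gene_id, gene_biotype = "processed_pseudogene")
    rows[[length(rows) + 1L]] <- add_row("transcript", pg$start, pg$end, "+",
      pg$gene_id, tx_id, gene_biotype = "processed_pseudogene",
      tx_biotype = "processed_pseudogene")
    rows[[length(rows) + 1L]] <- add_row("exon", pg$start, pg$end, "+",
      pg$gene_id, tx_id, 1, "processed_pseudogene", "processed_pseudogene")
    seqs[tx_id] <- paste0(gchars[pg$start:pg$end], collapse = "")
    info[[tx_id]] <- data.frame(
      transcript_id = tx_id, gene_id = pg$gene_id,
      biotype = "processed_pseudogene", cds_key = NA_character_)
  }

  annotation <- suppressWarnings(do.call(c, rows))
  genome <- Biostrings::DNAStringSet(setNames(paste0(gchars, collapse = ""),
                                              contig))
  list(annotation = annotation,
       genome = genome,
       transcripts = Biostrings::DNAStringSet(seqs),
       transcript_info = do.call(rbind, c(info, make.row.names = FALSE)),
       pseudogene_pairs = pg_pairs)
}

#' Write a generated transcriptome to disk
#'
#' Writes `annotation.gtf` (1-based inclusive, `gene_id`/`transcript_id`/
#' `gene_biotype` attributes), `genome.fa` and `transcripts.fa`.
#'
#' @param txome Result of [generate_transcriptome()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_transcriptome <- function(txome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rtracklayer::export(txome$annotation, file.path(dir, "annotation.gtf"),
                      format = "gtf")
  Biostrings::writeXStringSet(txome$genome, file.path(dir, "genome.fa"))
  Biostrings::writeXStringSet(txome$transcripts,
                              file.path(dir, "transcripts.fa"))
  invisible(dir)
}

#' Spike-in panel with known concentrations
#'
#' Synthetic analogue of an ERCC-style panel: `n` molecules with
#' concentrations log-uniform across `concentration_range` (relative
#' molarity) and random sequences of the given length range.
#'
#' @param n Number of spike-in species.
#' @param concentration_range `c(min, max)` relative molarity; the ratio is
#'   the panel's dynamic range.
#' @param length_range Sequence length range in bases.
#' @param seed Integer seed.
#' @return List with `panel` (data frame: spike_id, concentration, length)
#'   and `sequences` (DNAStringSet); `dynamic_range` attribute on the panel.
#' @export
spikein_panel <- function(n = 50, concentration_range = c(0.1, 1000),
                          length_range = c(300, 800), seed = NULL) {
  stopifnot(n >= 1, all(concentration_range > 0))
  if (!is.null(seed)) set.seed(seed)
  conc <- 10^runif(n, log10(concentration_range[1]),
                   log10(concentration_range[2]))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  ids <- sprintf("SPIKE%03d", seq_len(n))
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(lens, function(L) random_dna(1L, L), character(1)), ids))
  panel <- data.frame(spike_id = ids, concentration = conc, length = lens)
  attr(panel, "dynamic_range") <- max(conc) / min(conc)
  list(panel = panel, sequences = seqs)
}

#' Write / read a spike-in concentration table (TSV: spike_id, concentration)
#'
#' @param panel Data frame with `spike_id` and `concentration`.
#' @param path TSV path.
#' @export
write_spikeins <- function(panel, path) {
  write.table(panel[, c("spike_id", "concentration")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikeins
#' @export
read_spikeins <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("spike_id", "concentration") %in% names(df)),
            all(df$concentration > 0))
  df
}
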