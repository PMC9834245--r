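# Classification of transcript models against a reference annotation:
# FSM / ISM / NIC (CJ, CS, IR) / NNC / genic / antisense / fusion /
# intergenic, plus splice-junction canonicity auditing.

#' Transcript model
#'
#' An exon-chain transcript model. Exons are 1-based closed genomic
#' intervals, sorted and non-overlapping.
#'
#' @param model_id Model identifier.
#' @param contig Contig name.
#' @param strand "+" or "-".
#' @param starts,ends Integer vectors of exon starts/ends.
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(model_id, contig, strand, starts, ends) {
  stopifnot(length(starts) == length(ends), length(starts) >= 1L,
            all(ends >= starts), strand %in% c("+", "-"))
  o <- order(starts)
  starts <- as.integer(starts[o]); ends <- as.integer(ends[o])
  if (length(starts) > 1L && any(starts[-1L] <= ends[-length(ends)]))
    stop("exons must be non-overlapping and separated by introns")
  structure(list(model_id = model_id, contig = contig, strand = strand,
                 starts = starts, ends = ends),
            class = "transcript_model")
}

#' Extract the junction chain of a transcript model
#'
#' Junction i is the (donor, acceptor) pair formed by the end of exon i
#' and the start of exon i+1 (1-based exonic boundary coordinates; the
#' intron spans `donor+1 .. acceptor-1`). A single-exon model has an
#' empty chain.
#'
#' @param model A [transcript_model] (or list with `starts`/`ends`).
#' @return Data frame with `donor`, `acceptor`, strictly increasing.
#' @export
extract_junctions <- function(model) {
  k <- length(model$starts)
  if (k < 2L)
    return(data.frame(donor = integer(0), acceptor = integer(0)))
  data.frame(donor = model$ends[-k], acceptor = model$starts[-1L])
}

#' Index a reference annotation for classification
#'
#' Builds per-gene catalogs of transcripts, junction chains, donor and
#' acceptor sites from a GTF annotation (exon rows grouped by
#' transcript_id).
#'
#' @param annotation GRanges in GTF row layout, or a GTF file path.
#' @return Object of class `annotation_index`.
#' @export
annotation_index <- function(annotation) {
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gtf")
  ex <- annotation[annotation$type == "exon"]
  if (length(ex) == 0L) stop("annotation contains no exon rows")
  tx_ids <- ex$transcript_id
  exl <- split(data.frame(
    start = GenomicRanges::start(ex), end = GenomicRanges::end(ex),
    contig = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = ex$gene_id, stringsAsFactors = FALSE), tx_ids)
  tx <- do.call(rbind, lapply(names(exl), function(t) {
    e <- exl[[t]]
    data.frame(transcript_id = t, gene_id = e$gene_id[1],
               contig = e$contig[1], strand = e$strand[1],
               start = min(e$start), end = max(e$end),
               n_exons = nrow(e), stringsAsFactors = FALSE)
  }))
  chains <- lapply(exl, function(e) {
    o <- order(e$start)
    m <- transcript_model("x", e$contig[1], e$strand[1], e$start[o], e$end[o])
    j <- extract_junctions(m)
    cbind(donor = j$donor, acceptor = j$acceptor)
  })
  mono_exon <- lapply(exl, function(e)
    c(min(e$start), max(e$end)))
  genes <- do.call(rbind, lapply(split(tx, tx$gene_id), function(t)
    data.frame(gene_id = t$gene_id[1], contig = t$contig[1],
               strand = t$strand[1], start = min(t$start), end = max(t$end),
               stringsAsFactors = FALSE)))
  per_gene <- lapply(split(tx$transcript_id, tx$gene_id), identity)
  site_cat <- lapply(per_gene, function(ts) {
    ch <- do.call(rbind, chains[ts])
    if (is.null(ch) || nrow(ch) == 0L)
      return(list(donors = integer(0), acceptors = integer(0),
                  junctions = character(0)))
    list(donors = unique(ch[, 1]), acceptors = unique(ch[, 2]),
         junctions = unique(paste(ch[, 1], ch[, 2])))
  })
  structure(list(tx = tx, genes = genes, chains = chains,
                 tx_of_gene = per_gene, sites = site_cat,
                 mono_exon = mono_exon),
            class = "annotation_index")
}

# internal: is `sub` a contiguous sub-chain of `full`? (chains as matrices)
is_subchain <- function(sub, full) {
  ns <- nrow(sub); nf <- nrow(full)
  if (ns == 0L || ns > nf) return(FALSE)
  key_s <- paste(sub[, 1], sub[, 2], collapse = ";")
  for (off in 0:(nf - ns)) {
    key_f <- paste(full[off + seq_len(ns), 1], full[off + seq_len(ns), 2],
                   collapse = ";")
    if (key_s == key_f) return(TRUE)
  }
  FALSE
}

#' Classify a transcript model against the reference
#'
#' Categories: `FSM` (junction chain identical to a reference transcript
#' of the locus; single-exon models match single-exon references by
#' containment), `ISM` (non-empty chain equal to a contiguous sub-chain of
#' a reference transcript), `NIC` (all splice sites known at the locus but
#' the chain novel; subcategories CJ/CS/IR), `NNC` (at least one novel
#' donor or acceptor), `genic` (overlap inside a gene without chain
#' evidence), `antisense` (overlaps genes on the opposite strand only),
#' `fusion` (spans two or more non-overlapping reference genes), and
#' `intergenic`.
#'
#' @param model A [transcript_model].
#' @param index An [annotation_index].
#' @return One-row data frame: `model_id`, `category`, `nic_subcategory`,
#'   `matched_reference_transcript`, `associated_gene`.
#' @export
classify_transcript <- function(model, index) {
  res <- function(category, sub = "none", match = NA_character_,
                  gene = NA_character_)
    data.frame(model_id = model$model_id, category = category,
               nic_subcategory = sub, matched_reference_transcript = match,
               associated_gene = gene, stringsAsFactors = FALSE)
  g <- index$genes
  span_s <- min(model$starts); span_e <- max(model$ends)
  ov <- g$contig == model$contig & g$start <= span_e & g$end >= span_s
  if (!any(ov)) return(res("intergenic"))
  same <- ov & g$strand == model$strand
  if (!any(same)) return(res("antisense"))
  gs <- g[same, , drop = FALSE]
  if (nrow(gs) > 1L) {
    # non-overlapping loci bridged by one model -> fusion
    disjoint <- any(outer(gs$start, gs$end, ">") |
                      outer(gs$end, gs$start, "<"))
    if (disjoint)
      return(res("fusion", gene = paste(gs$gene_id, collapse = ",")))
  }
  # associate with the gene of maximal overlap
  ovw <- pmin(gs$end, span_e) - pmax(gs$start, span_s) + 1
  gene <- gs$gene_id[which.max(ovw)]
  txs <- index$tx_of_gene[[gene]]
  cat <- index$sites[[gene]]
  jc <- extract_junctions(model)
  mch <- cbind(donor = jc$donor, acceptor = jc$acceptor)

  if (nrow(mch) == 0L) {
    # mono-exon: retained intron > FSM-by-containment > genic
    spans_intron <- any(vapply(txs, function(t) {
      ch <- index$chains[[t]]
      nrow(ch) > 0L && any(span_s <= ch[, 1] & span_e >= ch[, 2])
    }, logical(1)))
    if (spans_intron) return(res("NIC", "IR", gene = gene))
    for (t in txs) {
      if (nrow(index$chains[[t]]) == 0L) {
        me <- index$mono_exon[[t]]
        if (span_s >= me[1] && span_e <= me[2])
          return(res("FSM", match = t, gene = gene))
      }
    }
    return(res("genic", gene = gene))
  }

  key <- paste(mch[, 1], mch[, 2], collapse = ";")
  for (t in txs) {
    ch <- index$chains[[t]]
    if (nrow(ch) == nrow(mch) &&
        key == paste(ch[, 1], ch[, 2], collapse = ";"))
      return(res("FSM", match = t, gene = gene))
  }
  for (t in txs) {
    if (is_subchain(mch, index$chains[[t]]))
      return(res("ISM", match = t, gene = gene))
  }
  novel_site <- !all(mch[, 1] %in% cat$donors) ||
    !all(mch[, 2] %in% cat$acceptors)
  if (novel_site) return(res("NNC", gene = gene))
  res("NIC", nic_subcategory_internal(model, mch, txs, index, cat),
      gene = gene)
}

# internal: NIC subtype given a model already known to be NIC
nic_subcategory_internal <- function(model, mch, txs, index, cat) {
  # IR: a model exon fully spans a reference intron
  for (t in txs) {
    ch <- index$chains[[t]]
    if (nrow(ch) == 0L) next
    for (i in seq_len(nrow(ch)))
      if (any(model$starts <= ch[i, 1] & model$ends >= ch[i, 2]))
        return("IR")
  }
  all_junctions_known <- all(paste(mch[, 1], mch[, 2]) %in% cat$junctions)
  if (all_junctions_known) "CJ" else "CS"
}

#' NIC subcategory of a model
#'
#' `CJ`: every junction (donor-acceptor pair) is annotated but the chain
#' is novel; `CS`: some junction pairs are novel while every individual
#' donor and acceptor is annotated; `IR`: a model exon fully spans a
#' reference intron. Calling this on a model that does not classify as
#' NIC is a contract error.
#'
#' @param model A [transcript_model].
#' @param index An [annotation_index].
#' @return "CJ", "CS" or "IR".
#' @export
nic_subcategory <- function(model, index) {
  cl <- classify_transcript(model, index)
  if (cl$category != "NIC")
    stop(sprintf("nic_subcategory called on a %s model", cl$category))
  cl$nic_subcategory
}

#' Classify many transcript models
#'
#' @param models List of [transcript_model] objects, or a GTF path /
#'   GRanges of models (exon rows grouped by transcript_id).
#' @param index An [annotation_index].
#' @return Data frame, one row per model.
#' @export
classify_transcripts <- function(models, index) {
  if (!is.list(models) || inherits(models, "GRanges") ||
      is.character(models))
    models <- read_transcript_models(models)
  out <- do.call(rbind, lapply(models, classify_transcript, index = index))
  rownames(out) <- NULL
  out
}

#' Read transcript models from GTF
#'
#' @param x GTF path or GRanges with exon rows carrying `transcript_id`.
#' @return Named list of [transcript_model] objects.
#' @export
read_transcript_models <- function(x) {
  if (is.character(x)) x <- rtracklayer::import(x, format = "gtf")
  ex <- x[x$type == "exon"]
  lapply(split(seq_along(ex), ex$transcript_id), function(i) {
    e <- ex[i]
    transcript_model(e$transcript_id[1],
                     as.character(GenomicRanges::seqnames(e))[1],
                     as.character(GenomicRanges::strand(e))[1],
                     GenomicRanges::start(e), GenomicRanges::end(e))
  })
}

#' Audit splice-junction canonicity
#'
#' Extracts the intron-terminal dinucleotides of every junction from the
#' genome and labels a junction canonical when the strand-corrected motif
#' is GT..AG, GC..AG or AT..AC.
#'
#' @param junctions Data frame with `contig`, `strand`, `donor`,
#'   `acceptor` (exonic boundary coordinates as in
#'   [extract_junctions()]).
#' @param genome Named DNAStringSet (or FASTA path).
#' @return List with `junctions` (input plus `motif`, `canonical`,
#'   `valid`) and `canonical_fraction` over valid junctions.
#' @export
junction_canonicity <- function(junctions, genome) {
  if (is.character(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  gl <- setNames(Biostrings::width(genome), names(genome))
  is_s <- junctions$donor + 1L
  is_e <- junctions$acceptor - 1L
  valid <- junctions$contig %in% names(genome) &
    is_e > is_s + 2L & is_s >= 1L &
    is_e <= gl[match(junctions$contig, names(genome))]
  motif <- rep(NA_character_, nrow(junctions))
  idx <- which(valid)
  if (length(idx)) {
    left <- as.character(Biostrings::subseq(
      genome[junctions$contig[idx]], start = is_s[idx],
      end = is_s[idx] + 1L))
    right <- as.character(Biostrings::subseq(
      genome[junctions$contig[idx]], start = is_e[idx] - 1L,
      end = is_e[idx]))
    plus <- junctions$strand[idx] == "+"
    motif[idx] <- ifelse(plus, paste0(left, "..", right),
                         paste0(revcomp(right), "..", revcomp(left)))
  }
  canonical <- motif %in% c("GT..AG", "GC..AG", "AT..AC")
  canonical[!valid] <- NA
  out <- cbind(junctions, motif = motif, canonical = canonical,
               valid = valid)
  list(junctions = out,
       canonical_fraction = mean(canonical[valid]))
}

#' Write classification results and a junction BED
#'
#' The BED uses 0-based half-open intron intervals.
#'
#' @param classification Data frame from [classify_transcripts()].
#' @param junctions Junction data frame (`contig`, `donor`, `acceptor`,
#'   `strand`).
#' @param dir Output directory.
#' @export
write_classification <- function(classification, junctions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(classification, file.path(dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- data.frame(junctions$contig, junctions$donor,
                    junctions$acceptor - 1L,
                    sprintf("junction%d", seq_len(nrow(junctions))), 0,
                    junctions$strand)
  write.table(bed, file.path(dir, "junctions.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
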