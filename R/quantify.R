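# Feature assignment, UMI deduplication, count matrices, and the
# accuracy/sensitivity metrics (spike-in correlation, UMI set matching,
# saturation).

#' Join demultiplexed reads to their source features (truth mode)
#'
#' On simulated data the read-to-feature assignment is taken from the
#' simulator's truth table (alignment is delegated to an external aligner
#' on real data; see [assign_reads_bam()]).
#'
#' @param assignments `assignments` data frame from [demultiplex()].
#' @param truth Truth table from [simulate_reads()].
#' @return Data frame of assigned reads with `read_id`, `cell_id`, `umi`,
#'   `feature_id`, `gene_id`, `is_spikein`.
#' @export
assign_reads_truth <- function(assignments, truth) {
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  m <- match(a$read_id, truth$read_id)
  if (anyNA(m)) stop("assignments contain read ids absent from the truth table")
  data.frame(read_id = a$read_id, cell_id = a$cell_id, umi = a$umi,
             feature_id = truth$source_feature_id[m],
             gene_id = truth$gene_id[m],
             is_spikein = truth$is_spikein[m], stringsAsFactors = FALSE)
}

#' Assign aligned reads to genes from a BAM file
#'
#' Reads alignments carrying `CB` (cell) and `UB` (UMI) tags and assigns
#' each read to a gene by locus overlap: the gene whose annotated range
#' overlaps the alignment most (same strand not required, long-read cDNA
#' orientation being library-dependent). Reads overlapping no gene are
#' unassigned; reads tied between genes are flagged ambiguous. Transcript-
#' level assignment requires the read's junction chain (from N CIGAR
#' operations) to be a sub-chain of the transcript's.
#'
#' @param bam Path to a coordinate-sorted BAM with CB/UB tags.
#' @param annotation GTF annotation as GRanges (or a GTF path).
#' @param level "gene" or "transcript".
#' @return Data frame with `read_id`, `cell_id`, `umi`, `feature_id`,
#'   `gene_id`, `status` (assigned/ambiguous/unassigned).
#' @export
assign_reads_bam <- function(bam, annotation, level = c("gene", "transcript")) {
  level <- match.arg(level)
  if (!requireNamespace("Rsamtools", quietly = TRUE) ||
      !requireNamespace("GenomicAlignments", quietly = TRUE))
    stop("BAM input requires Rsamtools and GenomicAlignments")
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gtf")
  param <- Rsamtools::ScanBamParam(tag = c("CB", "UB", "NM"),
                                   what = c("qname"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param,
                                            use.names = FALSE)
  md <- S4Vectors::mcols(aln)
  genes <- annotation[annotation$type == "gene"]
  rng <- GenomicRanges::granges(aln)
  hits <- GenomicRanges::findOverlaps(rng, genes, ignore.strand = TRUE)
  ovw <- GenomicRanges::width(IRanges::pintersect(
    rng[S4Vectors::queryHits(hits)], genes[S4Vectors::subjectHits(hits)],
    ignore.strand = TRUE))
  best <- tapply(seq_along(ovw), S4Vectors::queryHits(hits), function(i) {
    w <- ovw[i]
    top <- i[w == max(w)]
    if (length(top) > 1L) NA_integer_ else top
  })
  out <- data.frame(read_id = md$qname,
                    cell_id = md$CB %||% NA_character_,
                    umi = md$UB %||% NA_character_,
                    feature_id = NA_character_, gene_id = NA_character_,
                    status = "unassigned", stringsAsFactors = FALSE)
  q <- as.integer(names(best))
  amb <- is.na(best)
  out$status[q[amb]] <- "ambiguous"
  ok <- q[!amb]
  gid <- genes$gene_id[S4Vectors::subjectHits(hits)[unlist(best[!amb])]]
  out$gene_id[ok] <- gid
  out$status[ok] <- "assigned"
  if (level == "gene") {
    out$feature_id[ok] <- gid
    return(out)
  }
  # transcript level: read junction chain must be a sub-chain of the
  # transcript's junction chain and the read must lie within its span
  idx <- annotation_index(annotation)
  jl <- GenomicAlignments::junctions(aln)
  for (k in ok) {
    g <- out$gene_id[k]
    txs <- idx$tx$transcript_id[idx$tx$gene_id == g]
    rj <- jl[[k]]
    rch <- if (length(rj)) cbind(GenomicRanges::start(rj) - 1L,
                                 GenomicRanges::end(rj) + 1L) else
      matrix(integer(0), ncol = 2)
    compat <- vapply(txs, function(tx) {
      ch <- idx$chains[[tx]]
      if (nrow(rch) == 0L) return(TRUE)
      if (nrow(ch) == 0L) return(FALSE)
      key <- paste(ch[, 1], ch[, 2])
      all(paste(rch[, 1], rch[, 2]) %in% key)
    }, logical(1))
    if (sum(compat) == 1L) out$feature_id[k] <- txs[compat]
    else if (sum(compat) > 1L) {
      # prefer fewest mismatches is moot across identical-compat models;
      # pick the transcript with the fewest junctions beyond the read's
      extra <- vapply(txs[compat], function(tx)
        nrow(idx$chains[[tx]]) - nrow(rch), numeric(1))
      out$feature_id[k] <- txs[compat][which.min(extra)]
    } else out$status[k] <- "ambiguous"
  }
  out
}

#' Deduplicate UMIs for one cell x feature by directional clustering
#'
#' Builds the directed graph u -> v for pairs within `max_dist` edits where
#' `count(u) >= 2 * count(v) - 1`, then grows clusters from local count
#' maxima by directed reachability (the count-aware "directional" scheme
#' that avoids chaining distinct molecules at long-read error rates).
#' Each cluster is one molecule; its representative is the highest-count
#' UMI.
#'
#' @param umis Character vector of UMI sequences (one per read), or a
#'   named integer vector of per-UMI read counts.
#' @param max_dist Maximum edit distance connecting two UMIs.
#' @return Data frame with one row per molecule: `representative`,
#'   `n_umis`, `reads` (summed read count).
#' @export
dedup_umis <- function(umis, max_dist = 1L) {
  if (length(umis) == 0L)
    return(data.frame(representative = character(0), n_umis = integer(0),
                      reads = integer(0), stringsAsFactors = FALSE))
  counts <- if (is.numeric(umis)) {
    stopifnot(!is.null(names(umis)))
    umis
  } else table(umis) |> c()
  counts <- sort(counts, decreasing = TRUE)
  # deterministic tie-break: count desc, then lexicographic
  counts <- counts[order(-counts, names(counts))]
  seqs <- names(counts)
  k <- length(seqs)
  if (k == 1L)
    return(data.frame(representative = seqs, n_umis = 1L,
                      reads = as.integer(counts), stringsAsFactors = FALSE))
  d <- edit_distance(seqs)
  assigned <- integer(k)  # cluster id per umi, 0 = unassigned
  ncl <- 0L
  for (i in seq_len(k)) {
    if (assigned[i]) next
    ncl <- ncl + 1L
    queue <- i
    assigned[i] <- ncl
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(assigned == 0L & d[u, ] <= max_dist &
                    counts[u] >= 2L * counts - 1L)
      assigned[nb] <- ncl
      queue <- c(queue, nb)
    }
  }
  reps <- vapply(seq_len(ncl), function(cl) seqs[which(assigned == cl)[1L]],
                 character(1))
  data.frame(
    representative = reps,
    n_umis = as.integer(tabulate(assigned, ncl)),
    reads = as.integer(vapply(seq_len(ncl), function(cl)
      sum(counts[assigned == cl]), numeric(1))),
    stringsAsFactors = FALSE)
}

#' Collapse assigned reads into molecules
#'
#' Runs [dedup_umis()] within every cell x feature group.
#'
#' @param reads Data frame with `cell_id`, `feature_id`, `umi` (one row per
#'   read), e.g. from [assign_reads_truth()].
#' @param max_dist UMI clustering distance.
#' @return Data frame of molecular records: `cell_id`, `feature_id`,
#'   `umi_representative`, `read_count`.
#' @export
count_molecules <- function(reads, max_dist = 1L) {
  stopifnot(all(c("cell_id", "feature_id", "umi") %in% names(reads)))
  if (nrow(reads) == 0L)
    return(data.frame(cell_id = character(0), feature_id = character(0),
                      umi_representative = character(0),
                      read_count = integer(0), stringsAsFactors = FALSE))
  key <- paste(reads$cell_id, reads$feature_id, sep = "\r")
  grp <- split(reads$umi, key)
  res <- lapply(names(grp), function(g) {
    cl <- dedup_umis(grp[[g]], max_dist = max_dist)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    data.frame(cell_id = parts[1], feature_id = parts[2],
               umi_representative = cl$representative,
               read_count = cl$reads, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build a sparse UMI count matrix from molecular records
#'
#' @param records Molecular records from [count_molecules()].
#' @param kind Feature kind label ("gene", "transcript" or "spikein").
#' @param cells Optional cell universe (columns); defaults to cells seen.
#' @param features Optional feature universe (rows).
#' @return A `dgCMatrix` (features x cells) with a `feature_kind` attribute.
#' @export
build_count_matrix <- function(records, kind = "gene", cells = NULL,
                               features = NULL) {
  key <- paste(records$cell_id, records$feature_id,
               records$umi_representative)
  if (anyDuplicated(key))
    stop("duplicate (cell, feature, representative) molecular records; deduplication contract violated")
  features <- features %||% sort(unique(records$feature_id))
  cells <- cells %||% sort(unique(records$cell_id))
  i <- match(records$feature_id, features)
  j <- match(records$cell_id, cells)
  if (anyNA(i) || anyNA(j))
    stop("records contain features/cells outside the declared universe")
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(features), length(cells)),
                            dimnames = list(features, cells))
  m <- methods::as(m, "CsparseMatrix")
  attr(m, "feature_kind") <- kind
  m
}

#' Write a count matrix as MatrixMarket triple
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#'
#' @param mat Sparse matrix from [build_count_matrix()].
#' @param dir Output directory.
#' @export
write_count_matrix <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # force a general (non-symmetric) representation: writeMM otherwise
  # stores coincidentally symmetric matrices in symmetric format
  Matrix::writeMM(methods::as(mat, "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(mat), file.path(dir, "features.tsv"))
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket count matrix with feature/barcode sidecars
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @return A sparse matrix with dimnames.
#' @export
read_count_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                   "generalMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "features.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  methods::as(m, "CsparseMatrix")
}

#' Spike-in concentration vs UMI count correlation
#'
#' Pearson correlation between spike-in concentration and the mean
#' deduplicated UMI count per cell, the standard accuracy readout for an
#' ERCC-style panel. By default both axes are log10-transformed and
#' spike-ins with zero mean count are excluded (not pseudocounted).
#'
#' @param mat Count matrix restricted to spike-in features (rows).
#' @param panel Spike-in table with `spike_id` and `concentration`.
#' @param transform "log10" or "linear".
#' @return List with `r`, `n_used`, `transform`.
#' @export
ercc_correlation <- function(mat, panel, transform = c("log10", "linear")) {
  transform <- match.arg(transform)
  common <- intersect(rownames(mat), panel$spike_id)
  mean_counts <- setNames(rep(0, nrow(panel)), panel$spike_id)
  if (length(common))
    mean_counts[common] <- Matrix::rowMeans(mat[common, , drop = FALSE])
  conc <- panel$concentration
  use <- mean_counts > 0
  if (sum(use) < 3L)
    stop("need at least 3 spike-ins with nonzero mean count")
  x <- conc[use]; y <- mean_counts[use]
  if (transform == "log10") { x <- log10(x); y <- log10(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance across usable spike-ins; correlation undefined")
  list(r = cor(x, y, method = "pearson"), n_used = sum(use),
       transform = transform)
}

#' Match one UMI multiset against another at bounded edit distance
#'
#' Greedy one-to-one matching: UMIs of set A, visited by descending count
#' then lexicographic order, are matched to the nearest unmatched UMI of
#' set B within `max_dist` edits. Returns the matched fraction of A —
#' the statistic used to compare the platform's UMI calls with matched
#' short-read UMIs of the same library.
#'
#' @param set_a,set_b Character vectors (multisets) of UMIs.
#' @param max_dist Maximum edit distance for a match.
#' @return Fraction of distinct A UMIs matched (weighted by multiset
#'   counts).
#' @export
match_umi_sets <- function(set_a, set_b, max_dist = 1L) {
  if (length(set_a) == 0L) return(NaN)
  ca <- c(table(set_a)); cb <- c(table(set_b))
  ca <- ca[order(-ca, names(ca))]
  if (length(cb) == 0L) return(0)
  d <- edit_distance(names(ca), names(cb))
  avail <- rep(TRUE, length(cb))
  matched <- 0
  for (i in seq_along(ca)) {
    cand <- which(avail & d[i, ] <= max_dist)
    if (length(cand)) {
      pick <- cand[which.min(d[i, cand])]
      avail[pick] <- FALSE
      matched <- matched + ca[i]
    }
  }
  unname(matched / sum(ca))
}

#' Detection saturation by read subsampling
#'
#' Subsamples each cell's reads without replacement at a grid of per-cell
#' depths, re-runs UMI deduplication and counting, and reports the median
#' number of genes and transcripts detected per cell. Detection plateaus
#' once additional reads mostly hit already-seen molecules.
#'
#' @param reads Assigned reads (`cell_id`, `feature_id`, `gene_id`, `umi`).
#' @param depths Ascending vector of per-cell read depths.
#' @param max_dist UMI clustering distance.
#' @param seed Integer seed for subsampling.
#' @return Data frame: `depth`, `median_genes`, `median_transcripts`.
#' @export
saturation_curve <- function(reads, depths, max_dist = 1L, seed = NULL) {
  stopifnot(!is.unsorted(depths))
  if (!is.null(seed)) set.seed(seed)
  by_cell <- split(seq_len(nrow(reads)), reads$cell_id)
  max_avail <- max(vapply(by_cell, length, integer(1)))
  if (any(depths > max_avail))
    message("depths above the available reads per cell are capped")
  res <- lapply(depths, function(dp) {
    if (dp == 0)
      return(data.frame(depth = 0, median_genes = 0, median_transcripts = 0))
    idx <- unlist(lapply(by_cell, function(ix) {
      if (length(ix) <= dp) ix else sample(ix, dp)
    }), use.names = FALSE)
    sub <- reads[idx, , drop = FALSE]
    mol <- count_molecules(sub, max_dist = max_dist)
    gene_of <- reads$gene_id[match(mol$feature_id, reads$feature_id)]
    ng <- tapply(gene_of, mol$cell_id, function(x) length(unique(x)))
    nt <- tapply(mol$feature_id, mol$cell_id, function(x) length(unique(x)))
    data.frame(depth = dp, median_genes = median(as.vector(ng)),
               median_transcripts = median(as.vector(nt)))
  })
  do.call(rbind, res)
}
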