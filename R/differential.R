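# Differential expression (Wilcoxon rank-sum), differential transcript
# usage (chi-square homogeneity of isoform counts) and protein-consequence
# calling for significant DTU events.

#' Counts-per-10k normalization
#'
#' Scales each cell to 10,000 total counts; optionally log1p-transforms.
#'
#' @param mat Count matrix (features x cells).
#' @param log1p Apply log1p after scaling.
#' @return Dense or sparse matrix of normalized values.
#' @export
normalize_cp10k <- function(mat, log1p = FALSE) {
  tot <- Matrix::colSums(mat)
  tot[tot == 0] <- 1
  norm <- t(t(mat) / tot) * 1e4
  if (log1p) norm <- log1p(norm)
  norm
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-feature two-tailed Wilcoxon rank-sum test between two cell groups
#' on counts-per-10k log1p-normalized values (exact p-values for group
#' sizes up to 8 without ties, normal approximation with tie correction
#' otherwise), with BH correction across features. The log2 fold change
#' compares mean normalized expression with a pseudocount of 1.
#'
#' @param mat Count matrix (features x cells).
#' @param groups Factor/character vector over cells with exactly two
#'   levels; the first level is the "A" (numerator) group.
#' @param alpha BH-adjusted significance threshold.
#' @param lfc_threshold Minimum |log2 fold change| for significance.
#' @param normalize Apply counts-per-10k/log1p before testing.
#' @return Data frame: `feature_id`, `mean_a`, `mean_b`, `log2_fc`,
#'   `statistic`, `p_value`, `adjusted_p`, `significant`.
#' @export
wilcoxon_de <- function(mat, groups, alpha = 0.05, lfc_threshold = 0.25,
                        normalize = TRUE) {
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) != 2L) stop("groups must have exactly two levels")
  ia <- which(groups == lv[1]); ib <- which(groups == lv[2])
  if (length(ia) < 2L || length(ib) < 2L)
    stop("both groups need at least two cells")
  x <- as.matrix(mat)
  norm <- if (normalize) as.matrix(normalize_cp10k(mat)) else x
  test_in <- if (normalize) log1p(norm) else norm
  exact <- length(ia) <= 8L && length(ib) <= 8L
  res <- t(vapply(seq_len(nrow(x)), function(i) {
    wt <- suppressWarnings(wilcox.test(test_in[i, ia], test_in[i, ib],
                                       exact = exact, correct = !exact))
    c(stat = unname(wt$statistic), p = wt$p.value)
  }, numeric(2)))
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  lfc <- log2((mean_a + 1) / (mean_b + 1))
  padj <- p.adjust(res[, "p"], method = "BH")
  data.frame(
    feature_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    mean_a = mean_a, mean_b = mean_b, log2_fc = lfc,
    statistic = res[, "stat"], p_value = res[, "p"], adjusted_p = padj,
    significant = padj < alpha & abs(lfc) >= lfc_threshold,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential transcript usage between two cell groups
#'
#' For each gene with at least two expressed isoforms, tests homogeneity
#' of the isoform x group table of aggregated UMI counts with a
#' chi-square test (Fisher's exact test when the table is 2x2 and any
#' expected cell is below 5), reports per-group isoform usage
#' proportions, and BH-corrects across genes. Single-isoform genes are
#' excluded with a reason.
#'
#' @param tx_mat Transcript-level count matrix (transcripts x cells).
#' @param tx2gene Data frame with `transcript_id`, `gene_id`.
#' @param groups Two-level factor over cells.
#' @param alpha BH-adjusted significance threshold.
#' @return List with `events` (per-gene data frame: statistic, p_value,
#'   adjusted_p, significant), `proportions` (per gene x isoform x group),
#'   and `excluded` (gene_id, reason).
#' @export
dtu_test <- function(tx_mat, tx2gene, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) != 2L) stop("groups must have exactly two levels")
  x <- as.matrix(tx_mat)
  agg <- cbind(A = rowSums(x[, groups == lv[1], drop = FALSE]),
               B = rowSums(x[, groups == lv[2], drop = FALSE]))
  gene_of <- tx2gene$gene_id[match(rownames(x), tx2gene$transcript_id)]
  events <- list(); props <- list(); excluded <- list()
  for (g in unique(gene_of[!is.na(gene_of)])) {
    rows <- which(gene_of == g)
    tab <- agg[rows, , drop = FALSE]
    keep <- rowSums(tab) > 0
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) < 2L) {
      excluded[[g]] <- data.frame(gene_id = g,
                                  reason = "fewer_than_two_expressed_isoforms")
      next
    }
    use_fisher <- FALSE
    if (nrow(tab) == 2L) {
      exp_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      use_fisher <- any(exp_cells < 5)
    }
    if (use_fisher) {
      ft <- fisher.test(tab)
      stat <- NA_real_; p <- ft$p.value; test <- "fisher"
    } else if (any(colSums(tab) == 0)) {
      stat <- 0; p <- 1; test <- "chisq"  # one group silent: no usage evidence
    } else {
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      stat <- unname(ct$statistic); p <- ct$p.value; test <- "chisq"
    }
    events[[g]] <- data.frame(gene_id = g, statistic = stat, p_value = p,
                              test = test, stringsAsFactors = FALSE)
    pr <- sweep(tab, 2, pmax(colSums(tab), 1), "/")
    props[[g]] <- data.frame(gene_id = g,
                             transcript_id = rownames(x)[rows][keep],
                             usage_a = pr[, "A"], usage_b = pr[, "B"],
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, events)
  if (!is.null(ev)) {
    rownames(ev) <- NULL
    ev$adjusted_p <- p.adjust(ev$p_value, method = "BH")
    ev$significant <- ev$adjusted_p < alpha
  }
  list(events = ev,
       proportions = do.call(rbind, c(props, make.row.names = FALSE)),
       excluded = do.call(rbind, c(excluded, make.row.names = FALSE)))
}

#' Protein consequence of a significant DTU event
#'
#' Compares the dominant isoform (argmax usage) per group:
#' `coding_potential_change` when the dominant isoforms differ in coding
#' status (protein_coding vs a non-coding biotype such as
#' nonsense_mediated_decay — the switch that silences protein output
#' while total gene expression is unchanged), `protein_alteration` when
#' both are coding but their CDS identity keys differ, `none` otherwise.
#' Missing biotype annotation yields `undetermined`.
#'
#' @param proportions Per-isoform usage for one gene (`transcript_id`,
#'   `usage_a`, `usage_b`), as returned by [dtu_test()].
#' @param tx_annotation Data frame with `transcript_id`, `biotype`, and
#'   `cds_key` (identity key of the annotated CDS exon chain).
#' @return One of "coding_potential_change", "protein_alteration",
#'   "none", "undetermined".
#' @export
dtu_consequence <- function(proportions, tx_annotation) {
  dom_a <- proportions$transcript_id[which.max(proportions$usage_a)]
  dom_b <- proportions$transcript_id[which.max(proportions$usage_b)]
  if (dom_a == dom_b) return("none")
  m <- match(c(dom_a, dom_b), tx_annotation$transcript_id)
  if (anyNA(m)) return("undetermined")
  bio <- tx_annotation$biotype[m]
  if (anyNA(bio)) return("undetermined")
  coding <- bio == "protein_coding"
  if (xor(coding[1], coding[2])) return("coding_potential_change")
  if (all(coding)) {
    keys <- tx_annotation$cds_key[m]
    if (anyNA(keys)) return("undetermined")
    if (keys[1] != keys[2]) return("protein_alteration")
  }
  "none"
}

#' Annotate significant DTU events with protein consequences
#'
#' @param dtu Result of [dtu_test()].
#' @param tx_annotation See [dtu_consequence()].
#' @return The `events` data frame with a `consequence` column
#'   (NA for non-significant events).
#' @export
dtu_consequences <- function(dtu, tx_annotation) {
  ev <- dtu$events
  ev$consequence <- NA_character_
  for (i in which(ev$significant)) {
    pr <- dtu$proportions[dtu$proportions$gene_id == ev$gene_id[i], ,
                          drop = FALSE]
    ev$consequence[i] <- dtu_consequence(pr, tx_annotation)
  }
  ev
}

#' DEG / DTU overlap summary
#'
#' @param deg_genes,dtu_genes Character vectors of gene ids.
#' @return List with disjoint counts (`deg_only`, `dtu_only`, `both`) and
#'   the corresponding fractions of each input set.
#' @export
overlap_summary <- function(deg_genes, dtu_genes) {
  deg_genes <- unique(deg_genes); dtu_genes <- unique(dtu_genes)
  both <- intersect(deg_genes, dtu_genes)
  list(deg_only = length(setdiff(deg_genes, both)),
       dtu_only = length(setdiff(dtu_genes, both)),
       both = length(both),
       frac_dtu_not_deg = if (length(dtu_genes))
         length(setdiff(dtu_genes, both)) / length(dtu_genes) else NaN,
       frac_deg_not_dtu = if (length(deg_genes))
         length(setdiff(deg_genes, both)) / length(deg_genes) else NaN)
}
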