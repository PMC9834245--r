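# Quality-control analyses: dual-species contamination calling,
# pseudogene/parent read disambiguation and co-expression.

#' Species assignment from a dual-species (barnyard) alignment
#'
#' For each cell, reads are counted against a combined two-genome
#' reference so every read has one best species. A cell is labeled with
#' the majority species when the majority fraction is at least
#' `purity_threshold` (inclusive), `contaminated` when coverage is
#' adequate but purity is below threshold, and `low_coverage` when fewer
#' than `min_reads` reads are available.
#'
#' @param counts Data frame with `cell_id`, `reads_a`, `reads_b`.
#' @param purity_threshold Minimum majority fraction (default 0.9).
#' @param min_reads Minimum reads for a confident call (default 100).
#' @param species_names Labels for the two species.
#' @return Data frame with per-cell counts, `majority_fraction`, `label`.
#' @export
species_assignment <- function(counts, purity_threshold = 0.9,
                               min_reads = 100L,
                               species_names = c("species_a", "species_b")) {
  stopifnot(all(c("cell_id", "reads_a", "reads_b") %in% names(counts)),
            all(counts$reads_a >= 0), all(counts$reads_b >= 0))
  tot <- counts$reads_a + counts$reads_b
  maj <- ifelse(tot > 0, pmax(counts$reads_a, counts$reads_b) / tot, NA)
  label <- ifelse(tot < min_reads, "low_coverage",
           ifelse(maj >= purity_threshold,
                  ifelse(counts$reads_a >= counts$reads_b,
                         species_names[1], species_names[2]),
                  "contaminated"))
  data.frame(cell_id = counts$cell_id, reads_a = counts$reads_a,
             reads_b = counts$reads_b, majority_fraction = maj,
             label = label, stringsAsFactors = FALSE)
}

#' Resolve a read between a pseudogene and its parent gene
#'
#' Pseudogene/parent pairs can differ by only a few substitutions (e.g.
#' 2 bases over a 400-bp stretch), so a read is assigned to whichever
#' candidate it aligns to with strictly fewer mismatches; equal mismatch
#' counts are ambiguous. Vectorized over reads.
#'
#' @param parent_mismatches,pseudogene_mismatches Mismatch counts of each
#'   read's candidate alignments.
#' @return Character vector: "parent", "pseudogene" or "ambiguous".
#' @export
resolve_pseudogene_read <- function(parent_mismatches,
                                    pseudogene_mismatches) {
  stopifnot(length(parent_mismatches) == length(pseudogene_mismatches))
  ifelse(parent_mismatches < pseudogene_mismatches, "parent",
         ifelse(pseudogene_mismatches < parent_mismatches, "pseudogene",
                "ambiguous"))
}

#' Pseudogene-parent co-expression across cells
#'
#' For each pair expressed (count > 0) in at least `min_cells_expressed`
#' cells for both members, correlates pseudogene and parent counts across
#' cells (Spearman by default, to tame count skew) and classifies the
#' pair `positive` / `negative` when the BH-adjusted p-value is below
#' `alpha` with the matching sign, else `uncorrelated`.
#'
#' @param mat Gene-level count matrix (genes x cells).
#' @param pairs Data frame with `pseudogene_id`, `parent_id` (and
#'   optionally `divergence`).
#' @param min_cells_expressed Expression filter per member.
#' @param alpha BH-adjusted significance threshold.
#' @param method Correlation estimator ("spearman" or "pearson").
#' @return Data frame with `rho`, `p_value`, `adjusted_p`,
#'   `classification`, and `excluded_reason` for filtered pairs.
#' @export
pseudogene_parent_correlation <- function(mat, pairs,
                                          min_cells_expressed = 10L,
                                          alpha = 0.05,
                                          method = c("spearman", "pearson")) {
  method <- match.arg(method)
  out <- data.frame(pairs, rho = NA_real_, p_value = NA_real_,
                    adjusted_p = NA_real_, classification = "excluded",
                    excluded_reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pairs))) {
    pg <- pairs$pseudogene_id[i]; par <- pairs$parent_id[i]
    if (!(pg %in% rownames(mat)) || !(par %in% rownames(mat))) {
      out$excluded_reason[i] <- "member_absent_from_matrix"
      next
    }
    x <- as.numeric(mat[pg, ]); y <- as.numeric(mat[par, ])
    if (sum(x > 0) < min_cells_expressed ||
        sum(y > 0) < min_cells_expressed) {
      out$excluded_reason[i] <- "below_expression_filter"
      next
    }
    ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
    out$rho[i] <- unname(ct$estimate)
    out$p_value[i] <- ct$p.value
  }
  tested <- !is.na(out$p_value)
  out$adjusted_p[tested] <- p.adjust(out$p_value[tested], method = "BH")
  sig <- tested & out$adjusted_p < alpha
  out$classification[tested] <- "uncorrelated"
  out$classification[sig & out$rho > 0] <- "positive"
  out$classification[sig & out$rho < 0] <- "negative"
  out
}
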