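test_that("exact Wilcoxon p for complete separation at 5 vs 5 is 2/252", {
  mat <- matrix(c(11, 12, 13, 14, 15, 1, 2, 3, 4, 5), nrow = 1,
                dimnames = list("g1", paste0("c", 1:10)))
  groups <- rep(c("A", "B"), each = 5)
  res <- wilcoxon_de(mat, groups, normalize = FALSE)
  expect_equal(res$p_value, 2 / 252, tolerance = 1e-12)
  expect_gt(res$log2_fc, 0)
})

test_that("identical groups give p near 1 and label swaps negate the fold change", {
  mat <- matrix(c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5,
                  10, 1, 7, 2, 9, 1, 1, 1, 8, 2), nrow = 2, byrow = TRUE,
                dimnames = list(c("same", "diff"), paste0("c", 1:10)))
  groups <- rep(c("A", "B"), each = 5)
  res <- wilcoxon_de(mat, groups, normalize = FALSE)
  expect_gt(res$p_value[1], 0.99)
  flipped <- wilcoxon_de(mat, rep(c("B", "A"), each = 5), normalize = FALSE)
  # factor level order keeps A as numerator, so cells swap groups
  expect_equal(res$p_value, flipped$p_value, tolerance = 1e-12)
  expect_equal(res$log2_fc, -flipped$log2_fc, tolerance = 1e-12)
})

test_that("BH-adjusted p-values are monotone in p-value rank", {
  set.seed(141)
  mat <- matrix(rnbinom(100 * 20, mu = 5, size = 2), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:20)))
  res <- wilcoxon_de(mat, rep(c("A", "B"), each = 10))
  o <- order(res$p_value)
  expect_true(!is.unsorted(res$adjusted_p[o]))
  expect_true(all(res$adjusted_p >= res$p_value - 1e-12))
})

test_that("DTU homogeneity test hits its closed forms", {
  tx2gene <- data.frame(transcript_id = c("t1", "t2", "t3"),
                        gene_id = c("g1", "g1", "g2"))
  groups <- rep(c("A", "B"), each = 4)
  # equal usage in both groups -> statistic 0, p = 1
  eq <- matrix(c(rep(25, 8), rep(25, 8), rep(5, 8)), nrow = 3, byrow = TRUE,
               dimnames = list(c("t1", "t2", "t3"), paste0("c", 1:8)))
  req <- dtu_test(eq, tx2gene, groups)
  g1 <- req$events[req$events$gene_id == "g1", ]
  expect_equal(g1$statistic, 0, tolerance = 1e-12)
  expect_equal(g1$p_value, 1, tolerance = 1e-12)
  # single-isoform gene excluded
  expect_equal(req$excluded$gene_id, "g2")
  expect_match(req$excluded$reason, "fewer_than_two")

  # complete switch (100,0) vs (0,100): chi-square 200 at 1 df
  sw <- matrix(0, nrow = 3, ncol = 8,
               dimnames = dimnames(eq))
  sw["t1", 1:4] <- 25; sw["t2", 5:8] <- 25; sw["t3", ] <- 5
  rsw <- dtu_test(sw, tx2gene, groups)
  g1 <- rsw$events[rsw$events$gene_id == "g1", ]
  expect_equal(g1$statistic, 200, tolerance = 1e-9)
  expect_lt(g1$p_value, 1e-20)
  pr <- rsw$proportions[rsw$proportions$gene_id == "g1", ]
  expect_equal(pr$usage_a, c(1, 0))
  expect_equal(pr$usage_b, c(0, 1))

  # sparse 2x2 tables fall back to Fisher's exact test
  tiny <- matrix(0, nrow = 3, ncol = 8, dimnames = dimnames(eq))
  tiny["t1", 1:4] <- 1; tiny["t2", 5:8] <- 1; tiny["t3", ] <- 2
  rt <- dtu_test(tiny, tx2gene, groups)
  expect_equal(rt$events$test[rt$events$gene_id == "g1"], "fisher")
})

test_that("DTU consequences follow dominant-isoform switches", {
  anno <- data.frame(
    transcript_id = c("t1", "t2", "t3", "t4"),
    biotype = c("protein_coding", "nonsense_mediated_decay",
                "protein_coding", "protein_coding"),
    cds_key = c("cdsA", NA, "cdsB", "cdsA"))
  prop <- function(ids, ua, ub)
    data.frame(gene_id = "g", transcript_id = ids, usage_a = ua,
               usage_b = ub)
  # coding -> NMD dominant switch silences protein output
  expect_equal(dtu_consequence(prop(c("t1", "t2"), c(0.8, 0.2),
                                    c(0.1, 0.9)), anno),
               "coding_potential_change")
  # switch between two coding isoforms with different CDS
  expect_equal(dtu_consequence(prop(c("t1", "t3"), c(0.9, 0.1),
                                    c(0.2, 0.8)), anno),
               "protein_alteration")
  # same dominant isoform: no consequence
  expect_equal(dtu_consequence(prop(c("t1", "t2"), c(0.8, 0.2),
                                    c(0.6, 0.4)), anno), "none")
  # identical CDS keys despite the switch: no protein change
  expect_equal(dtu_consequence(prop(c("t1", "t4"), c(0.9, 0.1),
                                    c(0.2, 0.8)), anno), "none")
  # missing annotation is flagged, not guessed
  expect_equal(dtu_consequence(prop(c("t1", "tX"), c(0.9, 0.1),
                                    c(0.2, 0.8)), anno), "undetermined")
})

test_that("DEG/DTU overlap counts are disjoint and complete", {
  ov <- overlap_summary(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(ov$deg_only, 1)
  expect_equal(ov$dtu_only, 2)
  expect_equal(ov$both, 2)
  expect_equal(ov$frac_dtu_not_deg, 0.5)
  same <- overlap_summary(c("x", "y"), c("x", "y"))
  expect_equal(same$both, 2)
  expect_equal(same$deg_only + same$dtu_only, 0)
  expect_equal(overlap_summary(c("a"), c("b"))$both, 0)
})

test_that("planted isoform switches are detected with high power", {
  set.seed(151)
  n_genes <- 100; n_cells <- 100
  groups <- rep(c("A", "B"), each = n_cells / 2)
  rows <- list(); tx2gene <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("g%03d", g)
    # strong usage swap 0.8/0.2 -> 0.2/0.8 at moderate expression
    tot <- rpois(n_cells, 8)
    pa <- ifelse(groups == "A", 0.8, 0.2)
    t1 <- rbinom(n_cells, tot, pa)
    rows[[paste0(gid, ".A")]] <- t1
    rows[[paste0(gid, ".B")]] <- tot - t1
    tx2gene[[gid]] <- data.frame(
      transcript_id = paste0(gid, c(".A", ".B")), gene_id = gid)
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- paste0("c", seq_len(n_cells))
  res <- dtu_test(mat, do.call(rbind, tx2gene), groups)
  expect_gt(mean(res$events$significant), 0.9)
})
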