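test_that("directional UMI clustering follows the count rule", {
  expect_equal(nrow(dedup_umis(rep("AAAAAAAA", 5))), 1)
  expect_equal(nrow(dedup_umis(c(rep("AAAAAAAA", 5), rep("TTTTTTTT", 5)))), 2)
  one <- dedup_umis(c(AAAAAAAA = 10, AAAAAAAT = 1))
  expect_equal(nrow(one), 1)
  expect_equal(one$representative, "AAAAAAAA")
  expect_equal(one$reads, 11L)
  two <- dedup_umis(c(AAAAAAAA = 10, AAAAAAAT = 9))
  expect_equal(nrow(two), 2)
  expect_equal(nrow(dedup_umis(character(0))), 0)
})

test_that("UMI clusters satisfy the directional invariants on random inputs", {
  set.seed(41)
  for (rep in 1:30) {
    core <- random_dna(sample(2:6, 1), 8)
    umis <- sample(core, 60, replace = TRUE)
    # sprinkle 1-edit neighbours
    mut <- vapply(sample(umis, 15), function(u) {
      ch <- strsplit(u, "")[[1]]
      i <- sample(8, 1)
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      paste0(ch, collapse = "")
    }, character(1))
    all_umis <- c(umis, mut)
    cl <- dedup_umis(all_umis, max_dist = 1)
    # conservation of reads
    expect_equal(sum(cl$reads), length(all_umis))
    # representatives are mutually unmergeable local maxima
    if (nrow(cl) > 1) {
      d <- edit_distance(cl$representative)
      cnt <- table(all_umis)[cl$representative]
      for (i in seq_len(nrow(cl))) for (j in seq_len(nrow(cl))) {
        if (i == j) next
        expect_false(d[i, j] <= 1 && cnt[i] >= 2 * cnt[j] - 1)
      }
    }
    # idempotence on representatives
    again <- dedup_umis(setNames(as.integer(cl$reads), cl$representative),
                        max_dist = 1)
    expect_equal(sort(again$representative), sort(cl$representative))
    # distance 0 counts distinct sequences
    expect_equal(nrow(dedup_umis(all_umis, max_dist = 0)),
                 length(unique(all_umis)))
  }
})

test_that("count matrices conserve molecules and reject dedup violations", {
  recs <- data.frame(cell_id = c("c1", "c1", "c2"),
                     feature_id = c("g1", "g1", "g2"),
                     umi_representative = c("AAAA", "CCCC", "AAAA"),
                     read_count = c(3L, 1L, 2L))
  m <- build_count_matrix(recs)
  expect_equal(dim(m), c(2, 2))
  expect_equal(sum(m), nrow(recs))
  expect_equal(m["g1", "c1"], 2)
  dup <- rbind(recs, recs[1, ])
  expect_error(build_count_matrix(dup), "deduplication contract")
  single <- build_count_matrix(recs[1, , drop = FALSE])
  expect_equal(dim(single), c(1, 1))
  expect_equal(sum(single), 1)
  d <- withr::local_tempdir()
  write_count_matrix(m, d)
  back <- read_count_matrix(d)
  expect_equal(as.matrix(back), as.matrix(m))
})

test_that("error-free pipeline reproduces truth molecule counts exactly", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 5, seed = 51)
  sp <- spikein_panel(n = 10, seed = 52)
  sim <- simulate_reads(20, wl$rt, wl$pcr, transcriptome = tx,
                        spikeins = sp, error_model = error_model(0, 0, 0),
                        seed = 53)
  dm <- demultiplex(sim$reads, default_layout(), wl$rt, wl$pcr)
  reads <- assign_reads_truth(dm$assignments, sim$truth)
  expect_equal(nrow(reads), nrow(sim$truth))  # 100% assignment

  # with exact UMI matching the molecule count equals the number of
  # distinct true UMIs per cell x feature
  mol0 <- count_molecules(reads, max_dist = 0)
  truth_distinct <- stats::aggregate(
    umi_sequence ~ cell_id + source_feature_id, data = sim$truth,
    FUN = function(u) length(unique(u)))
  m_pipe <- build_count_matrix(mol0)
  key <- paste(truth_distinct$source_feature_id, truth_distinct$cell_id)
  got <- m_pipe[cbind(match(truth_distinct$source_feature_id,
                            rownames(m_pipe)),
                      match(truth_distinct$cell_id, colnames(m_pipe)))]
  expect_equal(got, truth_distinct$umi_sequence)
  expect_equal(sum(m_pipe), sum(truth_distinct$umi_sequence))

  # directional dedup of the pipeline equals directional dedup of truth
  mol1 <- count_molecules(reads, max_dist = 1)
  truth_reads <- data.frame(cell_id = sim$truth$cell_id,
                            feature_id = sim$truth$source_feature_id,
                            umi = sim$truth$umi_sequence)
  mol1t <- count_molecules(truth_reads, max_dist = 1)
  expect_equal(nrow(mol1), nrow(mol1t))
})

test_that("spike-in correlation behaves at the boundaries", {
  panel <- data.frame(spike_id = sprintf("S%02d", 1:10),
                      concentration = 2^(1:10))
  mat <- Matrix::Matrix(matrix(rep(panel$concentration * 4, 3), ncol = 3,
                               dimnames = list(panel$spike_id, paste0("c", 1:3))),
                        sparse = TRUE)
  r <- ercc_correlation(mat, panel)
  expect_equal(r$r, 1.0, tolerance = 1e-12)
  expect_equal(r$n_used, 10)
  const <- Matrix::Matrix(matrix(5, 10, 3,
                                 dimnames = dimnames(mat)), sparse = TRUE)
  expect_error(ercc_correlation(const, panel), "zero variance")
  expect_error(ercc_correlation(mat[1:2, ], panel[1:2, ]), "at least 3")
  lin <- ercc_correlation(mat, panel, transform = "linear")
  expect_equal(lin$r, 1.0, tolerance = 1e-12)
})

test_that("UMI multiset matching is exact on structured cases", {
  set.seed(61)
  base <- generate_whitelist(20, 8, 4, seed = 62)$barcodes |> unname()
  expect_equal(match_umi_sets(base, base), 1.0)
  far <- c("AAAAAAAA", "CCCCCCCC", "GGGGGGGG")
  expect_equal(match_umi_sets(far, c("TTTTTTTT", "ACACACAC")), 0.0)
  mutated <- vapply(base, function(u) {
    ch <- strsplit(u, "")[[1]]
    i <- sample(8, 1)
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    paste0(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_equal(match_umi_sets(base, mutated, max_dist = 1), 1.0)
  # greedy result matches brute-force optimal matching here
  expect_equal(match_umi_sets(base, mutated, max_dist = 1),
               optimal_umi_matching(base, mutated, 1) / length(base))
  # and never exceeds the optimum on random sets
  for (rep in 1:10) {
    a <- unique(random_dna(12, 6)); b <- random_dna(12, 6)
    expect_lte(match_umi_sets(a, b, max_dist = 2),
               optimal_umi_matching(a, b, 2) / length(a) + 1e-9)
  }
})

test_that("saturation curves are anchored and non-decreasing", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 12, seed = 71)
  sim <- simulate_reads(10, wl$rt, wl$pcr, transcriptome = tx,
                        error_model = error_model(0, 0, 0), seed = 72)
  reads <- data.frame(cell_id = sim$truth$cell_id,
                      feature_id = sim$truth$source_feature_id,
                      gene_id = sim$truth$gene_id,
                      umi = sim$truth$umi_sequence)
  max_depth <- max(table(reads$cell_id))
  sat <- saturation_curve(reads, c(0, 5, 20, 100, max_depth), seed = 73)
  expect_equal(sat$median_genes[1], 0)
  expect_true(!is.unsorted(sat$median_genes))
  full <- count_molecules(reads)
  ng <- tapply(reads$gene_id[match(full$feature_id, reads$feature_id)],
               full$cell_id, function(x) length(unique(x)))
  expect_equal(sat$median_genes[nrow(sat)], median(as.vector(ng)))
})
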