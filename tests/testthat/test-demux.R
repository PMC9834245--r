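# build one exact read for the default layout
exact_read <- function(layout, pcr_seq, insert, umi, rt_seq) {
  seg <- layout$segments
  paste0(seg$sequence[1], pcr_seq, insert, strrep("A", 20), umi, rt_seq,
         seg$sequence[nrow(seg)])
}

test_that("orientation detection recovers the strand and flags garbage", {
  wl <- small_whitelists()
  lay <- default_layout()
  r <- exact_read(lay, wl$pcr$barcodes[1], random_dna(1, 300),
                  "ACGTACGT", wl$rt$barcodes[1])
  o <- orient_read(r, lay)
  expect_equal(o$orientation, "+")
  expect_identical(o$sequence, r)
  o2 <- orient_read(revcomp(r), lay)
  expect_equal(o2$orientation, "-")
  expect_identical(o2$sequence, r)
  set.seed(1)
  expect_equal(orient_read(random_dna(1, 400), lay)$orientation, "*")
})

test_that("structure parsing extracts truth segments and names failures", {
  wl <- small_whitelists()
  lay <- default_layout()
  umi <- "ACGTACGT"
  r <- exact_read(lay, wl$pcr$barcodes[3], random_dna(1, 300), umi,
                  wl$rt$barcodes[2])
  p <- parse_structure(r, lay)
  expect_true(p$complete)
  expect_identical(p$pcr_barcode_obs, unname(wl$pcr$barcodes[3]))
  expect_identical(p$rt_barcode_obs, unname(wl$rt$barcodes[2]))
  expect_identical(p$umi_obs, umi)

  seg <- lay$segments
  no3p <- paste0(seg$sequence[1], wl$pcr$barcodes[3], random_dna(1, 300),
                 strrep("A", 20), umi, wl$rt$barcodes[2])
  p3 <- parse_structure(no3p, lay)
  expect_false(p3$complete)
  expect_equal(p3$failure_reason, "missing_adapter_3p")

  noA <- paste0(seg$sequence[1], wl$pcr$barcodes[3], random_dna(1, 300),
                umi, wl$rt$barcodes[2], seg$sequence[nrow(seg)])
  pA <- parse_structure(noA, lay)
  expect_false(pA$complete)
  expect_equal(pA$failure_reason, "missing_polyA")
})

test_that("barcode assignment resolves errors within the distance budget", {
  wl <- protocol_whitelists()$pcr
  exact <- assign_barcode(unname(wl$barcodes[10]), wl)
  expect_equal(exact$barcode_id, names(wl$barcodes)[10])
  expect_equal(exact$distance, 0L)

  tie_wl <- barcode_whitelist(c(x = "AAAAAAAA", y = "TTTTTTTT"))
  tie <- assign_barcode("AAAATTTT", tie_wl, max_dist = 5, min_margin = 1)
  expect_equal(tie$status, "ambiguous")

  far <- assign_barcode(random_dna(1, 24), wl, max_dist = 2)
  expect_true(far$status %in% c("too_distant", "ambiguous"))

  # two random substitutions stay uniquely resolvable (min distance 11)
  set.seed(31)
  for (rep in 1:20) {
    i <- sample(96, 1)
    ch <- strsplit(unname(wl$barcodes[i]), "")[[1]]
    at <- sample(24, 2)
    ch[at] <- vapply(ch[at], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    hit <- assign_barcode(paste0(ch, collapse = ""), wl, max_dist = 5,
                          min_margin = 2)
    expect_equal(hit$barcode_id, names(wl$barcodes)[i])
    expect_lte(hit$distance, 2L)
  }
})

test_that("error-free libraries demultiplex to the truth table exactly", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 4, seed = 21)
  sim <- simulate_reads(24, wl$rt, wl$pcr, transcriptome = tx,
                        error_model = error_model(0, 0, 0), seed = 22)
  dm <- demultiplex(sim$reads, default_layout(), wl$rt, wl$pcr)
  a <- dm$assignments
  expect_true(all(a$status == "assigned"))
  m <- match(a$read_id, sim$truth$read_id)
  expect_identical(a$cell_id, sim$truth$cell_id[m])
  expect_identical(a$umi, sim$truth$umi_sequence[m])
  expect_equal(unname(dm$stats$counts["ambiguous"]), 0)
})

test_that("broken reads are rejected and the assigned fraction tracks the intact fraction", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 4, seed = 23)
  sim <- simulate_reads(24, wl$rt, wl$pcr, transcriptome = tx,
                        error_model = error_model(0, 0, 0),
                        broken_fraction = 0.25, seed = 24)
  dm <- demultiplex(sim$reads, default_layout(), wl$rt, wl$pcr)
  a <- dm$assignments
  m <- match(a$read_id, sim$truth$read_id)
  # no broken read is ever assigned
  expect_true(all(sim$truth$structure_complete[m][a$status == "assigned"]))
  expect_equal(unname(dm$stats$fractions["assigned"]), 0.75,
               tolerance = 0.02)
})

test_that("empty input yields empty output with zeroed stats", {
  wl <- small_whitelists()
  dm <- demultiplex(character(0), default_layout(), wl$rt, wl$pcr)
  expect_equal(nrow(dm$assignments), 0)
  expect_true(all(dm$stats$counts == 0))
})

test_that("statuses partition the input reads", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 4, seed = 25)
  sim <- simulate_reads(24, wl$rt, wl$pcr, transcriptome = tx,
                        broken_fraction = 0.15, seed = 26)
  reads <- head(sim$reads, 1500)
  dm <- demultiplex(reads, default_layout(), wl$rt, wl$pcr)
  expect_equal(sum(dm$stats$counts) + dm$stats$n_malformed, length(reads))
  expect_false(any(is.na(dm$assignments$status)))
})

test_that("assignment counts are monotone in max_dist and min_margin", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 4, seed = 27)
  sim <- simulate_reads(24, wl$rt, wl$pcr, transcriptome = tx, seed = 28)
  reads <- head(sim$reads, 1200)
  lay <- default_layout()
  n_assigned <- function(md, mm)
    unname(demultiplex(reads, lay, wl$rt, wl$pcr, max_dist = md,
                       min_margin = mm)$stats$counts["assigned"])
  a2 <- n_assigned(2, 2); a4 <- n_assigned(4, 2); a6 <- n_assigned(6, 2)
  expect_lte(a2, a4); expect_lte(a4, a6)
  m0 <- n_assigned(5, 0); m3 <- n_assigned(5, 3); m6 <- n_assigned(5, 6)
  expect_gte(m0, m3); expect_gte(m3, m6)
})

test_that("demultiplexing is invariant to read strand", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 4, seed = 29)
  sim <- simulate_reads(12, wl$rt, wl$pcr, transcriptome = tx, seed = 30)
  reads <- head(sim$reads, 300)
  lay <- default_layout()
  fwd <- demultiplex(reads, lay, wl$rt, wl$pcr)$assignments
  rev <- demultiplex(setNames(revcomp(reads), names(reads)), lay, wl$rt,
                     wl$pcr)$assignments
  expect_identical(fwd$status, rev$status)
  expect_identical(fwd$cell_id, rev$cell_id)
  expect_identical(fwd$umi, rev$umi)
})

test_that("malformed records are counted and skipped", {
  wl <- small_whitelists()
  tx <- generate_transcriptome(n_genes = 2, seed = 31)
  sim <- simulate_reads(5, wl$rt, wl$pcr, transcriptome = tx, seed = 32)
  reads <- c(sim$reads[1:20], bad1 = "", bad2 = "XXYYZZ")
  expect_warning(dm <- demultiplex(reads, default_layout(), wl$rt, wl$pcr),
                 "malformed")
  expect_equal(dm$stats$n_malformed, 2)
  expect_equal(sum(dm$stats$counts), 20)
})
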