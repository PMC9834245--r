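test_that("junction chains come from exon boundaries", {
  m <- transcript_model("m", "chr1", "+", c(1, 201), c(100, 300))
  j <- extract_junctions(m)
  expect_equal(j$donor, 100)
  expect_equal(j$acceptor, 201)
  single <- transcript_model("s", "chr1", "+", 10, 500)
  expect_equal(nrow(extract_junctions(single)), 0)
  multi <- transcript_model("n", "chr1", "+", c(1, 201, 401, 601),
                            c(100, 300, 500, 700))
  jm <- extract_junctions(multi)
  expect_equal(nrow(jm), 3)
  expect_true(all(diff(c(t(as.matrix(jm)))) > 0))
  expect_error(transcript_model("bad", "chr1", "+", c(1, 50), c(100, 300)),
               "non-overlapping")
})

test_that("each category is recovered from engineered models", {
  idx <- toy_index()
  cls <- function(...) classify_transcript(transcript_model(...), idx)

  fsm <- cls("fsm", "chr1", "+", c(101, 301, 501), c(200, 400, 600))
  expect_equal(fsm$category, "FSM")
  expect_equal(fsm$matched_reference_transcript, "tx_a")

  ism <- cls("ism", "chr1", "+", c(301, 501), c(400, 600))
  expect_equal(ism$category, "ISM")
  expect_equal(ism$matched_reference_transcript, "tx_a")

  cj <- cls("cj", "chr1", "+", c(101, 301, 521), c(200, 400, 600))
  expect_equal(cj$category, "NIC")
  expect_equal(cj$nic_subcategory, "CJ")

  cs <- cls("cs", "chr1", "+", c(101, 521), c(200, 600))
  expect_equal(cs$category, "NIC")
  expect_equal(cs$nic_subcategory, "CS")

  ir <- cls("ir", "chr1", "+", 101, 400)
  expect_equal(ir$category, "NIC")
  expect_equal(ir$nic_subcategory, "IR")

  nnc <- cls("nnc", "chr1", "+", c(101, 301), c(210, 400))
  expect_equal(nnc$category, "NNC")

  genic <- cls("genic", "chr1", "+", 120, 180)
  expect_equal(genic$category, "genic")

  anti <- cls("anti", "chr1", "-", c(101, 301), c(200, 400))
  expect_equal(anti$category, "antisense")

  fus <- cls("fus", "chr1", "+", c(501, 2001), c(600, 2100))
  expect_equal(fus$category, "fusion")

  inter <- cls("inter", "chr1", "+", 5000, 5100)
  expect_equal(inter$category, "intergenic")

  unknown <- cls("offmap", "chrZ", "+", 1, 100)
  expect_equal(unknown$category, "intergenic")
})

test_that("every model receives exactly one category and NIC excludes novel sites", {
  idx <- toy_index()
  set.seed(81)
  cats <- character(0)
  for (rep in 1:40) {
    # random perturbations of tx_a exon boundaries; zero-heavy so that
    # known-site chains (FSM/ISM/NIC) arise alongside novel-site ones
    starts <- c(101, 301, 501) + sample(c(0, 0, 0, 0, 20, -9, 15), 3,
                                        replace = TRUE)
    ends <- c(200, 400, 600) + sample(c(0, 0, 0, 0, 20, -9, 15), 3,
                                      replace = TRUE)
    cl <- classify_transcript(
      transcript_model("r", "chr1", "+", starts, ends), idx)
    expect_equal(nrow(cl), 1)
    expect_true(cl$category %in% c("FSM", "ISM", "NIC", "NNC", "genic",
                                   "antisense", "fusion", "intergenic"))
    expect_equal(cl$nic_subcategory != "none", cl$category == "NIC")
    # a model with a splice site unknown at the locus is never NIC
    j <- extract_junctions(transcript_model("r", "chr1", "+", starts, ends))
    known <- all(j$donor %in% c(200, 400)) &
      all(j$acceptor %in% c(301, 321, 501, 521))
    if (!known) expect_false(cl$category == "NIC")
    cats <- c(cats, cl$category)
  }
  expect_gt(length(unique(cats)), 1)
})

test_that("nic_subcategory refuses non-NIC models", {
  idx <- toy_index()
  m <- transcript_model("fsm", "chr1", "+", c(101, 301, 501),
                        c(200, 400, 600))
  expect_error(nic_subcategory(m, idx), "FSM")
})

test_that("generated annotations self-classify as FSM", {
  tx <- generate_transcriptome(n_genes = 10, isoforms_per_gene = c(1, 3),
                               pseudogene_pairs = 2, seed = 85)
  idx <- annotation_index(tx$annotation)
  models <- read_transcript_models(tx$annotation)
  cls <- classify_transcripts(models, idx)
  expect_true(all(cls$category == "FSM"))
  expect_identical(sort(cls$model_id),
                   sort(cls$matched_reference_transcript))
})

test_that("junction canonicity reads strand-corrected motifs", {
  # engineered toy genome: 10 introns, 9 canonical GT..AG and 1 AA..TT
  set.seed(91)
  g <- strsplit(random_dna(1, 2000), "")[[1]]
  donors <- seq(100, 1900, by = 200)[1:10]
  acceptors <- donors + 80
  for (k in 1:9) {
    g[donors[k] + 1:2] <- c("G", "T")
    g[acceptors[k] - 2:1] <- c("A", "G")
  }
  g[donors[10] + 1:2] <- c("A", "A")
  g[acceptors[10] - 2:1] <- c("T", "T")
  genome <- Biostrings::DNAStringSet(setNames(paste0(g, collapse = ""),
                                              "chrT"))
  j <- data.frame(contig = "chrT", strand = "+", donor = donors,
                  acceptor = acceptors)
  res <- junction_canonicity(j, genome)
  expect_equal(res$canonical_fraction, 0.9)
  expect_equal(res$junctions$motif[1], "GT..AG")

  # minus strand: genomic CT..AC is the reverse complement of GT..AG
  g[donors[1] + 1:2] <- c("C", "T")
  g[acceptors[1] - 2:1] <- c("A", "C")
  genome2 <- Biostrings::DNAStringSet(setNames(paste0(g, collapse = ""),
                                               "chrT"))
  jm <- data.frame(contig = "chrT", strand = "-", donor = donors[1],
                   acceptor = acceptors[1])
  resm <- junction_canonicity(jm, genome2)
  expect_equal(resm$junctions$motif[1], "GT..AG")
  expect_true(resm$junctions$canonical[1])

  # out-of-bounds junctions are flagged invalid and excluded
  jbad <- rbind(j, data.frame(contig = "chrT", strand = "+", donor = 1990,
                              acceptor = 2100))
  resb <- junction_canonicity(jbad, genome)
  expect_false(resb$junctions$valid[11])
  expect_equal(resb$canonical_fraction, 0.9)

  # generated transcriptomes are engineered fully canonical
  txg <- generate_transcriptome(n_genes = 6, seed = 92)
  models <- read_transcript_models(txg$annotation)
  jall <- do.call(rbind, lapply(models, function(m) {
    jj <- extract_junctions(m)
    if (nrow(jj) == 0) return(NULL)
    data.frame(contig = m$contig, strand = m$strand, donor = jj$donor,
               acceptor = jj$acceptor)
  }))
  expect_equal(junction_canonicity(jall, txg$genome)$canonical_fraction, 1.0)
})
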