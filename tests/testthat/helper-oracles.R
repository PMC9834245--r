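# Independent oracles and shared fixtures for the suite.

# quadratic-DP Levenshtein, pure R, independent of the package kernels
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  prev <- 0:n
  for (i in seq_len(m)) {
    curr <- integer(n + 1)
    curr[1] <- i
    for (j in seq_len(n)) {
      curr[j + 1] <- min(prev[j] + (x[i] != y[j]), prev[j + 1] + 1,
                         curr[j] + 1)
    }
    prev <- curr
  }
  as.integer(prev[n + 1])
}

# naive per-base corruption loop with the same model semantics
# (exclusive del/sub/ins categories, sub never reproduces the base,
# insertion after the position) -- used as a Monte-Carlo oracle
naive_corrupt <- function(seq, model) {
  bases <- c("A", "C", "G", "T")
  ch <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (b in ch) {
    u <- runif(1)
    if (u < model$deletion_rate) next
    if (u < model$deletion_rate + model$substitution_rate) {
      b <- sample(setdiff(bases, b), 1)
    } else if (u < model$deletion_rate + model$substitution_rate +
               model$insertion_rate) {
      out <- c(out, b)
      b <- sample(bases, 1)
    }
    out <- c(out, b)
  }
  paste0(out, collapse = "")
}

# optimal one-to-one matching size between two UMI sets at max_dist,
# by augmenting-path bipartite matching (brute force)
optimal_umi_matching <- function(a, b, max_dist = 1L) {
  d <- utils::adist(a, b) <= max_dist
  match_b <- rep(0L, length(b))
  try_aug <- function(i, seen) {
    for (j in which(d[i, ])) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_b[j] == 0L || Recall(match_b[j], seen)) {
        match_b[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  n <- 0L
  for (i in seq_along(a)) {
    if (try_aug(i, rep(FALSE, length(b)))) n <- n + 1L
  }
  n
}

# memoized protocol-scale whitelists (expensive to regenerate per test)
protocol_whitelists <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        rt = generate_whitelist(32, 24, 11, seed = 101, name = "rt",
                                id_prefix = "rt"),
        pcr = generate_whitelist(96, 24, 11, seed = 102, name = "pcr",
                                 id_prefix = "pcr"))
    }
    cache
  }
})

# small whitelists for fast demux round trips
small_whitelists <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(
        rt = generate_whitelist(8, 24, 11, seed = 103, name = "rt",
                                id_prefix = "rt"),
        pcr = generate_whitelist(12, 24, 11, seed = 104, name = "pcr",
                                 id_prefix = "pcr"))
    }
    cache
  }
})

# hand-built reference annotation for the classifier:
# gene GX (chr1, +): tx_a exons [101,200],[301,400],[501,600]
#                    tx_c exons [101,200],[321,400],[521,600]
# gene GY (chr1, +): [2001,2100],[2201,2300]  (distinct locus)
toy_index <- function() {
  gr <- c(
    GenomicRanges::GRanges("chr1", IRanges::IRanges(
      c(101, 301, 501, 101, 321, 521),
      c(200, 400, 600, 200, 400, 600)),
      strand = "+", type = "exon",
      gene_id = "GX",
      transcript_id = c(rep("tx_a", 3), rep("tx_c", 3))),
    GenomicRanges::GRanges("chr1", IRanges::IRanges(c(2001, 2201),
                                                    c(2100, 2300)),
      strand = "+", type = "exon", gene_id = "GY",
      transcript_id = "tx_y"))
  annotation_index(gr)
}
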