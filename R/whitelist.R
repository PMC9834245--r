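#' Barcode whitelist
#'
#' A named, ordered set of fixed-length barcodes with a guaranteed minimum
#' pairwise Levenshtein distance. Cell-identifying barcodes must be far
#' apart in edit space so that the per-barcode sequencing errors of a noisy
#' long-read platform (typically a handful of errors on a 24-mer) cannot
#' turn one whitelist entry into another.
#'
#' @param barcodes Named character vector (names are barcode ids, values
#'   uppercase ACGT sequences, all the same length, all distinct).
#' @param name Label for the whitelist (e.g. "rt", "pcr").
#' @param min_pairwise_distance Claimed minimum pairwise edit distance;
#'   verified at construction (skipped for a single barcode).
#' @return Object of class `barcode_whitelist`.
#' @export
barcode_whitelist <- function(barcodes, name = "whitelist",
                              min_pairwise_distance = 1L) {
  stopifnot(is.character(barcodes), length(barcodes) >= 1L)
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop("barcodes must have unique names (barcode ids)")
  if (!all(grepl("^[ACGT]+$", barcodes)))
    stop("barcodes must be uppercase ACGT sequences")
  len <- unique(nchar(barcodes))
  if (length(len) != 1L)
    stop("all barcodes must have the same length")
  if (anyDuplicated(barcodes))
    stop("barcode sequences must be unique")
  if (length(barcodes) >= 2L) {
    d <- edit_distance(barcodes)
    observed_min <- min(d[upper.tri(d)])
    if (observed_min < min_pairwise_distance)
      stop(sprintf(
        "observed minimum pairwise edit distance %d is below the declared %d",
        observed_min, min_pairwise_distance))
  }
  structure(
    list(name = name, barcodes = barcodes, length = as.integer(len),
         min_pairwise_distance = as.integer(min_pairwise_distance)),
    class = "barcode_whitelist")
}

#' @export
print.barcode_whitelist <- function(x, ...) {
  cat(sprintf(
    "<barcode_whitelist '%s'> %d barcodes of %d nt, min pairwise distance >= %d\n",
    x$name, length(x$barcodes), x$length, x$min_pairwise_distance))
  invisible(x)
}

#' @export
length.barcode_whitelist <- function(x) length(x$barcodes)

#' Design a barcode whitelist by seeded rejection sampling
#'
#' Draws random barcodes and keeps a candidate only if its Levenshtein
#' distance to every accepted barcode is at least `min_dist`. Deterministic
#' for a fixed seed. At the scale used by dual-barcode long-read protocols
#' (96 barcodes of 24 nt at minimum distance 11) random 24-mers almost
#' always satisfy the constraint, so rejection sampling converges quickly.
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bases.
#' @param min_dist Required minimum pairwise edit distance.
#' @param seed Integer seed (NULL to use the current RNG state).
#' @param name Whitelist label.
#' @param id_prefix Prefix for barcode ids (`<prefix>01`, ...).
#' @param max_tries Rejection-sampling retry cap.
#' @return A [barcode_whitelist].
#' @examples
#' wl <- generate_whitelist(8, length = 12, min_dist = 4, seed = 1)
#' min(edit_distance(wl$barcodes)[upper.tri(diag(8))])
#' @export
generate_whitelist <- function(n, length, min_dist, seed = NULL,
                               name = "whitelist", id_prefix = "bc",
                               max_tries = 1e6) {
  stopifnot(n >= 1, length >= 1, min_dist >= 0)
  if (min_dist > length)
    stop(sprintf(
      "min_dist (%d) exceeds the maximum possible Levenshtein distance (%d) between length-%d barcodes",
      min_dist, length, length))
  if (!is.null(seed)) set.seed(seed)
  accepted <- character(0)
  tries <- 0L
  while (base::length(accepted) < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop(sprintf(
        "could not place %d barcodes of length %d at min distance %d within %g tries; relax the constraint",
        n, length, min_dist, max_tries))
    cand <- random_dna(1L, length)
    if (base::length(accepted) == 0L ||
        min(edit_distance(cand, accepted)) >= min_dist) {
      accepted <- c(accepted, cand)
    }
  }
  names(accepted) <- sprintf("%s%02d", id_prefix, seq_len(n))
  barcode_whitelist(accepted, name = name,
                    min_pairwise_distance = as.integer(min_dist))
}

#' Audit all pairwise distances of a whitelist
#'
#' Computes the full all-pairs Levenshtein distance matrix and summarizes
#' it. Useful to confirm that observed per-barcode error counts stay well
#' below half the minimum pairwise distance.
#'
#' @param whitelist A [barcode_whitelist] (or named character vector) with
#'   at least two barcodes.
#' @return List with `min`, `max`, `mean`, `n_pairs` and `distribution`
#'   (a table of pairwise distances).
#' @export
whitelist_distance_audit <- function(whitelist) {
  bc <- if (inherits(whitelist, "barcode_whitelist")) whitelist$barcodes
        else whitelist
  if (length(bc) < 2L)
    stop("whitelist audit needs at least two barcodes")
  d <- edit_distance(bc)
  pd <- d[upper.tri(d)]
  list(min = min(pd), max = max(pd), mean = mean(pd),
       n_pairs = length(pd), distribution = table(pd))
}

#' Write / read whitelists as two-column TSV (barcode_id, sequence)
#'
#' @param whitelist A [barcode_whitelist].
#' @param path Output TSV path.
#' @export
write_whitelist <- function(whitelist, path) {
  write.table(
    data.frame(barcode_id = names(whitelist$barcodes),
               sequence = unname(whitelist$barcodes)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @param name,min_pairwise_distance Passed to [barcode_whitelist].
#' @export
read_whitelist <- function(path, name = "whitelist",
                           min_pairwise_distance = 1L) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  barcode_whitelist(setNames(df$sequence, df$barcode_id), name = name,
                    min_pairwise_distance = min_pairwise_distance)
}
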