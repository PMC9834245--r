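DNA_BASES <- c("A", "C", "G", "T")

#' Generate random DNA sequences
#'
#' Uniform i.i.d. sequences over A/C/G/T, drawn from the current RNG stream.
#'
#' @param n Number of sequences.
#' @param width Length of each sequence in bases.
#' @return Character vector of length `n`.
#' @export
random_dna <- function(n, width) {
  stopifnot(n >= 0, width >= 1)
  if (n == 0) return(character(0))
  chars <- sample(DNA_BASES, n * width, replace = TRUE)
  apply(matrix(chars, nrow = width), 2, paste0, collapse = "")
}

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of ACGT(N) sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Pairwise Levenshtein edit distances
#'
#' Unit-cost edit distance (substitution, insertion, deletion) between two
#' sets of strings, as a full distance matrix.
#'
#' @param a,b Character vectors; `b` defaults to `a`.
#' @return Integer matrix of dimension `length(a)` x `length(b)`.
#' @export
edit_distance <- function(a, b = a) {
  d <- utils::adist(a, b)
  storage.mode(d) <- "integer"
  d
}

#' Locate a pattern inside noisy sequences by semi-global alignment
#'
#' Aligns the whole `pattern` against the best-matching substring of each
#' text (edit distance with free leading/trailing gaps in the text). Used to
#' anchor fixed adapters in error-containing long reads.
#'
#' @param pattern Single pattern string.
#' @param texts Character vector of texts to search.
#' @return Data frame with columns `dist`, `start`, `end` (1-based inclusive
#'   match coordinates in each text; `end = 0` if the best alignment deletes
#'   the whole pattern).
#' @export
locate_subsequence <- function(pattern, texts) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nchar(pattern) >= 1L)
  .infix_locate_cpp(pattern, as.character(texts))
}

#' Write sequences as FASTQ
#'
#' @param seqs Named character vector of sequences (names become read ids).
#' @param path Output path (`.gz` suffix triggers gzip compression).
#' @param quality Constant per-base quality character (default "I", Q40).
#' @export
write_fastq <- function(seqs, path, quality = "I") {
  dna <- Biostrings::DNAStringSet(unname(seqs))
  names(dna) <- names(seqs)
  quals <- Biostrings::BStringSet(strrep(quality, Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = quals)
  invisible(path)
}

#' Read a FASTQ file as a named character vector
#'
#' @param path FASTQ path (optionally gzipped).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- as.character(dna)
  # FASTQ ids may carry comments after whitespace; keep the id token only
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

# internal: Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
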