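#' Per-base sequencing error model
#'
#' Independent per-base substitution / insertion / deletion probabilities
#' plus optional whole-read end truncation, emulating Nanopore-era error
#' behavior. Substitutions never reproduce the original base; insertions
#' add one uniform random base after the position. Truncation clips a
#' geometric number of bases (mean `truncation_mean`) from an end with the
#' given per-read probability.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base
#'   probabilities; their sum must be < 1.
#' @param truncation_5p_prob,truncation_3p_prob Per-read clip probabilities.
#' @param truncation_mean Mean clipped bases when truncation occurs.
#' @return Object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.03, insertion_rate = 0.02,
                        deletion_rate = 0.02, truncation_5p_prob = 0,
                        truncation_3p_prob = 0, truncation_mean = 50) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate,
             truncation_5p_prob, truncation_3p_prob)
  if (any(rates < 0) || any(rates > 1))
    stop("all error-model probabilities must lie in [0, 1]")
  if (substitution_rate + insertion_rate + deletion_rate >= 1)
    stop("per-base substitution + insertion + deletion rates must total < 1")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 truncation_5p_prob = truncation_5p_prob,
                 truncation_3p_prob = truncation_3p_prob,
                 truncation_mean = truncation_mean),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model> sub %.3g, ins %.3g, del %.3g per base; truncation p5 %.3g / p3 %.3g (mean %g nt)\n",
    x$substitution_rate, x$insertion_rate, x$deletion_rate,
    x$truncation_5p_prob, x$truncation_3p_prob, x$truncation_mean))
  invisible(x)
}

#' Corrupt sequences under an error model
#'
#' Vectorized over reads: each base independently falls into one of the
#' exclusive categories deletion / substitution / insertion / intact, then
#' end truncation is applied per read. Draws come from the current RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param seqs Character vector of non-empty ACGT sequences.
#' @param model An [error_model].
#' @return Character vector of corrupted sequences (same length as input).
#' @export
corrupt_sequences <- function(seqs, model) {
  stopifnot(inherits(model, "error_model"))
  if (length(seqs) == 0L) return(character(0))
  if (any(nchar(seqs) == 0L)) stop("sequences must be non-empty")
  p_del <- model$deletion_rate
  p_sub <- model$substitution_rate
  p_ins <- model$insertion_rate

  lens <- nchar(seqs)
  chars <- strsplit(seqs, "", fixed = TRUE)
  flat <- unlist(chars, use.names = FALSE)
  n <- length(flat)

  u <- runif(n)
  is_del <- u < p_del
  is_sub <- !is_del & u < p_del + p_sub
  is_ins <- !is_del & !is_sub & u < p_del + p_sub + p_ins

  out <- flat
  if (any(is_sub)) {
    orig <- match(flat[is_sub], DNA_BASES)
    shift <- sample.int(3L, sum(is_sub), replace = TRUE)
    out[is_sub] <- DNA_BASES[((orig - 1L + shift) %% 4L) + 1L]
  }
  if (any(is_ins)) {
    ins_base <- sample(DNA_BASES, sum(is_ins), replace = TRUE)
    out[is_ins] <- paste0(out[is_ins], ins_base)
  }
  out[is_del] <- ""
  # reassemble without per-read splitting: one flat paste, then substring
  # at cumulative per-read boundaries
  big <- paste(out, collapse = "")
  outlen <- nchar(out)
  ends_flat <- cumsum(outlen)
  read_end <- ends_flat[cumsum(lens)]
  read_start <- c(0L, read_end[-length(read_end)]) + 1L
  res <- substring(big, read_start, read_end)
  names(res) <- names(seqs)

  # end truncation (read may lose a clip of geometric extent)
  if (model$truncation_5p_prob > 0 || model$truncation_3p_prob > 0) {
    m <- length(res)
    w <- nchar(res)
    clip5 <- ifelse(runif(m) < model$truncation_5p_prob,
                    rgeom(m, 1 / (model$truncation_mean + 1)) + 1L, 0L)
    clip3 <- ifelse(runif(m) < model$truncation_3p_prob,
                    rgeom(m, 1 / (model$truncation_mean + 1)) + 1L, 0L)
    clip5 <- pmin(clip5, pmax(w - 1L, 0L))
    clip3 <- pmin(clip3, pmax(w - 1L - clip5, 0L))
    res <- substr(res, 1L + clip5, w - clip3)
  }
  res
}

#' @rdname corrupt_sequences
#' @param seq A single sequence.
#' @export
corrupt_sequence <- function(seq, model) {
  stopifnot(length(seq) == 1L)
  unname(corrupt_sequences(seq, model))
}
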