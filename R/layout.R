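#' Declarative read layout
#'
#' A library read is modeled as an ordered chain of segments. Segment kinds:
#' `fixed_adapter` (literal sequence), `pcr_barcode`, `rt_barcode`, `umi`
#' (fixed declared lengths), `polyA` (homopolymer tail of a declared
#' minimum length) and exactly one `insert` (the cDNA, variable length).
#' The first and last segments must be fixed adapters so that noisy reads
#' can be anchored from both ends; every barcode/UMI window is derived from
#' those anchors. `strandable = TRUE` means reads arrive on either strand.
#'
#' @param segments Data frame with columns `kind`, `length` (NA for
#'   fixed_adapter/insert) and `sequence` (NA except fixed_adapter).
#' @param strandable Logical; reads may be reverse-complemented.
#' @return Object of class `read_layout`.
#' @export
read_layout <- function(segments, strandable = TRUE) {
  stopifnot(is.data.frame(segments),
            all(c("kind", "length", "sequence") %in% names(segments)))
  kinds <- c("fixed_adapter", "rt_barcode", "pcr_barcode", "umi", "polyA",
             "insert")
  if (!all(segments$kind %in% kinds))
    stop("unknown segment kind: ",
         paste(setdiff(segments$kind, kinds), collapse = ", "))
  if (sum(segments$kind == "insert") != 1L)
    stop("layout must contain exactly one insert segment")
  fixed <- segments$kind == "fixed_adapter"
  if (any(fixed & (is.na(segments$sequence) | segments$sequence == "")))
    stop("fixed_adapter segments need a literal sequence")
  sized <- segments$kind %in% c("rt_barcode", "pcr_barcode", "umi", "polyA")
  if (any(sized & (is.na(segments$length) | segments$length < 1)))
    stop("barcode/umi/polyA segments need a positive declared length")
  if (segments$kind[1L] != "fixed_adapter" ||
      segments$kind[nrow(segments)] != "fixed_adapter")
    stop("the first and last segments must be fixed adapters (anchors)")
  segments$length[fixed] <- nchar(segments$sequence[fixed])
  structure(list(segments = segments, strandable = isTRUE(strandable)),
            class = "read_layout")
}

#' @export
print.read_layout <- function(x, ...) {
  seg <- x$segments
  lab <- ifelse(seg$kind == "fixed_adapter",
                sprintf("%s(%d)", seg$kind, nchar(seg$sequence)),
                ifelse(is.na(seg$length), seg$kind,
                       sprintf("%s(%d)", seg$kind, seg$length)))
  cat("<read_layout> 5'-[", paste(lab, collapse = "]-["), "]-3'",
      if (x$strandable) " (strandable)" else "", "\n", sep = "")
  invisible(x)
}

#' Default dual-barcode full-length layout
#'
#' 5' to 3': 5' adapter, 24-nt PCR barcode, cDNA insert, polyA tail,
#' 8-nt UMI, 24-nt RT barcode, 3' adapter — the oligo-dT/UMI/barcode
#' RT-primer design used by combinatorial dual-barcode full-length
#' protocols. Every length and both adapter literals are configurable so
#' the exact architecture of a given kit can be dropped in.
#'
#' @param pcr_barcode_len,rt_barcode_len,umi_len,polyA_len Segment lengths
#'   in bases.
#' @param adapter5,adapter3 Literal anchor sequences.
#' @param strandable Reads may arrive on either strand.
#' @return A [read_layout].
#' @export
default_layout <- function(pcr_barcode_len = 24L, rt_barcode_len = 24L,
                           umi_len = 8L, polyA_len = 20L,
                           adapter5 = "TTTCCATATCTCGTGAACCCCC",
                           adapter3 = "TGCACGCCCTAAAGTACAATTA",
                           strandable = TRUE) {
  read_layout(data.frame(
    kind = c("fixed_adapter", "pcr_barcode", "insert", "polyA", "umi",
             "rt_barcode", "fixed_adapter"),
    length = c(NA, pcr_barcode_len, NA, polyA_len, umi_len, rt_barcode_len,
               NA),
    sequence = c(adapter5, NA, NA, NA, NA, NA, adapter3),
    stringsAsFactors = FALSE), strandable = strandable)
}

#' Read a layout from a YAML description
#'
#' The YAML holds `strandable` and a `segments` list of
#' `{kind, length, sequence}` entries in 5'→3' order.
#'
#' @param path YAML file path.
#' @return A [read_layout].
#' @export
read_layout_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML layouts requires the 'yaml' package")
  y <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(y$segments, function(s) data.frame(
    kind = s$kind,
    length = if (is.null(s$length)) NA_integer_ else as.integer(s$length),
    sequence = if (is.null(s$sequence)) NA_character_ else s$sequence,
    stringsAsFactors = FALSE)))
  read_layout(seg, strandable = isTRUE(y$strandable %||% TRUE))
}

# internal: segment rows before/after the insert, for anchor-derived windows
layout_split <- function(layout) {
  seg <- layout$segments
  ins <- which(seg$kind == "insert")
  list(before = seg[seq_len(ins - 1L), , drop = FALSE],
       after = seg[seq(ins + 1L, nrow(seg)), , drop = FALSE],
       insert_at = ins)
}
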