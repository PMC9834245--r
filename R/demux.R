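# Structure-aware demultiplexing of noisy full-length reads:
# orient by adapter alignment, anchor fixed adapters, derive barcode/UMI
# windows from the anchors, and assign dual barcodes by bounded edit
# distance against the whitelists.

# internal: vectorized orientation. Strand score = summed semi-global
# distance of both terminal adapters; lower wins. Undetermined when no
# single adapter on either strand is within adapter_max_dist.
orient_many <- function(reads, layout, adapter_max_dist = 6L,
                        anchor_search_width = 150L) {
  seg <- layout$segments
  a5 <- seg$sequence[1L]
  a3 <- seg$sequence[nrow(seg)]
  fwd <- unname(reads)
  rev <- revcomp(fwd)
  w <- nchar(fwd)
  # terminal adapters are searched in end windows only (linear, not
  # quadratic, in read length); window must cover adapter + indel drift
  sw <- pmin(w, anchor_search_width)
  soff <- w - sw  # suffix window offset
  locate_ends <- function(x) {
    d5 <- .infix_locate_cpp(a5, substr(x, 1L, sw))
    d3 <- .infix_locate_cpp(a3, substr(x, soff + 1L, w))
    d3$start <- d3$start + soff; d3$end <- d3$end + soff
    list(d5 = d5, d3 = d3)
  }
  lf <- locate_ends(fwd)
  d5f <- lf$d5; d3f <- lf$d3
  if (layout$strandable) {
    lr <- locate_ends(rev)
    d5r <- lr$d5; d3r <- lr$d3
    use_rev <- (d5r$dist + d3r$dist) < (d5f$dist + d3f$dist)
  } else {
    d5r <- d5f; d3r <- d3f
    use_rev <- rep(FALSE, length(fwd))
  }
  best_any <- pmin(d5f$dist, d3f$dist, d5r$dist, d3r$dist)
  orientation <- ifelse(best_any > adapter_max_dist, "*",
                        ifelse(use_rev, "-", "+"))
  pick <- function(f, r, col) ifelse(use_rev, r[[col]], f[[col]])
  data.frame(
    read_id = names(reads) %||% sprintf("read%d", seq_along(reads)),
    orientation = orientation,
    oriented = ifelse(use_rev, rev, fwd),
    a5_dist = pick(d5f, d5r, "dist"), a5_start = pick(d5f, d5r, "start"),
    a5_end = pick(d5f, d5r, "end"),
    a3_dist = pick(d3f, d3r, "dist"), a3_start = pick(d3f, d3r, "start"),
    a3_end = pick(d3f, d3r, "end"),
    stringsAsFactors = FALSE)
}

#' Orient a read against a layout
#'
#' Chooses the strand whose terminal adapters align with the lower summed
#' semi-global edit distance; returns the read in layout orientation.
#' Orientation `"*"` (undetermined) is returned when no adapter on either
#' strand aligns within `adapter_max_dist`.
#'
#' @param read A single read sequence.
#' @param layout A [read_layout].
#' @param adapter_max_dist Maximum allowed adapter edit distance.
#' @return List with `sequence` (oriented) and `orientation` (+/-/*).
#' @export
orient_read <- function(read, layout, adapter_max_dist = 6L) {
  stopifnot(length(read) == 1L)
  o <- orient_many(setNames(read, "r"), layout, adapter_max_dist)
  list(sequence = if (o$orientation == "*") unname(read) else o$oriented,
       orientation = o$orientation)
}

# internal: detect a polyA run of >= min_len A bases with <= 1 interruption
polyA_in <- function(zones, min_len = 15L) {
  vapply(zones, function(z) {
    if (is.na(z) || nchar(z) < min_len) return(FALSE)
    m <- gregexpr("A+", z)[[1]]
    if (m[1] == -1L) return(FALSE)
    len <- attr(m, "match.length")
    if (any(len >= min_len)) return(TRUE)
    if (length(m) >= 2L) {
      gap <- m[-1L] - (m[-length(m)] + len[-length(len)])
      merged <- len[-length(len)] + len[-1L]
      if (any(gap == 1L & merged >= min_len)) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
}

# internal: vectorized structure parsing of oriented reads
parse_many <- function(om, layout, adapter_max_dist = 6L, flank = 4L,
                       polyA_min = 15L, polyA_zone = 150L) {
  seg <- layout$segments
  ins <- which(seg$kind == "insert")
  n <- nrow(om)
  res <- data.frame(read_id = om$read_id, orientation = om$orientation,
                    complete = FALSE, failure_reason = NA_character_,
                    stringsAsFactors = FALSE)
  res$a5_dist <- om$a5_dist; res$a3_dist <- om$a3_dist

  fail <- function(cond, reason) {
    new <- cond & is.na(res$failure_reason)
    res$failure_reason[new] <<- reason
  }
  fail(om$orientation == "*", "undetermined_orientation")
  fail(om$a5_dist > adapter_max_dist, "missing_adapter_5p")
  fail(om$a3_dist > adapter_max_dist, "missing_adapter_3p")
  # anchors must be ordered with room for the inter-anchor segments
  min_room <- sum(seg$length[-c(1L, ins, nrow(seg))], na.rm = TRUE)
  fail(om$a3_start <= om$a5_end + min_room %/% 2L, "segments_out_of_order")

  w <- nchar(om$oriented)
  clip <- function(x) pmax(1L, pmin(x, w))
  extract <- function(start, len, fl) {
    s <- clip(start - fl); e <- clip(start + len - 1L + fl)
    substr(om$oriented, s, e)
  }

  # segments between the 5' anchor and the insert, offsets from anchor end
  ofs <- 0L
  for (i in seq(2L, ins - 1L)) {
    len <- seg$length[i]
    start <- om$a5_end + 1L + ofs
    if (seg$kind[i] %in% c("pcr_barcode", "rt_barcode", "umi")) {
      res[[paste0(seg$kind[i], "_obs")]] <- extract(start, len, 0L)
      res[[paste0(seg$kind[i], "_window")]] <- extract(start, len, flank)
    }
    ofs <- ofs + len
  }
  # segments between the insert and the 3' anchor, offsets from anchor start
  ofs <- 0L
  for (i in seq(nrow(seg) - 1L, ins + 1L)) {
    len <- seg$length[i]
    start <- om$a3_start - ofs - len
    if (seg$kind[i] %in% c("pcr_barcode", "rt_barcode", "umi")) {
      res[[paste0(seg$kind[i], "_obs")]] <- extract(start, len, 0L)
      res[[paste0(seg$kind[i], "_window")]] <- extract(start, len, flank)
    } else if (seg$kind[i] == "polyA") {
      zs <- clip(pmax(om$a5_end + 1L, start + len - polyA_zone))
      ze <- clip(start + len + 10L)
      found <- polyA_in(substr(om$oriented, zs, ze), polyA_min)
      fail(!found, "missing_polyA")
    }
    ofs <- ofs + len
  }
  res$complete <- is.na(res$failure_reason)
  res
}

#' Parse the library structure of an oriented read
#'
#' Anchors the terminal adapters by semi-global alignment, derives the
#' barcode and UMI windows from the anchor coordinates (with a flank
#' allowance for indel drift), and checks the polyA tail (a run of at
#' least `polyA_min` A bases with at most one interruption within the
#' expected zone). A read is complete iff both anchors align within
#' tolerance, in order, and the polyA is found.
#'
#' @param read A single oriented read (see [orient_read()]).
#' @param layout A [read_layout].
#' @param adapter_max_dist Maximum adapter edit distance.
#' @param flank Flanking bases added to anchor-derived barcode windows.
#' @param polyA_min,polyA_zone PolyA detection parameters (bases).
#' @return List with `complete`, `failure_reason` (one of
#'   `missing_adapter_5p`, `missing_adapter_3p`, `missing_polyA`,
#'   `segments_out_of_order`, `undetermined_orientation`, or NA), adapter
#'   distances, and the extracted `*_obs` / `*_window` sequences.
#' @export
parse_structure <- function(read, layout, adapter_max_dist = 6L, flank = 4L,
                            polyA_min = 15L, polyA_zone = 150L) {
  stopifnot(length(read) == 1L)
  lay <- layout
  lay$strandable <- FALSE  # caller already oriented the read
  om <- orient_many(setNames(read, "r"), lay, adapter_max_dist)
  om$orientation <- "+"
  as.list(parse_many(om, layout, adapter_max_dist, flank, polyA_min,
                     polyA_zone))
}

#' Orient and structure-parse many reads
#'
#' Vectorized [orient_read()] + [parse_structure()]: orients every read,
#' anchors the adapters and extracts the barcode/UMI observations and
#' windows. Mostly useful for auditing extraction accuracy against a
#' simulator truth table; [demultiplex()] wraps this with barcode
#' assignment.
#'
#' @inheritParams demultiplex
#' @return Data frame with one row per read: `read_id`, `orientation`,
#'   `complete`, `failure_reason`, adapter distances, and the extracted
#'   `*_obs` / `*_window` sequences for each barcode/UMI segment.
#' @export
parse_reads <- function(reads, layout, adapter_max_dist = 6L, flank = 4L,
                        polyA_min = 15L, polyA_zone = 150L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%07d", seq_along(reads))
  om <- orient_many(reads, layout, adapter_max_dist)
  parse_many(om, layout, adapter_max_dist, flank, polyA_min, polyA_zone)
}

#' Assign an observed barcode to a whitelist entry
#'
#' Computes the edit distance from the observed sequence to every whitelist
#' entry and returns the argmin iff its distance is at most `max_dist` and
#' the runner-up is at least `min_margin` further; ties are ambiguous.
#' With `semiglobal = TRUE` each whitelist barcode is aligned as an infix
#' of the observed window (used on anchor-derived windows that carry
#' flanking bases).
#'
#' @param observed Character vector of observed sequences/windows.
#' @param whitelist A [barcode_whitelist].
#' @param max_dist Maximum accepted distance.
#' @param min_margin Required margin to the second-best hit.
#' @param semiglobal Align barcodes as infixes of the observation.
#' @return Data frame with `barcode_id`, `distance`, `status`
#'   (assigned/ambiguous/too_distant).
#' @export
assign_barcode <- function(observed, whitelist, max_dist = 5L,
                           min_margin = 2L, semiglobal = FALSE) {
  stopifnot(inherits(whitelist, "barcode_whitelist"))
  hit <- .best_barcode_cpp(unname(whitelist$barcodes),
                           as.character(observed), semiglobal)
  id <- names(whitelist$barcodes)[hit$best_idx]
  status <- rep("assigned", length(observed))
  status[!is.na(hit$second_dist) &
           (hit$second_dist - hit$best_dist) < min_margin] <- "ambiguous"
  status[hit$best_dist > max_dist] <- "too_distant"
  data.frame(
    barcode_id = ifelse(status == "assigned", id, NA_character_),
    distance = hit$best_dist, status = status, stringsAsFactors = FALSE)
}

#' Demultiplex a library of noisy long reads
#'
#' Full pipeline per read: orient, parse the library structure, then
#' assign the RT and PCR barcodes by bounded edit distance. Every read
#' lands in exactly one status bucket: `assigned` (both barcodes resolved),
#' `ambiguous`, `too_distant`, `incomplete` (failed structure parsing or
#' orientation), or `malformed` (empty / non-nucleotide record, counted and
#' skipped with a warning).
#'
#' @param reads FASTQ path or named character vector of read sequences.
#' @param layout A [read_layout].
#' @param rt_whitelist,pcr_whitelist [barcode_whitelist] objects.
#' @param max_dist,min_margin Barcode acceptance parameters (see
#'   [assign_barcode()]); defaults leave headroom below half the whitelist
#'   minimum pairwise distance.
#' @param adapter_max_dist,flank,polyA_min,polyA_zone Structure-parsing
#'   parameters (see [parse_structure()]).
#' @return List with `assignments` (per-read data frame: read_id,
#'   orientation, status, failure_reason, rt/pcr barcode ids and distances,
#'   umi, cell_id) and `stats` (input count, per-status counts and
#'   fractions, observed barcode-distance tables).
#' @export
demultiplex <- function(reads, layout, rt_whitelist, pcr_whitelist,
                        max_dist = 5L, min_margin = 2L,
                        adapter_max_dist = 6L, flank = 4L, polyA_min = 15L,
                        polyA_zone = 150L) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- sprintf("read%07d", seq_along(reads))
  n_input <- length(reads)
  ok <- nchar(reads) > 0L & grepl("^[ACGTN]*$", reads)
  if (any(!ok))
    warning(sum(!ok), " malformed read record(s) skipped")
  n_malformed <- sum(!ok)
  reads <- reads[ok]

  empty <- data.frame(
    read_id = character(0), orientation = character(0),
    status = character(0), failure_reason = character(0),
    rt_barcode_id = character(0), pcr_barcode_id = character(0),
    rt_distance = integer(0), pcr_distance = integer(0),
    umi = character(0), cell_id = character(0), stringsAsFactors = FALSE)
  if (length(reads) == 0L) {
    stats <- list(n_input = n_input, n_malformed = n_malformed,
                  counts = c(assigned = 0, ambiguous = 0, too_distant = 0,
                             incomplete = 0),
                  fractions = c(assigned = 0, ambiguous = 0,
                                too_distant = 0, incomplete = 0))
    return(list(assignments = empty, stats = stats))
  }

  om <- orient_many(reads, layout, adapter_max_dist)
  pr <- parse_many(om, layout, adapter_max_dist, flank, polyA_min,
                   polyA_zone)
  out <- data.frame(
    read_id = pr$read_id, orientation = pr$orientation,
    status = ifelse(pr$complete, NA_character_, "incomplete"),
    failure_reason = pr$failure_reason,
    rt_barcode_id = NA_character_, pcr_barcode_id = NA_character_,
    rt_distance = NA_integer_, pcr_distance = NA_integer_,
    umi = NA_character_, cell_id = NA_character_, stringsAsFactors = FALSE)

  idx <- which(pr$complete)
  if (length(idx)) {
    rt <- assign_barcode(pr$rt_barcode_window[idx], rt_whitelist, max_dist,
                         min_margin, semiglobal = TRUE)
    pcr <- assign_barcode(pr$pcr_barcode_window[idx], pcr_whitelist,
                          max_dist, min_margin, semiglobal = TRUE)
    out$rt_barcode_id[idx] <- rt$barcode_id
    out$pcr_barcode_id[idx] <- pcr$barcode_id
    out$rt_distance[idx] <- rt$distance
    out$pcr_distance[idx] <- pcr$distance
    out$umi[idx] <- pr$umi_obs[idx]
    status <- rep("assigned", length(idx))
    status[rt$status == "ambiguous" | pcr$status == "ambiguous"] <- "ambiguous"
    status[rt$status == "too_distant" | pcr$status == "too_distant"] <-
      "too_distant"
    out$status[idx] <- status
    good <- idx[status == "assigned"]
    out$cell_id[good] <- paste(out$rt_barcode_id[good],
                               out$pcr_barcode_id[good], sep = "_")
  }

  lev <- c("assigned", "ambiguous", "too_distant", "incomplete")
  counts <- table(factor(out$status, levels = lev))
  stats <- list(
    n_input = n_input, n_malformed = n_malformed,
    counts = as.vector(counts) |> setNames(lev),
    fractions = (as.vector(counts) / max(1L, n_input)) |> setNames(lev),
    rt_distance_table = table(out$rt_distance[out$status == "assigned"]),
    pcr_distance_table = table(out$pcr_distance[out$status == "assigned"]))
  list(assignments = out, stats = stats)
}

#' Write demultiplexing results
#'
#' Writes an annotated FASTQ of assigned reads (header comment
#' `CB:<cell> UB:<umi>`), a reject FASTQ for ambiguous/too-distant/
#' incomplete reads, and the statistics as JSON.
#'
#' @param reads Named character vector of the original reads.
#' @param demux Result of [demultiplex()].
#' @param dir Output directory.
#' @export
write_demux <- function(reads, demux, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  a <- demux$assignments
  keep <- a$status == "assigned"
  kept <- reads[a$read_id[keep]]
  names(kept) <- sprintf("%s CB:%s UB:%s", a$read_id[keep], a$cell_id[keep],
                         a$umi[keep])
  write_fastq(kept, file.path(dir, "assigned.fastq.gz"))
  rej <- reads[a$read_id[!keep]]
  if (length(rej))
    write_fastq(rej, file.path(dir, "rejected.fastq.gz"))
  stats <- demux$stats
  stats$rt_distance_table <- as.list(stats$rt_distance_table)
  stats$pcr_distance_table <- as.list(stats$pcr_distance_table)
  jsonlite::write_json(stats, file.path(dir, "demux_stats.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
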