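# Tag extraction: demultiplexing of barcoded di-tag reads, PCR-duplicate
# collapse, poly-A homopolymer filtering, and di-tag splitting into single
# canonical tags.

#' Demultiplex barcoded reads into libraries
#'
#' Assigns each read to the unique library whose barcode is an exact prefix
#' of its sequence and strips the barcode. Reads matching no barcode are
#' dropped and counted. Barcodes must be prefix-free so the assignment is
#' unambiguous; no barcode error correction is attempted.
#'
#' @param reads data.frame with `read_id`, `sequence` (or named character
#'   vector of sequences).
#' @param barcodes named character vector, library -> barcode.
#' @return list with `libraries` (named list of per-library read
#'   data.frames, barcode stripped) and `n_demux_fail`.
#' @export
demultiplex <- function(reads, barcodes) {
  reads <- as_reads_df(reads)
  check_dna(barcodes, "barcodes")
  if (anyDuplicated(barcodes) || !is_prefix_free(barcodes))
    stop("barcodes must be pairwise distinct and prefix-free", call. = FALSE)
  libs <- vector("list", length(barcodes))
  names(libs) <- names(barcodes)
  assigned <- rep(FALSE, nrow(reads))
  for (lib in names(barcodes)) {
    bc <- barcodes[[lib]]
    hit <- startsWith(reads$sequence, bc)
    sub <- reads[hit, , drop = FALSE]
    sub$sequence <- substring(sub$sequence, nchar(bc) + 1L)
    rownames(sub) <- NULL
    libs[[lib]] <- sub
    assigned <- assigned | hit
  }
  list(libraries = libs, n_demux_fail = sum(!assigned))
}

#' Collapse PCR-duplicate di-tags
#'
#' Identical di-tag inserts within one library are presumed PCR duplicates:
#' the independent ligation of the same two tags twice is improbable, which
#' is the di-tag design's device for discriminating amplification copies.
#' Exactly one representative (the first occurrence) is retained.
#'
#' @param reads per-library data.frame with `read_id`, `sequence` (barcode
#'   already stripped).
#' @return list with `reads` (deduplicated, first-occurrence order) and
#'   `n_removed`.
#' @export
collapse_pcr_duplicates <- function(reads) {
  reads <- as_reads_df(reads)
  dup <- duplicated(reads$sequence)
  out <- reads[!dup, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, n_removed = sum(dup))
}

#' Remove low-complexity poly-A reads
#'
#' Drops any read whose insert contains a run of `min_run` or more
#' consecutive adenines, at any position.
#'
#' @param reads per-library data.frame with `read_id`, `sequence`.
#' @param min_run minimum adenine run length that disqualifies a read.
#' @return list with `reads` (surviving) and `n_removed`.
#' @export
filter_polyA <- function(reads, min_run = 12) {
  reads <- as_reads_df(reads)
  if (min_run < 1) stop("min_run must be >= 1", call. = FALSE)
  hit <- grepl(strrep("A", min_run), reads$sequence, fixed = TRUE)
  out <- reads[!hit, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, n_removed = sum(hit))
}

#' Split di-tag inserts into single tags
#'
#' An insert of length `2 * tag_length` joins two canonical tags
#' head-to-head: tag1 is the first half as-is, tag2 is the reverse
#' complement of the second half. Tags are emitted in read order, tag1
#' before tag2. Reads of any other insert length are skipped and counted,
#' not fatal.
#'
#' @param reads per-library data.frame with `read_id`, `sequence`.
#' @param tag_length canonical tag length in bp.
#' @return list with `tags` (character vector, 2 per well-formed read) and
#'   `n_length_skipped`.
#' @export
split_ditags <- function(reads, tag_length = 26) {
  reads <- as_reads_df(reads)
  ok <- nchar(reads$sequence) == 2L * tag_length
  n_skip <- sum(!ok)
  if (n_skip > 0)
    warning(sprintf("%d read(s) with insert length != %d skipped",
                    n_skip, 2L * tag_length), call. = FALSE)
  s <- reads$sequence[ok]
  if (length(s) == 0L) return(list(tags = character(0),
                                   n_length_skipped = n_skip))
  tag1 <- substr(s, 1L, tag_length)
  tag2 <- revcomp(substr(s, tag_length + 1L, 2L * tag_length))
  list(tags = as.vector(rbind(tag1, tag2)), n_length_skipped = n_skip)
}

#' Run the full extraction stage on a bulk of barcoded reads
#'
#' Demultiplexes, collapses PCR duplicates within each library, removes
#' poly-A reads, splits di-tags, and returns the per-library clean tag
#' lists together with a balanced filter-statistics ledger.
#'
#' @param reads bulk reads: data.frame with `read_id`, `sequence`.
#' @param barcodes named character vector, library -> barcode.
#' @param tag_length canonical tag length in bp.
#' @param min_run poly-A filter threshold (consecutive adenines).
#' @return list with `tags` (named list of per-library tag vectors),
#'   `stats` (data.frame, one row per library plus a `total` row; see
#'   [filter_stats_balanced()]), and `reads` (surviving per-library reads).
#' @export
extract_tags <- function(reads, barcodes, tag_length = 26, min_run = 12) {
  dm <- demultiplex(reads, barcodes)
  tags <- list()
  surviving <- list()
  rows <- list()
  for (lib in names(dm$libraries)) {
    r0 <- dm$libraries[[lib]]
    cd <- collapse_pcr_duplicates(r0)
    pa <- filter_polyA(cd$reads, min_run = min_run)
    sp <- split_ditags(pa$reads, tag_length = tag_length)
    tags[[lib]] <- sp$tags
    surviving[[lib]] <- pa$reads
    rows[[lib]] <- data.frame(
      library = lib,
      n_input = nrow(r0),
      n_demux_fail = 0L,
      n_pcr_duplicates_removed = cd$n_removed,
      n_polyA_removed = pa$n_removed,
      n_length_skipped = sp$n_length_skipped,
      n_tags_out = length(sp$tags),
      stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, rows)
  total <- data.frame(
    library = "total",
    n_input = nrow(as_reads_df(reads)),
    n_demux_fail = dm$n_demux_fail,
    n_pcr_duplicates_removed = sum(stats$n_pcr_duplicates_removed),
    n_polyA_removed = sum(stats$n_polyA_removed),
    n_length_skipped = sum(stats$n_length_skipped),
    n_tags_out = sum(stats$n_tags_out),
    stringsAsFactors = FALSE)
  stats <- rbind(stats, total)
  rownames(stats) <- NULL
  stopifnot(filter_stats_balanced(stats))
  list(tags = tags, stats = stats, reads = surviving)
}

#' Check that a filter-statistics ledger balances
#'
#' Every row must satisfy
#' `n_tags_out = 2 * (n_input - n_demux_fail - n_pcr_duplicates_removed -
#' n_polyA_removed - n_length_skipped)` with all counts non-negative.
#'
#' @param stats filter-statistics data.frame from [extract_tags()].
#' @return logical scalar.
#' @export
filter_stats_balanced <- function(stats) {
  counts <- c("n_input", "n_demux_fail", "n_pcr_duplicates_removed",
              "n_polyA_removed", "n_tags_out")
  if (!all(counts %in% names(stats))) return(FALSE)
  skipped <- if ("n_length_skipped" %in% names(stats))
    stats$n_length_skipped else 0L
  all(unlist(stats[counts]) >= 0) &&
    all(stats$n_tags_out ==
          2L * (stats$n_input - stats$n_demux_fail -
                stats$n_pcr_duplicates_removed - stats$n_polyA_removed -
                skipped))
}
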