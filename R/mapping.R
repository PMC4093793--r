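# Tag mapping: anchored-tag index over a transcript set, unique-locus
# assignment, count matrix assembly and mapping-rate reporting.

#' Canonical tag of each transcript
#'
#' The canonical tag is the `tag_length`-base sequence starting at the
#' 3'-most anchor occurrence that leaves room for a full tag, mirroring the
#' NlaIII/EcoP15I excision geometry (the tag begins with the anchor). `NA`
#' for transcripts with no usable anchor.
#'
#' @param transcriptome data.frame with `gene_id`, `sequence`.
#' @param tag_length tag length in bp (anchor included).
#' @param anchor anchoring-enzyme site (default NlaIII, CATG).
#' @return named character vector, gene -> canonical tag (NA if none).
#' @export
canonical_tags <- function(transcriptome, tag_length = 26, anchor = "CATG") {
  seqs <- transcriptome$sequence
  out <- rep(NA_character_, length(seqs))
  hits <- gregexpr(anchor, seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    p <- as.integer(hits[[i]])
    if (p[1] == -1L) next
    p <- p[p + tag_length - 1L <= nchar(seqs[i])]
    if (length(p) == 0L) next
    out[i] <- substr(seqs[i], max(p), max(p) + tag_length - 1L)
  }
  stats::setNames(out, transcriptome$gene_id)
}

#' Build an anchored-tag index from a transcript set
#'
#' One canonical tag per gene is inserted, keyed by tag sequence; genes
#' whose transcripts lack an anchor are absent. Several genes may share a
#' key (ambiguous tags, discarded at assignment under the unique-locus
#' rule).
#'
#' @inheritParams canonical_tags
#' @return object of class `tag_index`: list with `tags` (named list,
#'   tag -> character vector of gene ids), `tag_length`, `anchor`.
#' @export
build_tag_index <- function(transcriptome, tag_length = 26, anchor = "CATG") {
  ct <- canonical_tags(transcriptome, tag_length, anchor)
  ct <- ct[!is.na(ct)]
  idx <- split(names(ct), unname(ct))
  structure(list(tags = idx, tag_length = as.integer(tag_length),
                 anchor = anchor),
            class = "tag_index")
}

#' Genes covered by a tag index
#' @param index a [build_tag_index()] result.
#' @return sorted character vector of gene ids present in the index.
#' @export
index_genes <- function(index) {
  sort(unique(unlist(index$tags, use.names = FALSE)))
}

#' Assign clean tags to gene loci
#'
#' A tag matching exactly one gene increments that gene's count; a tag
#' matching two or more genes is counted as multi-mapping and excluded from
#' further analysis; a tag absent from the index is counted as unmapped.
#' Matching is exact (no mismatches): at 26 bp against transcript-derived
#' canonical tags, exact lookup is the reproducible equivalent of
#' default-stringency short-read alignment. Tags of the wrong length are
#' rejected per tag with a counter, not fatally.
#'
#' @param tags character vector of tag sequences.
#' @param index a [build_tag_index()] result.
#' @return list with `counts` (named integer over all index genes),
#'   `stats` (one-row data.frame: `n_tags_in`, `n_unique`, `n_multi`,
#'   `n_unmapped`, `n_bad_length`), and `library_total` (= `n_unique`).
#' @export
assign_tags <- function(tags, index) {
  stopifnot(inherits(index, "tag_index"))
  genes <- index_genes(index)
  counts <- stats::setNames(integer(length(genes)), genes)
  n_in <- length(tags)
  bad <- nchar(tags) != index$tag_length
  n_bad <- sum(bad)
  tags <- tags[!bad]
  keys <- names(index$tags)
  hit <- match(tags, keys)
  n_unmapped <- sum(is.na(hit))
  hit <- hit[!is.na(hit)]
  n_genes_per_key <- lengths(index$tags)
  multi <- n_genes_per_key[hit] > 1L
  n_multi <- sum(multi)
  uni <- hit[!multi]
  if (length(uni)) {
    g <- unlist(index$tags[uni], use.names = FALSE)
    tab <- table(g)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  n_unique <- length(uni)
  stopifnot(n_unique + n_multi + n_unmapped + n_bad == n_in)
  list(counts = counts,
       stats = data.frame(n_tags_in = n_in, n_unique = n_unique,
                          n_multi = n_multi, n_unmapped = n_unmapped,
                          n_bad_length = n_bad),
       library_total = n_unique)
}

#' Assemble a tag count matrix from per-library assignments
#'
#' @param assignments named list of [assign_tags()] results, one per
#'   library.
#' @return object of class `tag_count_matrix`: list with `counts` (gene x
#'   library integer matrix), `library_totals` (named, = column sums =
#'   unambiguously assigned tags), and `mapping_stats` (data.frame, one row
#'   per library).
#' @export
tag_count_matrix <- function(assignments) {
  stopifnot(length(assignments) >= 1, !is.null(names(assignments)))
  genes <- sort(unique(unlist(lapply(assignments, function(a) names(a$counts)))))
  m <- sapply(assignments, function(a) {
    v <- stats::setNames(integer(length(genes)), genes)
    v[names(a$counts)] <- a$counts
    v
  })
  m <- matrix(as.integer(m), nrow = length(genes),
              dimnames = list(genes, names(assignments)))
  totals <- colSums(m)
  stats_df <- do.call(rbind, lapply(names(assignments), function(lib) {
    cbind(data.frame(library = lib), assignments[[lib]]$stats)
  }))
  stopifnot(all(totals == vapply(assignments, `[[`, 0, "library_total")))
  structure(list(counts = m, library_totals = totals,
                 mapping_stats = stats_df),
            class = "tag_count_matrix")
}

#' Mapping-rate report
#'
#' Computes per-library unique/multi/unmapped fractions. The headline
#' unique percentage is reported both truncated and rounded to one decimal
#' place: tag-profiling reports conventionally truncate (17,909 of 25,160
#' prints as 71.1), and both figures are emitted so either convention can
#' be compared.
#'
#' @param stats data.frame with columns `n_tags_in`, `n_unique`,
#'   `n_multi`, `n_unmapped` (one row per library; a `library` column is
#'   carried through if present).
#' @return data.frame with the input counts plus `pct_unique_trunc`,
#'   `pct_unique_round`, `pct_multi`, `pct_unmapped` (percentages, 1 d.p.).
#' @export
mapping_report <- function(stats) {
  need <- c("n_tags_in", "n_unique", "n_multi", "n_unmapped")
  stopifnot(all(need %in% names(stats)))
  if (any(stats$n_tags_in == 0))
    stop("empty library: n_tags_in is zero", call. = FALSE)
  trunc1 <- function(x) floor(x * 10) / 10
  pct <- 100 * stats$n_unique / stats$n_tags_in
  out <- stats
  out$pct_unique_trunc <- trunc1(pct)
  out$pct_unique_round <- round(pct, 1)
  out$pct_multi <- round(100 * stats$n_multi / stats$n_tags_in, 1)
  out$pct_unmapped <- round(100 * stats$n_unmapped / stats$n_tags_in, 1)
  out
}

#' Relative size difference between two libraries
#'
#' Percentage difference of library depths relative to the reference
#' (first) library; used to check that two libraries are comparably sized
#' (e.g. within a +-5% band).
#'
#' @param n_ref reference library depth.
#' @param n_other other library depth.
#' @return percentage, `100 * |n_other - n_ref| / n_ref`.
#' @export
library_balance <- function(n_ref, n_other) {
  stopifnot(n_ref > 0)
  100 * abs(n_other - n_ref) / n_ref
}
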