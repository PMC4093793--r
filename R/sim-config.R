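#' Simulation configuration for synthetic di-tag libraries
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study conditions of a two-tissue (nodule-free root vs. mature
#' root nodule) deepSuperSAGE experiment: two libraries of 25,160 and 26,380
#' duplicate- and homopolymer-filtered di-tag reads, roughly 1,800 expressed
#' gene loci, a differential-expression ladder that includes all-or-nothing
#' genes (zero counts in one tissue), PCR-duplicate di-tags, poly-A
#' low-complexity reads, and tag sequences shared by more than one locus.
#'
#' @param n_genes number of gene loci in the synthetic transcriptome.
#' @param depth_per_library target number of *filtered* di-tag reads per
#'   library; a single integer or a vector named by tissue. Each read carries
#'   two tags.
#' @param de_fraction fraction of genes that are differentially expressed.
#' @param fold_ladder positive fold changes assigned to DE genes, cycled in
#'   order; `Inf` encodes all-or-nothing genes (abundance exactly 0 in one
#'   tissue) and exercises the 0.05 zero-adjustment downstream.
#' @param pcr_duplicate_rate fraction of raw reads that are exact PCR copies
#'   of earlier reads.
#' @param polyA_read_rate fraction of raw reads carrying a run of >= 12
#'   adenines (low-complexity artifact class).
#' @param multimap_gene_pairs number of gene pairs engineered to share an
#'   identical canonical tag (these tags are excluded by the unique-mapping
#'   rule).
#' @param tag_length canonical tag length in bp, anchor included.
#' @param anchor anchoring-enzyme recognition site at the 5' end of every
#'   canonical tag (NlaIII: CATG).
#' @param barcodes named character vector, tissue -> barcode; must be
#'   pairwise distinct and prefix-free.
#' @param no_anchor_fraction fraction of transcripts carrying no anchor site
#'   at all (such genes can never yield a tag).
#' @param novel_tag_rate per-tag probability that a drawn tag comes from an
#'   unannotated locus, i.e. a valid-looking tag absent from the transcript
#'   index (ends up in the unmapped class).
#' @param transcript_length_range min/max synthetic transcript length (bp).
#' @param abundance_sdlog log-normal shape parameter of the baseline
#'   transcript-abundance distribution.
#' @param seed integer seed; all generator randomness derives from it.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1800,
                       depth_per_library = c(root = 25160, nodule = 26380),
                       de_fraction = 0.1,
                       fold_ladder = c(2, 4, 8, 64, 128, 256, Inf),
                       pcr_duplicate_rate = 0.10,
                       polyA_read_rate = 0.02,
                       multimap_gene_pairs = 30,
                       tag_length = 26,
                       anchor = "CATG",
                       barcodes = c(root = "ACAC", nodule = "TGTG"),
                       no_anchor_fraction = 0.02,
                       novel_tag_rate = 0.20,
                       transcript_length_range = c(400, 1500),
                       abundance_sdlog = 1.2,
                       seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              depth_per_library = depth_per_library,
              de_fraction = de_fraction,
              fold_ladder = fold_ladder,
              pcr_duplicate_rate = pcr_duplicate_rate,
              polyA_read_rate = polyA_read_rate,
              multimap_gene_pairs = as.integer(multimap_gene_pairs),
              tag_length = as.integer(tag_length),
              anchor = toupper(anchor),
              barcodes = barcodes,
              no_anchor_fraction = no_anchor_fraction,
              novel_tag_rate = novel_tag_rate,
              transcript_length_range = as.integer(transcript_length_range),
              abundance_sdlog = abundance_sdlog,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stop_cfg <- function(msg) stop(msg, call. = FALSE)
  if (cfg$n_genes < 2) stop_cfg("n_genes must be >= 2")
  check_dna(cfg$anchor, "anchor")
  if (cfg$tag_length <= nchar(cfg$anchor))
    stop_cfg("tag_length must exceed the anchor length")
  bcs <- cfg$barcodes
  if (is.null(names(bcs)) || any(names(bcs) == ""))
    stop_cfg("barcodes must be named by tissue")
  check_dna(bcs, "barcodes")
  if (anyDuplicated(bcs)) stop_cfg("barcodes must be pairwise distinct")
  if (!is_prefix_free(bcs))
    stop_cfg("barcodes must be prefix-free (no barcode a prefix of another)")
  for (r in c("de_fraction", "pcr_duplicate_rate", "polyA_read_rate",
              "no_anchor_fraction", "novel_tag_rate")) {
    v <- cfg[[r]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_cfg(sprintf("%s must lie in [0, 1]", r))
  }
  if (cfg$pcr_duplicate_rate + cfg$polyA_read_rate >= 1)
    stop_cfg("pcr_duplicate_rate + polyA_read_rate must be < 1")
  if (cfg$de_fraction > 0) {
    if (length(cfg$fold_ladder) == 0)
      stop_cfg("fold_ladder must be non-empty when de_fraction > 0")
    if (any(cfg$fold_ladder <= 0))
      stop_cfg("fold_ladder entries must be positive")
  }
  d <- cfg$depth_per_library
  if (any(d < 1)) stop_cfg("depth_per_library must be positive")
  if (diff(cfg$transcript_length_range) < 0 ||
      cfg$transcript_length_range[1] < cfg$tag_length)
    stop_cfg("transcript_length_range must be increasing and >= tag_length")
  invisible(cfg)
}

is_prefix_free <- function(x) {
  if (length(x) < 2) return(TRUE)
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (i != j && startsWith(x[[i]], x[[j]])) return(FALSE)
  }
  TRUE
}

# Depth for one tissue from a scalar or tissue-named depth setting.
depth_for_tissue <- function(cfg, tissue) {
  d <- cfg$depth_per_library
  if (length(d) == 1L && is.null(names(d))) return(as.integer(d))
  if (!tissue %in% names(d))
    stop(sprintf("no depth_per_library entry for tissue '%s'", tissue),
         call. = FALSE)
  as.integer(d[[tissue]])
}
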