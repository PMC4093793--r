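# End-to-end pipeline: simulate -> extract -> map -> DE -> qPCR -> report,
# with a flat validated configuration and deterministic, file-backed stage
# outputs.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    sim = list(),                     # overrides for sim_config()
    filter = list(min_run = 12),
    mapping = list(),                 # tag_length/anchor default to sim's
    de = list(alpha = 0.01, pseudo = 0.05,
              thresholds = c(2, 4, 8, 64, 128, 256),
              denominator = "assigned"),
    qpcr = list(n_targets_up = 10, n_targets_down = 10, n_replicates = 5,
                noise_sd = 0.4, sample_effect_sd = 0.5,
                ref_instability_sd = 0.05, candidate_instability_sd = 0.35,
                cap_log2 = 14, genorm_threshold = 0.5, linkage = "average")
  )
}

#' Build a validated pipeline configuration
#'
#' Flat configuration with one block per stage. Unknown keys (at the top
#' level or inside a block) are rejected rather than silently ignored.
#'
#' @param ... named blocks/values overriding the defaults: `seed`, `sim`
#'   (passed to [sim_config()]), `filter` (`min_run`), `mapping`
#'   (`tag_length`, `anchor`; default to the sim block's values), `de`
#'   (`alpha`, `pseudo`, `thresholds`, `denominator`), `qpcr`
#'   (target/replicate counts, noise levels, geNorm threshold, linkage).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  cfg <- defs
  for (blk in names(user)) {
    if (is.list(defs[[blk]]) && blk != "sim") {
      bad <- setdiff(names(user[[blk]]), names(defs[[blk]]))
      if (length(bad))
        stop(sprintf("unknown key(s) in '%s' block: %s", blk,
                     paste(bad, collapse = ", ")), call. = FALSE)
      cfg[[blk]][names(user[[blk]])] <- user[[blk]]
    } else {
      cfg[[blk]] <- user[[blk]]
    }
  }
  if (is.null(cfg$sim$seed)) cfg$sim$seed <- cfg$seed
  bad_sim <- setdiff(names(cfg$sim), names(formals(sim_config)))
  if (length(bad_sim))
    stop(sprintf("unknown key(s) in 'sim' block: %s",
                 paste(bad_sim, collapse = ", ")), call. = FALSE)
  # validate the sim block eagerly so configuration errors surface before
  # any stage runs
  sim_cfg <- do.call(sim_config, cfg$sim)
  if (is.null(cfg$mapping$tag_length)) cfg$mapping$tag_length <- sim_cfg$tag_length
  if (is.null(cfg$mapping$anchor)) cfg$mapping$anchor <- sim_cfg$anchor
  cfg$sim_config <- sim_cfg
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file with the blocks accepted by [pipeline_config()].
#' @return object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline into an output directory
#'
#' Simulates a two-tissue di-tag experiment, extracts and maps tags, calls
#' differential expression, simulates and analyzes the qRT-PCR validation,
#' and writes every stage output plus a machine-readable `summary.json`
#' and a provenance record (configuration hash, seed, package version).
#' Rerunning with the same configuration reproduces the outputs
#' byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the in-memory stage objects
#'   (`transcriptome`, `truth`, `libraries`, `extraction`, `count_matrix`,
#'   `de`, `threshold_table`, `overlap`, `qpcr`) and `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config$sim_config

  # --- simulate ------------------------------------------------------------
  tx <- generate_transcriptome(cfg)
  truth <- generate_truth(cfg)
  tissues <- names(cfg$barcodes)
  libs <- lapply(tissues, function(t) simulate_library(tx, truth, t, cfg))
  names(libs) <- tissues
  bulk <- do.call(rbind, lapply(libs, `[[`, "reads"))
  bulk <- with_seed(config$seed + 5L, bulk[sample(nrow(bulk)), , drop = FALSE])
  rownames(bulk) <- NULL
  write_transcriptome_fasta(tx, file.path(out_dir, "transcriptome.fasta"))
  write_reads_fastq(bulk, file.path(out_dir, "reads.fastq"))
  write_tsv(truth, file.path(out_dir, "truth.tsv"))

  # --- extract -------------------------------------------------------------
  ex <- extract_tags(bulk, cfg$barcodes,
                     tag_length = config$mapping$tag_length,
                     min_run = config$filter$min_run)
  write_tsv(ex$stats, file.path(out_dir, "filter_stats.tsv"))
  for (lib in tissues)
    writeLines(ex$tags[[lib]], file.path(out_dir, sprintf("tags_%s.txt", lib)))

  # --- map -----------------------------------------------------------------
  idx <- build_tag_index(tx, tag_length = config$mapping$tag_length,
                         anchor = config$mapping$anchor)
  asn <- lapply(tissues, function(lib) assign_tags(ex$tags[[lib]], idx))
  names(asn) <- tissues
  tcm <- tag_count_matrix(asn)
  mrep <- mapping_report(tcm$mapping_stats)
  write_tsv(data.frame(gene_id = rownames(tcm$counts), tcm$counts,
                       check.names = FALSE),
            file.path(out_dir, "counts.tsv"))
  write_tsv(mrep, file.path(out_dir, "mapping_report.tsv"))

  # --- differential expression --------------------------------------------
  det <- de_test(tcm, pseudo = config$de$pseudo,
                 denominator = config$de$denominator)
  tt <- build_threshold_table(det, alpha = config$de$alpha,
                              thresholds = config$de$thresholds)
  ov <- overlap_summary(tcm)
  write_tsv(det, file.path(out_dir, "de_results.tsv"))
  write_tsv(tt, file.path(out_dir, "threshold_table.tsv"))
  write_tsv(as.data.frame(ov), file.path(out_dir, "overlap.tsv"))

  # --- qPCR validation -----------------------------------------------------
  qp <- run_qpcr_validation(det, truth, config, out_dir)

  # --- summary + provenance ------------------------------------------------
  sig <- det$p_value < config$de$alpha
  summary <- list(
    seed = config$seed,
    mapping = mrep[, c("library", "n_tags_in", "n_unique", "n_multi",
                       "n_unmapped", "pct_unique_trunc", "pct_unique_round")],
    library_balance_pct = library_balance(mrep$n_tags_in[1], mrep$n_tags_in[2]),
    overlap = ov,
    n_expressed = nrow(det),
    n_significant = sum(sig),
    threshold_table = tt,
    qpcr = qp$summary)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  prov <- list(config_hash = unname(tools::md5sum(
                 write_config_for_hash(config, out_dir))),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("supersage")),
               r_version = R.version.string)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(transcriptome = tx, truth = truth, libraries = libs,
                 extraction = ex, index = idx, count_matrix = tcm,
                 mapping_report = mrep, de = det, threshold_table = tt,
                 overlap = ov, qpcr = qp, summary = summary,
                 out_dir = out_dir))
}

write_config_for_hash <- function(config, out_dir) {
  plain <- unclass(config)
  plain$sim_config <- unclass(plain$sim_config)
  path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(plain, path)
  path
}

# Select validation targets from the DE table, build their true log2
# ratios, simulate the Ct table and run the validation analytics.
run_qpcr_validation <- function(det, truth, config, out_dir) {
  qc <- config$qpcr
  sig <- det[det$p_value < config$de$alpha, , drop = FALSE]
  up <- sig[sig$direction == "up_in_B", , drop = FALSE]
  down <- sig[sig$direction == "down_in_B", , drop = FALSE]
  up <- up[order(-up$fold_change), , drop = FALSE]
  down <- down[order(down$fold_change), , drop = FALSE]
  targets <- c(head(up$gene_id, qc$n_targets_up),
               head(down$gene_id, qc$n_targets_down))
  tr <- truth[match(targets, truth$gene_id), , drop = FALSE]
  true_log2 <- ifelse(tr$de_label == "up", 1, -1) *
    pmin(log2(tr$true_fold), qc$cap_log2)
  true_log2[tr$de_label == "none"] <- 0
  names(true_log2) <- targets

  refs <- sprintf("ref_%d", 1:3)
  cands <- sprintf("cand_%d", 1:3)
  instab <- stats::setNames(c(rep(qc$ref_instability_sd, 3),
                              rep(qc$candidate_instability_sd, 3)),
                            c(refs, cands))
  panel_ratios <- stats::setNames(rep(0, 6), c(refs, cands))
  ct <- simulate_qpcr(c(true_log2, panel_ratios),
                      n_replicates = qc$n_replicates, ref_genes = refs,
                      noise_sd = qc$noise_sd, seed = config$seed + 31L,
                      gene_instability_sd = instab,
                      sample_effect_sd = qc$sample_effect_sd)
  mean_ct <- aggregate_tech_reps(ct)
  panel_mat <- ct_matrix(mean_ct[mean_ct$gene_id %in% c(refs, cands), ,
                                 drop = FALSE])
  gn <- genorm_stability(panel_mat, m_threshold = qc$genorm_threshold)
  ratios <- ddct_ratios(mean_ct, targets = targets, references = refs)
  l2m <- log2_ratio_matrix(ratios)
  cl <- cluster_ratios(l2m, linkage = qc$linkage)

  write_tsv(ct, file.path(out_dir, "ct_table.tsv"))
  write_tsv(data.frame(gene_id = names(gn$M), M = unname(gn$M),
                       exclusion_rank = unname(gn$exclusion_rank),
                       acceptable = unname(gn$acceptable)),
            file.path(out_dir, "genorm.tsv"))
  write_tsv(data.frame(pair = names(gn$V), V = unname(gn$V)),
            file.path(out_dir, "genorm_v.tsv"))
  write_tsv(ratios, file.path(out_dir, "qpcr_ratios.tsv"))
  writeLines(c(cl$row_newick, cl$col_newick),
             file.path(out_dir, "clustering.newick"))
  write_tsv(data.frame(gene_id = rownames(cl$ordered), cl$ordered,
                       check.names = FALSE),
            file.path(out_dir, "log2_ratios_ordered.tsv"))

  rec <- stats::aggregate(log2_ratio ~ gene_id, data = ratios[ratios$valid, ],
                          FUN = mean)
  recovered <- stats::setNames(rec$log2_ratio, rec$gene_id)
  err <- recovered[targets] - true_log2[targets]
  list(ct_table = ct, mean_ct = mean_ct, genorm = gn, ratios = ratios,
       log2_matrix = l2m, clustering = cl, true_log2 = true_log2,
       recovered_log2 = recovered,
       summary = list(n_targets = length(targets),
                      references = refs,
                      genorm_max_ref_M = max(gn$M[refs]),
                      mean_abs_log2_error = mean(abs(err))))
}

#' Format headline report tables from a pipeline run
#'
#' Writes a small markdown report laying out the mapping-rate table, the
#' tissue-overlap three-number summary with shared percentage, and the
#' fold-threshold table with its sum row, in the layout used by tag-based
#' profiling reports for side-by-side comparison.
#'
#' @param run result of [run_pipeline()], or a run directory containing the
#'   stage TSV files.
#' @param path output file; defaults to `report.md` in the run directory if
#'   `run` is a directory, otherwise must be given.
#' @return the report lines, invisibly.
#' @export
run_report <- function(run, path = NULL) {
  if (is.character(run)) {
    dir <- run
    need <- c("mapping_report.tsv", "overlap.tsv", "threshold_table.tsv")
    missing <- need[!file.exists(file.path(dir, need))]
    if (length(missing))
      stop(sprintf("incomplete run: missing %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    mrep <- read_tsv(file.path(dir, "mapping_report.tsv"))
    ov <- as.list(read_tsv(file.path(dir, "overlap.tsv")))
    tt <- read_tsv(file.path(dir, "threshold_table.tsv"))
    if (is.null(path)) path <- file.path(dir, "report.md")
  } else {
    mrep <- run$mapping_report
    ov <- run$overlap
    tt <- run$threshold_table
    if (is.null(path) && !is.null(run$out_dir))
      path <- file.path(run$out_dir, "report.md")
  }
  lines <- c(
    "# Tag-profiling summary", "",
    "## Mapping rates", "",
    "| library | tags in | unique | % unique (trunc) | % unique (round) |",
    "|---|---|---|---|---|",
    sprintf("| %s | %d | %d | %.1f | %.1f |", mrep$library, mrep$n_tags_in,
            mrep$n_unique, mrep$pct_unique_trunc, mrep$pct_unique_round),
    "",
    "## Tissue overlap of expressed genes", "",
    sprintf("- expressed only in %s: %d", colnames_or(mrep$library, 1),
            ov$n_only_a),
    sprintf("- expressed only in %s: %d", colnames_or(mrep$library, 2),
            ov$n_only_b),
    sprintf("- shared: %d of %d (%.1f%%)", ov$n_shared,
            ov$n_expressed_total, ov$pct_shared),
    "",
    "## Differentially expressed genes by fold threshold", "",
    paste0("| | ", paste(sprintf(">%g-fold", tt$threshold), collapse = " | "),
           " |"),
    paste0("|---|", paste(rep("---", nrow(tt)), collapse = "|"), "|"),
    paste0("| upregulated | ",
           paste(sprintf("%d (%d)", tt$n_up, tt$n_up_all), collapse = " | "),
           " |"),
    paste0("| downregulated | ",
           paste(sprintf("%d (%d)", tt$n_down, tt$n_down_all),
                 collapse = " | "), " |"),
    paste0("| sum | ",
           paste(sprintf("%d (%d)", tt$n_sum, tt$n_sum_all),
                 collapse = " | "), " |"))
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

colnames_or <- function(x, i) {
  if (length(x) >= i && nzchar(x[i])) x[i] else sprintf("library %d", i)
}
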