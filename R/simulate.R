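# Synthetic-data generator: transcriptomes, ground-truth expression,
# barcoded di-tag reads and qPCR Ct tables with known truth, so that every
# downstream stage of the pipeline can be validated without external data.

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

# Destroy every anchor occurrence (iterating, since a substitution can
# create a new occurrence spanning the edited position).
destroy_all_anchors <- function(seq, anchor) {
  repeat {
    m <- gregexpr(anchor, seq, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(seq)
    for (s in as.integer(m)) {
      cur <- substr(seq, s, s)
      substr(seq, s, s) <- sample(setdiff(DNA_BASES, cur), 1)
    }
  }
}

# Remove anchor occurrences starting strictly after `pos`, never editing
# bases at or before `protect_end` (the engineered anchor/tag region).
clean_downstream <- function(seq, anchor, pos, protect_end) {
  alen <- nchar(anchor)
  repeat {
    m <- as.integer(gregexpr(anchor, seq, fixed = TRUE)[[1]])
    m <- m[m > pos]
    if (length(m) == 0L || m[1] < 0L) return(seq)
    for (s in m) {
      i <- max(s, protect_end + 1L)
      if (i > s + alen - 1L) next  # fully inside the protected region
      cur <- substr(seq, i, i)
      substr(seq, i, i) <- sample(setdiff(DNA_BASES, cur), 1)
    }
  }
}

#' Generate a synthetic transcriptome
#'
#' Builds `n_genes` random transcripts. Each anchored transcript carries a
#' single anchor site (default CATG, the NlaIII recognition sequence)
#' positioned so that a full canonical tag of `tag_length` bases fits
#' downstream; a `no_anchor_fraction` of transcripts carry no anchor at all
#' and can therefore never yield a tag. Exactly `multimap_gene_pairs` pairs
#' of genes share an identical canonical tag, which downstream mapping must
#' discard under the unique-locus rule.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `sequence`; attribute
#'   `multimap_pairs` records the engineered shared-tag gene pairs.
#' @export
generate_transcriptome <- function(config) {
  cfg <- config
  validate_sim_config(cfg)
  n <- cfg$n_genes
  alen <- nchar(cfg$anchor)
  L <- cfg$tag_length
  n_pair_genes <- 2L * cfg$multimap_gene_pairs
  if (n_pair_genes + ceiling(cfg$no_anchor_fraction * n) > n)
    stop("n_genes too small for multimap_gene_pairs + no_anchor_fraction",
         call. = FALSE)
  with_seed(cfg$seed + 101L, {
    lens <- sample(seq(cfg$transcript_length_range[1],
                       cfg$transcript_length_range[2]), n, replace = TRUE)
    gene_id <- sprintf("gene_%05d", seq_len(n))
    seqs <- vapply(lens, random_dna, character(1))

    n_noanchor <- round(cfg$no_anchor_fraction * n)
    pool <- seq_len(n)
    noanchor <- if (n_noanchor > 0) sample(pool, n_noanchor) else integer(0)
    anchored <- setdiff(pool, noanchor)
    pair_genes <- if (n_pair_genes > 0) sample(anchored, n_pair_genes)
                  else integer(0)

    pos <- integer(n)
    for (i in anchored) {
      p <- sample.int(lens[i] - L + 1L, 1)
      substr(seqs[i], p, p + alen - 1L) <- cfg$anchor
      seqs[i] <- clean_downstream(seqs[i], cfg$anchor, p, p + alen - 1L)
      pos[i] <- p
    }
    for (i in noanchor) seqs[i] <- destroy_all_anchors(seqs[i], cfg$anchor)

    pairs <- NULL
    if (cfg$multimap_gene_pairs > 0) {
      a <- pair_genes[seq_len(cfg$multimap_gene_pairs)]
      b <- pair_genes[cfg$multimap_gene_pairs + seq_len(cfg$multimap_gene_pairs)]
      for (k in seq_along(a)) {
        tag_a <- substr(seqs[a[k]], pos[a[k]], pos[a[k]] + L - 1L)
        pb <- pos[b[k]]
        substr(seqs[b[k]], pb, pb + L - 1L) <- tag_a
        seqs[b[k]] <- clean_downstream(seqs[b[k]], cfg$anchor, pb, pb + L - 1L)
      }
      pairs <- data.frame(gene_a = gene_id[a], gene_b = gene_id[b],
                          stringsAsFactors = FALSE)
    }
    out <- data.frame(gene_id = gene_id, sequence = seqs,
                      stringsAsFactors = FALSE)
    attr(out, "multimap_pairs") <- pairs
    attr(out, "no_anchor_genes") <- gene_id[noanchor]
    out
  })
}

#' Generate ground-truth expression for two tissues
#'
#' Baseline abundances are log-normal; a `de_fraction` of genes (drawn from
#' the upper half of the abundance distribution, since tag-based DE calls
#' concern well-expressed loci) receive fold changes cycled from
#' `fold_ladder`, alternating between nodule-upregulated and
#' nodule-downregulated. An infinite fold encodes an all-or-nothing gene:
#' abundance exactly zero in one tissue. Differential expression is applied
#' by knocking the gene down in the opposite tissue (the high tissue keeps
#' the baseline abundance), and each tissue's abundance vector is then
#' normalized to sum to one.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `abundance_root`,
#'   `abundance_nodule`, `de_label` (up/down/none, nodule relative to root),
#'   `true_fold`.
#' @export
generate_truth <- function(config) {
  cfg <- config
  validate_sim_config(cfg)
  n <- cfg$n_genes
  n_de <- round(cfg$de_fraction * n)
  if (cfg$de_fraction > 0 && n_de < 1)
    stop("de_fraction * n_genes must be >= 1", call. = FALSE)
  with_seed(cfg$seed + 202L, {
    w <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)
    gene_id <- sprintf("gene_%05d", seq_len(n))
    root_w <- w
    nod_w <- w
    de_label <- rep("none", n)
    true_fold <- rep(1, n)
    if (n_de > 0) {
      eligible <- which(w >= stats::median(w))
      de_idx <- sample(eligible, n_de)
      folds <- rep_len(cfg$fold_ladder, n_de)
      dirs <- rep_len(c("up", "down"), n_de)
      for (k in seq_len(n_de)) {
        i <- de_idx[k]
        f <- folds[k]
        lo <- if (is.finite(f)) w[i] / f else 0
        if (dirs[k] == "up") root_w[i] <- lo else nod_w[i] <- lo
        de_label[i] <- dirs[k]
        true_fold[i] <- f
      }
    }
    data.frame(gene_id = gene_id,
               abundance_root = root_w / sum(root_w),
               abundance_nodule = nod_w / sum(nod_w),
               de_label = de_label,
               true_fold = true_fold,
               stringsAsFactors = FALSE)
  })
}

# Draw n tag observations: genes sampled by abundance among taggable genes,
# with a novel_tag_rate fraction replaced by tags from unannotated loci.
draw_tag_slots <- function(n, gene_ids, probs, tag_of, cfg) {
  g <- sample(gene_ids, n, replace = TRUE, prob = probs)
  tg <- unname(tag_of[g])
  if (cfg$novel_tag_rate > 0) {
    novel <- stats::runif(n) < cfg$novel_tag_rate
    if (any(novel)) {
      known <- unique(unname(tag_of))
      mk <- function() {
        repeat {
          t <- paste0(cfg$anchor,
                      random_dna(cfg$tag_length - nchar(cfg$anchor)))
          if (!t %in% known) return(t)
        }
      }
      tg[novel] <- vapply(seq_len(sum(novel)), function(i) mk(), character(1))
      g[novel] <- NA_character_
    }
  }
  list(gene = g, tag = tg)
}

#' Simulate one barcoded di-tag sequencing library
#'
#' Each record is `barcode + insert`, where the insert joins two canonical
#' tags head-to-head: `tag1 + reverse_complement(tag2)`. Tag pairs are drawn
#' independently from the tissue's abundance vector (restricted to genes
#' whose transcript carries an anchor). On top of the clean reads the
#' simulator injects a `pcr_duplicate_rate` fraction of exact copies of
#' earlier records and a `polyA_read_rate` fraction of low-complexity reads
#' carrying a run of >= 12 adenines, scaling the total so that the
#' post-filter depth matches `depth_per_library` up to sampling error.
#'
#' @param transcriptome from [generate_transcriptome()].
#' @param truth from [generate_truth()].
#' @param tissue tissue name; must have a barcode in the config.
#' @param config a [sim_config()].
#' @return object of class `sim_library`: list with `reads` (data.frame
#'   `read_id`, `sequence`), `ledger` (per-read draw record: gene of each
#'   tag, artifact class), `tissue`, `barcode`.
#' @export
simulate_library <- function(transcriptome, truth, tissue, config) {
  cfg <- config
  validate_sim_config(cfg)
  if (!tissue %in% names(cfg$barcodes))
    stop(sprintf("tissue '%s' has no barcode in the configuration", tissue),
         call. = FALSE)
  ab_col <- paste0("abundance_", tissue)
  if (!ab_col %in% names(truth))
    stop(sprintf("truth table has no column '%s'", ab_col), call. = FALSE)
  depth <- depth_for_tissue(cfg, tissue)
  barcode <- cfg$barcodes[[tissue]]

  tags <- canonical_tags(transcriptome, cfg$tag_length, cfg$anchor)
  ab <- stats::setNames(truth[[ab_col]], truth$gene_id)
  taggable <- names(tags)[!is.na(tags)]
  taggable <- taggable[ab[taggable] > 0]
  if (length(taggable) == 0L)
    stop("no taggable gene has positive abundance", call. = FALSE)
  probs <- ab[taggable] / sum(ab[taggable])
  tag_of <- tags[taggable]

  seed_t <- cfg$seed + 1000L * match(tissue, names(cfg$barcodes)) + 17L
  with_seed(seed_t, {
    n_total <- round(depth / (1 - cfg$pcr_duplicate_rate - cfg$polyA_read_rate))
    n_dup <- round(n_total * cfg$pcr_duplicate_rate)
    n_polyA <- round(n_total * cfg$polyA_read_rate)
    n_clean <- n_total - n_dup - n_polyA

    s1 <- draw_tag_slots(n_clean, taggable, probs, tag_of, cfg)
    s2 <- draw_tag_slots(n_clean, taggable, probs, tag_of, cfg)
    insert <- paste0(s1$tag, revcomp(s2$tag))
    gene1 <- s1$gene
    gene2 <- s2$gene
    cls <- rep("clean", n_clean)

    if (n_polyA > 0) {
      p1 <- draw_tag_slots(n_polyA, taggable, probs, tag_of, cfg)
      p2 <- draw_tag_slots(n_polyA, taggable, probs, tag_of, cfg)
      ins <- paste0(p1$tag, revcomp(p2$tag))
      for (i in seq_len(n_polyA)) {
        runlen <- sample(12:16, 1)
        start <- sample.int(nchar(ins[i]) - runlen + 1L, 1)
        substr(ins[i], start, start + runlen - 1L) <- strrep("A", runlen)
      }
      insert <- c(insert, ins)
      gene1 <- c(gene1, p1$gene)
      gene2 <- c(gene2, p2$gene)
      cls <- c(cls, rep("polyA", n_polyA))
    }

    ord <- sample(length(insert))
    insert <- insert[ord]
    gene1 <- gene1[ord]
    gene2 <- gene2[ord]
    cls <- cls[ord]

    # PCR duplicates are exact copies of earlier records (appended last so
    # the copy always follows its template in read order).
    if (n_dup > 0) {
      src <- sample(which(cls == "clean"), n_dup, replace = TRUE)
      insert <- c(insert, insert[src])
      gene1 <- c(gene1, gene1[src])
      gene2 <- c(gene2, gene2[src])
      cls <- c(cls, rep("pcr_duplicate", n_dup))
    }

    read_id <- sprintf("%s_%06d", tissue, seq_along(insert))
    reads <- data.frame(read_id = read_id,
                        sequence = paste0(barcode, insert),
                        stringsAsFactors = FALSE)
    ledger <- data.frame(read_id = read_id, insert = insert,
                         gene1 = gene1, gene2 = gene2, class = cls,
                         stringsAsFactors = FALSE)
    structure(list(reads = reads, ledger = ledger, tissue = tissue,
                   barcode = barcode),
              class = "sim_library")
  })
}

#' Simulate a qRT-PCR Ct table with known log2 expression ratios
#'
#' Generates threshold cycles for root and nodule samples across biological
#' replicates, two technical replicates each, under the standard
#' efficiency-2 model: a gene with true log2 ratio r (positive =
#' nodule-upregulated) has its nodule Ct lowered by r cycles. Per-sample
#' global offsets model RNA-loading differences (cancelled by reference
#' normalization), per-gene instability models reference-gene drift, and
#' `noise_sd` is well-level Gaussian noise.
#'
#' @param truth_log2_ratios named numeric: gene -> true log2(nodule/root)
#'   ratio; must be finite.
#' @param n_replicates number of biological replicates (>= 2).
#' @param ref_genes reference gene names; any not present among the ratios
#'   are added with ratio 0, and a supplied ratio for a reference must be 0.
#' @param noise_sd well-level Gaussian noise SD in Ct cycles.
#' @param seed integer seed.
#' @param gene_instability_sd per-gene, per-sample instability SD; scalar or
#'   named vector (unnamed genes fall back to the scalar default 0).
#' @param sample_effect_sd SD of per-(replicate, tissue) global Ct offsets.
#' @param base_ct_range range of per-gene baseline Ct values.
#' @return data.frame with columns `gene_id`, `replicate_id`, `tissue`,
#'   `tech_rep`, `ct`.
#' @export
simulate_qpcr <- function(truth_log2_ratios, n_replicates = 5,
                          ref_genes = character(0), noise_sd = 0.2,
                          seed = 1, gene_instability_sd = 0,
                          sample_effect_sd = 0.5,
                          base_ct_range = c(18, 30)) {
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (ratio aggregation needs >= 2)",
         call. = FALSE)
  ratios <- truth_log2_ratios
  if (is.null(names(ratios)) || any(names(ratios) == ""))
    stop("truth_log2_ratios must be named by gene", call. = FALSE)
  if (any(!is.finite(ratios)))
    stop("truth_log2_ratios must be finite (cap all-or-nothing genes first)",
         call. = FALSE)
  add_ref <- setdiff(ref_genes, names(ratios))
  if (length(add_ref))
    ratios <- c(ratios, stats::setNames(rep(0, length(add_ref)), add_ref))
  if (any(ratios[ref_genes] != 0))
    stop("reference genes must have a true log2 ratio of 0", call. = FALSE)

  genes <- names(ratios)
  instab <- rep(0, length(genes))
  names(instab) <- genes
  if (length(gene_instability_sd) == 1L && is.null(names(gene_instability_sd))) {
    instab[] <- gene_instability_sd
  } else {
    hit <- intersect(names(gene_instability_sd), genes)
    instab[hit] <- gene_instability_sd[hit]
  }

  tissues <- c("root", "nodule")
  reps <- sprintf("qPCR%d", seq_len(n_replicates))
  with_seed(seed, {
    base_ct <- stats::setNames(
      stats::runif(length(genes), base_ct_range[1], base_ct_range[2]), genes)
    grid <- expand.grid(gene_id = genes, replicate_id = reps,
                        tissue = tissues, tech_rep = 1:2,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    sample_key <- paste(grid$replicate_id, grid$tissue)
    samples <- unique(sample_key)
    offset <- stats::setNames(
      stats::rnorm(length(samples), 0, sample_effect_sd), samples)
    gskey <- paste(grid$gene_id, sample_key)
    gs <- unique(gskey)
    gs_gene <- sub(" .*$", "", gs)
    drift <- stats::setNames(stats::rnorm(length(gs), 0, 1) * instab[gs_gene],
                             gs)
    ct <- base_ct[grid$gene_id] + offset[sample_key] -
      ratios[grid$gene_id] * (grid$tissue == "nodule") +
      drift[gskey] +
      (if (noise_sd > 0) stats::rnorm(nrow(grid), 0, noise_sd) else 0)
    grid$ct <- unname(ct)
    grid[order(grid$gene_id, grid$replicate_id, grid$tissue, grid$tech_rep), ,
         drop = FALSE]
  })
}

#' Write a transcriptome to FASTA
#' @param transcriptome data.frame with `gene_id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcriptome_fasta <- function(transcriptome, path) {
  x <- Biostrings::DNAStringSet(transcriptome$sequence)
  names(x) <- transcriptome$gene_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a transcriptome from FASTA
#' @param path FASTA file.
#' @return data.frame with `gene_id`, `sequence`.
#' @export
read_transcriptome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  data.frame(gene_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' Qualities are filled with a constant score: the analysis never consumes
#' base qualities, only sequences.
#'
#' @param reads a `sim_library` or a data.frame with `read_id`, `sequence`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  if (inherits(reads, "sim_library")) reads <- reads$reads
  reads <- as_reads_df(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  q <- Biostrings::BStringSet(vapply(nchar(reads$sequence),
                                     function(n) strrep("I", n), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read di-tag reads from FASTQ
#' @param path FASTQ file.
#' @return data.frame with `read_id`, `sequence`.
#' @export
read_reads_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x), stringsAsFactors = FALSE)
}
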