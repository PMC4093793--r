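# qRT-PCR validation analytics: technical-replicate aggregation, geNorm
# reference-gene stability (M, stepwise exclusion, pairwise variation V),
# geometric-mean normalized delta-delta-Ct ratios, and hierarchical
# clustering of log2 expression ratios.

#' Aggregate technical replicates to mean Ct values
#'
#' Arithmetic mean of the technical-replicate Ct values per
#' (gene, biological replicate, tissue) well group. Well groups expected
#' from the full gene x replicate x tissue grid but absent from the table
#' are reported with a warning (they invalidate downstream ratios for the
#' affected replicate).
#'
#' @param ct_table data.frame with `gene_id`, `replicate_id`, `tissue`,
#'   `tech_rep`, `ct`.
#' @return data.frame with `gene_id`, `replicate_id`, `tissue`, `ct`
#'   (mean over technical replicates).
#' @export
aggregate_tech_reps <- function(ct_table) {
  need <- c("gene_id", "replicate_id", "tissue", "tech_rep", "ct")
  stopifnot(all(need %in% names(ct_table)))
  out <- stats::aggregate(ct ~ gene_id + replicate_id + tissue,
                          data = ct_table, FUN = mean)
  full <- expand.grid(gene_id = unique(ct_table$gene_id),
                      replicate_id = unique(ct_table$replicate_id),
                      tissue = unique(ct_table$tissue),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- function(d) paste(d$gene_id, d$replicate_id, d$tissue, sep = "\r")
  missing <- full[!key(full) %in% key(out), , drop = FALSE]
  if (nrow(missing) > 0)
    warning(sprintf("%d well group(s) missing from the Ct table (e.g. %s/%s/%s)",
                    nrow(missing), missing$gene_id[1], missing$replicate_id[1],
                    missing$tissue[1]), call. = FALSE)
  out <- out[order(out$gene_id, out$replicate_id, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_well_groups") <- missing
  out
}

#' Pivot mean Ct values to a gene x sample matrix
#'
#' Samples are `replicate.tissue` combinations; used as geNorm input.
#'
#' @param mean_ct output of [aggregate_tech_reps()].
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
ct_matrix <- function(mean_ct) {
  sample_id <- paste(mean_ct$replicate_id, mean_ct$tissue, sep = ".")
  genes <- sort(unique(mean_ct$gene_id))
  samples <- sort(unique(sample_id))
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  m[cbind(match(mean_ct$gene_id, genes), match(sample_id, samples))] <- mean_ct$ct
  m
}

# Relative quantities under 100% amplification efficiency: per gene,
# Q = 2^(Ct_min - Ct), so the best-expressed sample has Q = 1.
relative_quantities <- function(ct_mat) {
  2^(apply(ct_mat, 1, min) - ct_mat)
}

# Average pairwise stability of each gene on a log2-quantity matrix:
# M_j = mean over k != j of SD over samples of (log2 Q_j - log2 Q_k).
genorm_m_values <- function(log2q) {
  g <- nrow(log2q)
  vapply(seq_len(g), function(j) {
    mean(vapply(setdiff(seq_len(g), j), function(k) {
      stats::sd(log2q[j, ] - log2q[k, ])
    }, numeric(1)))
  }, numeric(1))
}

#' geNorm reference-gene stability analysis
#'
#' Computes the geNorm stability measure M for every candidate gene (lower
#' = more stable), the stepwise exclusion ranking obtained by repeatedly
#' removing the least stable gene down to a final pair, and the pairwise
#' variation series V(n/n+1) that guides the choice of how many reference
#' genes to use. Quantities are derived from mean Ct values under
#' efficiency 2.
#'
#' @param ct_mat gene x sample matrix of mean Ct values (>= 3 genes,
#'   >= 2 samples); see [ct_matrix()].
#' @param m_threshold stability threshold below which a candidate is
#'   flagged acceptable (geNorm convention: 0.5 on homogeneous panels).
#' @return object of class `genorm`: list with `M` (full-panel M per gene),
#'   `exclusion_rank` (1 = excluded first, i.e. least stable; the final
#'   pair receives the top ranks), `stability_order` (gene names, most
#'   stable first), `V` (named series `V2/3`, `V3/4`, ...), `acceptable`
#'   (logical, `M < m_threshold`), `m_threshold`.
#' @export
genorm_stability <- function(ct_mat, m_threshold = 0.5) {
  if (!is.matrix(ct_mat)) ct_mat <- as.matrix(ct_mat)
  if (nrow(ct_mat) < 3)
    stop("geNorm ranking needs at least 3 candidate genes", call. = FALSE)
  if (ncol(ct_mat) < 2)
    stop("geNorm needs at least 2 samples", call. = FALSE)
  if (any(is.na(ct_mat)))
    stop("ct_mat contains missing values", call. = FALSE)
  genes <- rownames(ct_mat)
  if (is.null(genes)) genes <- sprintf("gene%d", seq_len(nrow(ct_mat)))
  log2q <- log2(relative_quantities(ct_mat))
  rownames(log2q) <- genes

  M_full <- stats::setNames(genorm_m_values(log2q), genes)

  # stepwise exclusion of the least stable gene, recomputing M each round
  remaining <- genes
  exclusion_order <- character(0)
  while (length(remaining) > 2) {
    M_now <- stats::setNames(genorm_m_values(log2q[remaining, , drop = FALSE]),
                             remaining)
    worst <- names(which.max(M_now))
    exclusion_order <- c(exclusion_order, worst)
    remaining <- setdiff(remaining, worst)
  }
  # final pair is indistinguishable by M; order it by full-panel M
  final_pair <- remaining[order(M_full[remaining], decreasing = TRUE)]
  exclusion_order <- c(exclusion_order, final_pair)
  exclusion_rank <- stats::setNames(match(genes, exclusion_order), genes)
  stability_order <- rev(exclusion_order)

  # pairwise variation V(n/n+1) between normalization factors of the n and
  # n+1 most stable genes (geometric mean of quantities = mean of log2 Q)
  G <- length(genes)
  V <- numeric(0)
  if (G >= 3) {
    nf_log2 <- function(n) colMeans(log2q[stability_order[seq_len(n)], ,
                                          drop = FALSE])
    V <- vapply(2:(G - 1), function(n) {
      stats::sd(nf_log2(n) - nf_log2(n + 1))
    }, numeric(1))
    names(V) <- sprintf("V%d/%d", 2:(G - 1), 3:G)
  }

  structure(list(M = M_full, exclusion_rank = exclusion_rank,
                 stability_order = stability_order, V = V,
                 acceptable = M_full < m_threshold,
                 m_threshold = m_threshold),
            class = "genorm")
}

#' Delta-delta-Ct expression ratios with multi-reference normalization
#'
#' For each target gene and biological replicate, the Ct value is
#' normalized by the arithmetic mean Ct of the reference genes (which, at
#' efficiency 2, equals the log2 of the geometric mean of their relative
#' quantities): `dCt(tissue) = Ct_target - mean(Ct_references)`. Then
#' `ddCt = dCt(test tissue) - dCt(reference tissue)`, `ratio = 2^(-ddCt)`,
#' `log2_ratio = -ddCt`; positive log2 ratios mean upregulation in the test
#' tissue (nodule, by default). A replicate missing any reference
#' measurement in either tissue has all its ratios flagged invalid.
#'
#' @param mean_ct output of [aggregate_tech_reps()].
#' @param targets target gene ids.
#' @param references reference gene ids (conventionally 3).
#' @param tissue_ref,tissue_test tissue labels; the ratio is
#'   `tissue_test` over `tissue_ref`.
#' @return data.frame with `gene_id`, `replicate_id`, `delta_delta_ct`,
#'   `log2_ratio`, `ratio`, `valid`.
#' @export
ddct_ratios <- function(mean_ct, targets, references,
                        tissue_ref = "root", tissue_test = "nodule") {
  stopifnot(length(references) >= 1)
  missing_ref <- setdiff(references, mean_ct$gene_id)
  if (length(missing_ref))
    stop(sprintf("reference gene(s) not measured: %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  reps <- unique(mean_ct$replicate_id)
  ct_of <- function(gene, rep, tissue) {
    v <- mean_ct$ct[mean_ct$gene_id == gene & mean_ct$replicate_id == rep &
                    mean_ct$tissue == tissue]
    if (length(v) == 1) v else NA_real_
  }
  rows <- list()
  for (rep in reps) {
    ref_ct <- sapply(c(tissue_ref, tissue_test), function(tis) {
      mean(vapply(references, ct_of, numeric(1), rep = rep, tissue = tis))
    })
    rep_valid <- all(is.finite(ref_ct))
    for (g in targets) {
      ct_r <- ct_of(g, rep, tissue_ref)
      ct_t <- ct_of(g, rep, tissue_test)
      valid <- rep_valid && is.finite(ct_r) && is.finite(ct_t)
      ddct <- if (valid) (ct_t - ref_ct[[tissue_test]]) -
                         (ct_r - ref_ct[[tissue_ref]]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, replicate_id = rep, delta_delta_ct = ddct,
        log2_ratio = -ddct, ratio = 2^(-ddct), valid = valid,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot a ratio table to a gene x replicate log2-ratio matrix
#' @param ratio_table output of [ddct_ratios()].
#' @return numeric matrix of log2 ratios, genes in rows.
#' @export
log2_ratio_matrix <- function(ratio_table) {
  genes <- unique(ratio_table$gene_id)
  reps <- unique(ratio_table$replicate_id)
  m <- matrix(NA_real_, length(genes), length(reps),
              dimnames = list(genes, reps))
  m[cbind(match(ratio_table$gene_id, genes),
          match(ratio_table$replicate_id, reps))] <- ratio_table$log2_ratio
  m
}

#' Hierarchical clustering of a log2-ratio matrix
#'
#' Agglomerative clustering of genes (rows) and samples (columns) with
#' Euclidean distances; average linkage by default. Missing values are
#' mean-imputed per row with a warning. Merge heights, deterministic leaf
#' orders, the reordered matrix and newick renderings of both trees are
#' returned.
#'
#' @param log2_matrix numeric matrix, genes x samples.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `row_hclust`, `col_hclust` (NULL for single
#'   row/column), `ordered` (matrix in leaf order), `row_newick`,
#'   `col_newick`.
#' @export
cluster_ratios <- function(log2_matrix, linkage = "average") {
  m <- as.matrix(log2_matrix)
  if (any(is.na(m))) {
    warning("missing values mean-imputed per gene before clustering",
            call. = FALSE)
    for (i in seq_len(nrow(m))) {
      mu <- mean(m[i, ], na.rm = TRUE)
      m[i, is.na(m[i, ])] <- if (is.finite(mu)) mu else 0
    }
  }
  tree <- function(x) {
    if (nrow(x) < 2) return(NULL)
    stats::hclust(stats::dist(x, method = "euclidean"), method = linkage)
  }
  row_hc <- tree(m)
  col_hc <- tree(t(m))
  ro <- if (is.null(row_hc)) seq_len(nrow(m)) else row_hc$order
  co <- if (is.null(col_hc)) seq_len(ncol(m)) else col_hc$order
  newick <- function(hc, labels) {
    if (is.null(hc)) return(sprintf("(%s);", paste(labels, collapse = ",")))
    ape::write.tree(ape::as.phylo(hc))
  }
  list(row_hclust = row_hc, col_hclust = col_hc,
       ordered = m[ro, co, drop = FALSE],
       row_newick = newick(row_hc, rownames(m)),
       col_newick = newick(col_hc, colnames(m)))
}
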