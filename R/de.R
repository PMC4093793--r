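# Differential expression: TPT normalization, zero-adjusted fold changes,
# per-gene 2x2 chi-squared tests, fold-threshold binning and tissue-overlap
# summaries.

#' Tags-per-ten-thousand (TPT) normalization
#'
#' Scales a tag count to a library total of 10,000 so that abundances are
#' comparable across libraries: `count / library_total * 10000`.
#'
#' @param count tag count(s), `0 <= count <= library_total`.
#' @param library_total library total (unambiguously assigned tags by
#'   default); must be positive.
#' @return numeric TPT value(s).
#' @export
#' @examples
#' normalize_tpt(10, 26380)    # 3.7908...
#' normalize_tpt(0, 20000)     # 0
normalize_tpt <- function(count, library_total) {
  if (any(library_total <= 0))
    stop("library_total must be positive", call. = FALSE)
  if (any(count < 0) || any(count > library_total))
    stop("count must satisfy 0 <= count <= library_total", call. = FALSE)
  count / library_total * 10000
}

#' Zero-adjusted fold change between two TPT values
#'
#' TPT values of zero are replaced by a pseudo-count (default 0.05) before
#' division, so all-or-nothing genes receive a finite fold change. Fold is
#' B over A; with both inputs zero the fold is 1 and the direction `flat`
#' (both pseudo-counts cancel).
#'
#' @param tpt_a,tpt_b TPT values (vectors allowed), library A and B.
#' @param pseudo pseudo-count substituted for zeros.
#' @return data.frame with `tpt_a_adj`, `tpt_b_adj`, `fold_change`
#'   (= `tpt_b_adj / tpt_a_adj`), `log2_fold`, and `direction`
#'   (`up_in_B`/`down_in_B`/`flat`).
#' @export
#' @examples
#' adjusted_fold_change(0, 17.3)   # fold 346, up_in_B
adjusted_fold_change <- function(tpt_a, tpt_b, pseudo = 0.05) {
  if (any(tpt_a < 0) || any(tpt_b < 0))
    stop("TPT values must be non-negative", call. = FALSE)
  a <- ifelse(tpt_a == 0, pseudo, tpt_a)
  b <- ifelse(tpt_b == 0, pseudo, tpt_b)
  fold <- b / a
  direction <- ifelse(fold > 1, "up_in_B", ifelse(fold < 1, "down_in_B", "flat"))
  data.frame(tpt_a_adj = a, tpt_b_adj = b, fold_change = fold,
             log2_fold = log2(fold), direction = direction,
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared test for one gene across two libraries
#'
#' Tests equality of a gene's tag proportion in two libraries with the
#' Pearson chi-squared statistic on the 2x2 table
#' `[[count_a, total_a - count_a], [count_b, total_b - count_b]]`,
#' one degree of freedom, no continuity correction. With both counts zero
#' the statistic is 0 and p = 1 (no evidence). Vectorized over genes.
#'
#' @param count_a,count_b tag counts in library A and B.
#' @param total_a,total_b library totals.
#' @return data.frame with `chi2_stat` and `p_value`.
#' @export
chi2_de_test <- function(count_a, total_a, count_b, total_b) {
  if (any(total_a <= 0) || any(total_b <= 0))
    stop("library totals must be positive", call. = FALSE)
  if (any(count_a < 0) || any(count_b < 0) ||
      any(count_a > total_a) || any(count_b > total_b))
    stop("counts must satisfy 0 <= count <= total", call. = FALSE)
  a <- as.numeric(count_a); b <- as.numeric(count_b)
  A <- as.numeric(total_a); B <- as.numeric(total_b)
  N <- A + B
  # margins formula for the 2x2 Pearson statistic
  num <- N * (a * (B - b) - b * (A - a))^2
  den <- (a + b) * (N - a - b) * A * B
  stat <- ifelse(den == 0, 0, num / den)
  data.frame(chi2_stat = stat,
             p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Per-gene differential-expression table
#'
#' Computes, for every gene expressed in at least one library (count > 0
#' somewhere), the TPT pair, zero-adjusted fold change (library B over A,
#' i.e. nodule over root in the default orientation), chi-squared statistic
#' and raw p-value, plus a Benjamini-Hochberg column for convenience (the
#' headline calls use the raw p-values at `alpha`).
#'
#' @param matrix a [tag_count_matrix()] with exactly two libraries; the
#'   first column is library A (root), the second library B (nodule).
#' @param pseudo zero-adjustment pseudo-count in TPT space.
#' @param denominator `"assigned"` (default) normalizes by unambiguously
#'   assigned tags per library; `"input"` by the filtered input tag totals
#'   from `matrix$mapping_stats`.
#' @return data.frame of class `de_table`: `gene_id`, `count_a`, `count_b`,
#'   `tpt_a`, `tpt_b`, `tpt_a_adj`, `tpt_b_adj`, `fold_change`,
#'   `log2_fold`, `chi2_stat`, `p_value`, `padj_bh`, `direction`.
#' @export
de_test <- function(matrix, pseudo = 0.05,
                    denominator = c("assigned", "input")) {
  stopifnot(inherits(matrix, "tag_count_matrix"))
  denominator <- match.arg(denominator)
  m <- matrix$counts
  if (ncol(m) != 2)
    stop("de_test requires exactly two libraries", call. = FALSE)
  totals <- switch(denominator,
    assigned = matrix$library_totals,
    input = {
      st <- matrix$mapping_stats
      if (is.null(st)) stop("no mapping_stats for denominator = 'input'",
                            call. = FALSE)
      stats::setNames(st$n_tags_in, st$library)[colnames(m)]
    })
  expressed <- rowSums(m) > 0
  m <- m[expressed, , drop = FALSE]
  ca <- m[, 1]; cb <- m[, 2]
  tpt_a <- normalize_tpt(ca, totals[[1]])
  tpt_b <- normalize_tpt(cb, totals[[2]])
  fc <- adjusted_fold_change(tpt_a, tpt_b, pseudo = pseudo)
  x2 <- chi2_de_test(ca, totals[[1]], cb, totals[[2]])
  out <- data.frame(gene_id = rownames(m), count_a = ca, count_b = cb,
                    tpt_a = tpt_a, tpt_b = tpt_b, fc, x2,
                    padj_bh = stats::p.adjust(x2$p_value, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("de_table", class(out))
  out
}

#' Fold-threshold binning of differentially expressed genes
#'
#' Counts up- and downregulated genes above each fold threshold, both
#' restricted to significance (`p < alpha`, raw chi-squared p-values) and
#' unrestricted, with a sum row per threshold.
#'
#' @param records a `de_table` from [de_test()].
#' @param alpha significance level for the restricted counts.
#' @param thresholds fold cutoffs (sorted internally; counts use
#'   `fold > threshold` for up and `fold < 1/threshold` for down).
#' @return data.frame with one row per threshold: `threshold`, `n_up`,
#'   `n_down`, `n_sum` (significance-restricted) and `n_up_all`,
#'   `n_down_all`, `n_sum_all` (unrestricted).
#' @export
build_threshold_table <- function(records, alpha = 0.01,
                                  thresholds = c(2, 4, 8, 64, 128, 256)) {
  thresholds <- sort(thresholds)
  fold <- records$fold_change
  p <- records$p_value
  if (length(fold) == 0L) {
    z <- integer(length(thresholds))
    return(data.frame(threshold = thresholds, n_up = z, n_down = z,
                      n_sum = z, n_up_all = z, n_down_all = z, n_sum_all = z))
  }
  up <- records$direction == "up_in_B"
  down <- records$direction == "down_in_B"
  rows <- lapply(thresholds, function(t) {
    n_up <- sum(up & fold > t & p < alpha)
    n_down <- sum(down & fold < 1 / t & p < alpha)
    n_up_all <- sum(up & fold > t)
    n_down_all <- sum(down & fold < 1 / t)
    data.frame(threshold = t, n_up = n_up, n_down = n_down,
               n_sum = n_up + n_down, n_up_all = n_up_all,
               n_down_all = n_down_all, n_sum_all = n_up_all + n_down_all)
  })
  do.call(rbind, rows)
}

#' Tissue-overlap summary of expressed genes
#'
#' A gene is "expressed" in a library iff its count is at least
#' `presence_min`. Reports the shared and exclusive gene tallies of the two
#' libraries and the shared percentage of all expressed genes.
#'
#' @param matrix a [tag_count_matrix()] with exactly two libraries, or a
#'   two-column count matrix.
#' @param presence_min minimum count for presence.
#' @return list with `n_shared`, `n_only_a`, `n_only_b`,
#'   `n_expressed_total`, `pct_shared` (1 d.p.).
#' @export
overlap_summary <- function(matrix, presence_min = 1) {
  m <- if (inherits(matrix, "tag_count_matrix")) matrix$counts else matrix
  if (ncol(m) != 2)
    stop("overlap_summary requires exactly two libraries; use pairwise calls",
         call. = FALSE)
  in_a <- m[, 1] >= presence_min
  in_b <- m[, 2] >= presence_min
  n_shared <- sum(in_a & in_b)
  n_only_a <- sum(in_a & !in_b)
  n_only_b <- sum(!in_a & in_b)
  total <- n_shared + n_only_a + n_only_b
  list(n_shared = n_shared, n_only_a = n_only_a, n_only_b = n_only_b,
       n_expressed_total = total,
       pct_shared = if (total > 0) round(100 * n_shared / total, 1) else NA_real_)
}
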