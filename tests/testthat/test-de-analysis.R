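test_that("TPT normalization follows the per-ten-thousand formula", {
  expect_equal(normalize_tpt(0, 20000), 0)
  expect_equal(normalize_tpt(20000, 20000), 10000)
  expect_equal(normalize_tpt(10, 26380), 10 / 26380 * 10000)
  expect_error(normalize_tpt(1, 0), "positive")
  expect_error(normalize_tpt(-1, 10), "0 <= count")
  expect_error(normalize_tpt(11, 10), "0 <= count")
})

test_that("TPT columns sum to exactly ten thousand per library", {
  cfg <- small_cfg(seed = 4)
  tx <- generate_transcriptome(cfg)
  tr <- generate_truth(cfg)
  bulk <- rbind(simulate_library(tx, tr, "root", cfg)$reads,
                simulate_library(tx, tr, "nodule", cfg)$reads)
  ex <- extract_tags(bulk, cfg$barcodes)
  tcm <- tag_count_matrix(lapply(ex$tags, assign_tags,
                                 index = build_tag_index(tx)))
  for (lib in colnames(tcm$counts))
    expect_equal(sum(normalize_tpt(tcm$counts[, lib],
                                   tcm$library_totals[[lib]])),
                 10000, tolerance = 1e-6)
})

test_that("zero-adjusted fold changes follow the 0.05 pseudo-count rule", {
  up <- adjusted_fold_change(0, 17.3)
  expect_equal(up$fold_change, 346)
  expect_equal(up$direction, "up_in_B")

  flat <- adjusted_fold_change(5, 5)
  expect_equal(flat$fold_change, 1)
  expect_equal(flat$direction, "flat")

  both0 <- adjusted_fold_change(0, 0)
  expect_equal(both0$fold_change, 1)
  expect_equal(both0$direction, "flat")

  # reciprocal identity on adjusted values
  a <- c(0, 2.5, 11, 0.3); b <- c(4, 0, 7.7, 0.3)
  fwd <- adjusted_fold_change(a, b)
  rev <- adjusted_fold_change(b, a)
  expect_equal(fwd$fold_change * rev$fold_change, rep(1, 4))
  expect_equal(fwd$log2_fold, -rev$log2_fold)
})

test_that("the 2x2 chi-squared statistic matches its oracles", {
  eq <- chi2_de_test(10, 1000, 10, 1000)
  expect_equal(eq$chi2_stat, 0)
  expect_equal(eq$p_value, 1)

  # all-or-nothing gene at realistic library depths (frozen from an
  # independent Pearson computation)
  x <- chi2_de_test(0, 25160, 10, 26380)
  expect_equal(x$chi2_stat, 9.539379, tolerance = 1e-6)
  expect_equal(x$p_value, 0.002011, tolerance = 1e-4)

  both0 <- chi2_de_test(0, 100, 0, 200)
  expect_equal(both0$chi2_stat, 0)
  expect_equal(both0$p_value, 1)

  # library oracle: uncorrected chisq.test over random tables
  set.seed(7)
  for (i in 1:200) {
    A <- sample(100:30000, 1); B <- sample(100:30000, 1)
    a <- rbinom(1, A, runif(1, 0, 0.01)); b <- rbinom(1, B, runif(1, 0, 0.01))
    mine <- chi2_de_test(a, A, b, B)
    if (a + b == 0) {
      expect_equal(mine$chi2_stat, 0)
    } else {
      ref <- suppressWarnings(stats::chisq.test(
        matrix(c(a, A - a, b, B - b), 2, byrow = TRUE), correct = FALSE))
      expect_equal(mine$chi2_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
    }
  }

  # swapping libraries leaves the statistic unchanged
  s1 <- chi2_de_test(14, 25160, 40, 26380)
  s2 <- chi2_de_test(40, 26380, 14, 25160)
  expect_equal(s1$chi2_stat, s2$chi2_stat)

  # p decreases as the proportion difference grows at fixed totals
  ps <- chi2_de_test(seq(10, 60, by = 10), 20000, 10, 20000)$p_value
  expect_true(all(diff(ps) < 0))

  expect_error(chi2_de_test(5, 0, 1, 10), "positive")
  expect_error(chi2_de_test(11, 10, 1, 10), "counts")
})

test_that("threshold binning reproduces published-style sum identities", {
  rec_2fold <- data.frame(
    fold_change = c(rep(3, 108), rep(1 / 3, 56)),
    direction = c(rep("up_in_B", 108), rep("down_in_B", 56)),
    p_value = rep(0.001, 164))
  tt <- build_threshold_table(rec_2fold, alpha = 0.01, thresholds = 2)
  expect_equal(tt$n_up, 108)
  expect_equal(tt$n_down, 56)
  expect_equal(tt$n_sum, 164)

  rec_128 <- data.frame(
    fold_change = c(rep(200, 51), rep(1 / 200, 13)),
    direction = c(rep("up_in_B", 51), rep("down_in_B", 13)),
    p_value = rep(0.005, 64))
  tt2 <- build_threshold_table(rec_128, alpha = 0.01, thresholds = 128)
  expect_equal(tt2$n_sum, 64)

  empty <- build_threshold_table(data.frame(fold_change = numeric(0),
                                            direction = character(0),
                                            p_value = numeric(0)))
  expect_true(all(empty[, -1] == 0))
})

test_that("threshold counts are monotone in the cutoff and respect alpha", {
  cfg <- small_cfg(seed = 23)
  tx <- generate_transcriptome(cfg)
  tr <- generate_truth(cfg)
  bulk <- rbind(simulate_library(tx, tr, "root", cfg)$reads,
                simulate_library(tx, tr, "nodule", cfg)$reads)
  ex <- extract_tags(bulk, cfg$barcodes)
  det <- de_test(tag_count_matrix(lapply(ex$tags, assign_tags,
                                         index = build_tag_index(tx))))
  tt <- build_threshold_table(det, alpha = 0.01,
                              thresholds = c(256, 2, 8, 64, 4, 128))
  expect_equal(tt$threshold, sort(tt$threshold))
  for (col in c("n_up", "n_down", "n_sum", "n_up_all", "n_down_all"))
    expect_true(all(diff(tt[[col]]) <= 0))
  expect_true(all(tt$n_up <= tt$n_up_all))
  expect_equal(tt$n_sum, tt$n_up + tt$n_down)
})

test_that("tissue overlap tallies shared and exclusive genes", {
  counts <- rbind(matrix(1, 800, 2),
                  cbind(rep(0, 682), rep(1, 682)),
                  cbind(rep(1, 297), rep(0, 297)))
  colnames(counts) <- c("root", "nodule")
  rownames(counts) <- sprintf("g%04d", seq_len(nrow(counts)))
  ov <- overlap_summary(counts)
  expect_equal(ov$n_shared, 800)
  expect_equal(ov$n_only_a, 297)
  expect_equal(ov$n_only_b, 682)
  expect_equal(ov$n_expressed_total, 1779)
  expect_equal(ov$pct_shared, 45.0)

  disjoint <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(overlap_summary(disjoint)$n_shared, 0)
  same <- cbind(a = c(2, 3), b = c(1, 9))
  ovs <- overlap_summary(same)
  expect_equal(ovs$n_only_a + ovs$n_only_b, 0)

  expect_error(overlap_summary(cbind(1, 2, 3)), "two libraries")
})

test_that("de_test assembles a coherent per-gene table", {
  cfg <- clean_cfg(seed = 6)
  tx <- generate_transcriptome(cfg)
  tr <- generate_truth(cfg)
  bulk <- rbind(simulate_library(tx, tr, "root", cfg)$reads,
                simulate_library(tx, tr, "nodule", cfg)$reads)
  ex <- extract_tags(bulk, cfg$barcodes)
  tcm <- tag_count_matrix(lapply(ex$tags, assign_tags,
                                 index = build_tag_index(tx)))
  det <- de_test(tcm)
  # only genes expressed somewhere; internal identities hold
  expect_true(all(det$count_a + det$count_b > 0))
  expect_equal(det$fold_change, det$tpt_b_adj / det$tpt_a_adj)
  expect_equal(det$log2_fold, log2(det$fold_change))
  expect_true(all(det$direction[det$fold_change > 1] == "up_in_B"))
  expect_true(all(det$p_value > 0 & det$p_value <= 1))
})
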