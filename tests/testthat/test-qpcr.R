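test_that("technical replicates aggregate by arithmetic mean", {
  ct <- data.frame(gene_id = "g", replicate_id = "qPCR1",
                   tissue = c("root", "root", "nodule"),
                   tech_rep = c(1, 2, 1), ct = c(20.0, 20.4, 25))
  mc <- aggregate_tech_reps(ct)
  expect_equal(mc$ct[mc$tissue == "root"], 20.2)
  expect_equal(mc$ct[mc$tissue == "nodule"], 25)  # single value stays itself
})

test_that("aggregation equals a brute-force group-by mean on simulated data", {
  ct <- simulate_qpcr(c(gA = 2, gB = -1), n_replicates = 3,
                      ref_genes = c("r1", "r2", "r3"), noise_sd = 0.3,
                      seed = 5)
  mc <- aggregate_tech_reps(ct)
  for (i in sample(nrow(mc), 10)) {
    rows <- ct[ct$gene_id == mc$gene_id[i] &
               ct$replicate_id == mc$replicate_id[i] &
               ct$tissue == mc$tissue[i], ]
    expect_equal(mc$ct[i], mean(rows$ct))
  }
})

test_that("perfectly co-varying candidates all have geNorm M of zero", {
  # Ct = gene effect + sample effect: all pairwise log-ratios constant
  gene_eff <- c(g1 = 20, g2 = 24, g3 = 18, g4 = 27)
  samp_eff <- c(s1 = 0, s2 = 1.3, s3 = -0.7, s4 = 0.4)
  m <- outer(gene_eff, samp_eff, `+`)
  gn <- genorm_stability(m)
  expect_equal(unname(gn$M), rep(0, 4))
  expect_equal(unname(gn$V), rep(0, 2))
})

test_that("geNorm M matches a direct pairwise recomputation and ranks noise last", {
  set.seed(12)
  stable <- outer(c(g1 = 20, g2 = 22, g3 = 24, g4 = 26), rep(0, 6), `+`) +
    matrix(rnorm(24, 0, 0.05), 4)
  noisy <- matrix(20 + rnorm(6, 0, 1), 1,
                  dimnames = list("gN", NULL))
  m <- rbind(stable, noisy)
  colnames(m) <- sprintf("s%d", 1:6)
  gn <- genorm_stability(m)
  expect_equal(unname(gn$M), unname(direct_genorm_m(m)), tolerance = 1e-12)
  expect_equal(names(which.max(gn$M)), "gN")
  # the noisy gene is excluded first
  expect_equal(gn$exclusion_rank[["gN"]], 1L)
  expect_false("gN" %in% gn$stability_order[1:3])
})

test_that("geNorm M is invariant to per-sample shifts and gene relabeling", {
  set.seed(3)
  m <- matrix(20 + rnorm(24, 0, 0.5), 4, 6,
              dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:6)))
  gn <- genorm_stability(m)
  shifted <- sweep(m, 2, runif(6, -3, 3), `+`)
  expect_equal(genorm_stability(shifted)$M, gn$M, tolerance = 1e-12)
  perm <- m[c(3, 1, 4, 2), ]
  expect_equal(genorm_stability(perm)$M[rownames(m)], gn$M,
               tolerance = 1e-12)
})

test_that("geNorm input validation rejects degenerate panels", {
  m <- matrix(20, 2, 4)
  expect_error(genorm_stability(m), "3 candidate")
  expect_error(genorm_stability(matrix(20, 3, 1)), "2 samples")
})

test_that("ddCt ratios follow the geometric-mean reference convention", {
  refs <- c("r1", "r2", "r3")
  # identical Ct in both tissues -> ratio 1
  ct0 <- simulate_qpcr(c(g = 0), n_replicates = 2, ref_genes = refs,
                       noise_sd = 0, seed = 1, sample_effect_sd = 0)
  rt0 <- ddct_ratios(aggregate_tech_reps(ct0), "g", refs)
  expect_equal(rt0$ratio, rep(1, 2))
  expect_equal(rt0$log2_ratio, rep(0, 2))

  # target one cycle lower in nodule, references equal -> ratio 2
  ct1 <- simulate_qpcr(c(g = 1), n_replicates = 2, ref_genes = refs,
                       noise_sd = 0, seed = 2, sample_effect_sd = 0)
  rt1 <- ddct_ratios(aggregate_tech_reps(ct1), "g", refs)
  expect_equal(rt1$ratio, rep(2, 2))
  expect_equal(rt1$log2_ratio, rep(1, 2))

  # noise-free simulation round-trips a -3 log2 ratio exactly, with
  # loading offsets present (they must cancel through the references)
  ct3 <- simulate_qpcr(c(g = -3), n_replicates = 3, ref_genes = refs,
                       noise_sd = 0, seed = 3, sample_effect_sd = 0.8)
  rt3 <- ddct_ratios(aggregate_tech_reps(ct3), "g", refs)
  expect_equal(rt3$log2_ratio, rep(-3, 3))
  expect_equal(rt3$ratio, 2^rt3$log2_ratio)
  expect_equal(rt3$log2_ratio, -rt3$delta_delta_ct)
})

test_that("swapping tissue labels negates every log2 ratio", {
  ct <- simulate_qpcr(c(gA = 1.7, gB = -0.4), n_replicates = 3,
                      ref_genes = c("r1", "r2", "r3"), noise_sd = 0.2,
                      seed = 8)
  mc <- aggregate_tech_reps(ct)
  fwd <- ddct_ratios(mc, c("gA", "gB"), c("r1", "r2", "r3"))
  swp <- ddct_ratios(mc, c("gA", "gB"), c("r1", "r2", "r3"),
                     tissue_ref = "nodule", tissue_test = "root")
  expect_equal(fwd$log2_ratio, -swp$log2_ratio)
})

test_that("replicates missing a reference measurement are flagged invalid", {
  ct <- simulate_qpcr(c(g = 1), n_replicates = 3,
                      ref_genes = c("r1", "r2", "r3"), noise_sd = 0, seed = 4)
  drop <- !(ct$gene_id == "r2" & ct$replicate_id == "qPCR2" &
            ct$tissue == "root")
  mc <- suppressWarnings(aggregate_tech_reps(ct[drop, ]))
  rt <- ddct_ratios(mc, "g", c("r1", "r2", "r3"))
  expect_false(rt$valid[rt$replicate_id == "qPCR2"])
  expect_true(all(rt$valid[rt$replicate_id != "qPCR2"]))
  expect_error(ddct_ratios(mc, "g", c("r1", "nope")), "not measured")
})

test_that("hierarchical clustering merges forced structure correctly", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(9, 9, 9))
  cl <- cluster_ratios(m)
  expect_equal(cl$row_hclust$height[1], 0)       # identical rows first
  first_pair <- rownames(m)[-cl$row_hclust$merge[1, ]]
  expect_setequal(first_pair, c("a", "b"))

  m2 <- rbind(x = 0, y = 1, z = 10)
  cl2 <- cluster_ratios(cbind(m2))
  expect_setequal(rownames(m2)[-cl2$row_hclust$merge[1, ]], c("x", "y"))
  expect_match(cl2$row_newick, "^\\(")
})

test_that("merge heights equal a naive O(n^3) agglomeration oracle", {
  set.seed(31)
  for (trial in 1:5) {
    m <- matrix(rnorm(50), 10, 5,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
    cl <- cluster_ratios(m, linkage = "average")
    expect_equal(sort(cl$row_hclust$height),
                 sort(naive_average_linkage_heights(m)), tolerance = 1e-10)
  }
})
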