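# Shared fixtures and independent oracles used across test files.

# A small, fast simulation configuration; override any field.
small_cfg <- function(...) {
  args <- list(n_genes = 120, depth_per_library = c(root = 1500, nodule = 1600),
               de_fraction = 0.1, fold_ladder = c(8, 64, Inf),
               pcr_duplicate_rate = 0.1, polyA_read_rate = 0.02,
               multimap_gene_pairs = 3, no_anchor_fraction = 0.05,
               novel_tag_rate = 0.1, seed = 42)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# A configuration with every artifact class switched off: reads map 1:1 to
# the simulator's tag draws (up to coincidental di-tag collisions).
clean_cfg <- function(...) {
  small_cfg(pcr_duplicate_rate = 0, polyA_read_rate = 0,
            multimap_gene_pairs = 0, no_anchor_fraction = 0,
            novel_tag_rate = 0, ...)
}

# Expected per-gene tag counts implied by a simulated library's draw
# ledger, after applying the same duplicate-collapse rule the pipeline
# applies (one representative per identical insert) and dropping poly-A
# reads. Independent of the extraction/mapping code paths.
ledger_expected_counts <- function(lib, genes) {
  led <- lib$ledger
  led <- led[!duplicated(led$insert), , drop = FALSE]
  led <- led[led$class != "polyA" &
             !grepl("AAAAAAAAAAAA", led$insert, fixed = TRUE), , drop = FALSE]
  tally <- table(factor(c(led$gene1, led$gene2), levels = genes))
  as.integer(tally)
}

# Naive O(n^3) agglomerative clustering oracle (average linkage, Euclidean)
# returning merge heights; deliberately brute-force and independent of
# stats::hclust.
naive_average_linkage_heights <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + n - 1)
  active[(n + 1):(2 * n - 1)] <- FALSE
  members <- c(clusters, vector("list", n - 1))
  heights <- numeric(n - 1)
  avail <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(avail)) for (j in seq_len(i - 1)) {
      a <- members[[avail[i]]]; b <- members[[avail[j]]]
      dd <- mean(d[a, b])
      if (dd < best_d) { best_d <- dd; best <- c(avail[i], avail[j]) }
    }
    new_id <- n + step
    members[[new_id]] <- c(members[[best[1]]], members[[best[2]]])
    heights[step] <- best_d
    avail <- c(setdiff(avail, best), new_id)
  }
  heights
}

# Direct recomputation of geNorm M values by explicit double loops over
# gene pairs, independent of the package's vectorized implementation.
direct_genorm_m <- function(ct_mat) {
  q <- 2^(apply(ct_mat, 1, min) - ct_mat)
  g <- nrow(ct_mat)
  out <- numeric(g)
  for (j in seq_len(g)) {
    sds <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      sds <- c(sds, stats::sd(log2(q[j, ] / q[k, ])))
    }
    out[j] <- mean(sds)
  }
  stats::setNames(out, rownames(ct_mat))
}
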