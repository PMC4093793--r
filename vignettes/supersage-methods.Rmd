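---
title: "Methods: tag-based expression profiling with supersage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-based expression profiling with supersage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supersage)
```

## The analysis in brief

SuperSAGE profiles a transcriptome by excising one fixed-length (26 bp) cDNA
fragment per transcript, anchored at an NlaIII restriction site (CATG), and
counting how often each such *tag* is sequenced. Two tags are ligated
head-to-head into a *di-tag* before PCR: because the independent re-ligation
of the same two tags is improbable, identical di-tags can be recognized and
removed as PCR amplification copies — the design's built-in duplicate
discrimination. `supersage` implements the full downstream analysis for a
two-condition comparison (nodule-free root vs. mature root nodule tissue of
a legume is the motivating design):

1. **Extraction** — demultiplex barcoded reads by exact prefix match,
   collapse identical di-tag inserts within each library, discard
   low-complexity reads containing 12 or more consecutive adenines, and
   split each insert into its two oriented tags.
2. **Mapping** — assign each tag to a gene through an exact anchored-tag
   index over a transcript set; tags matching more than one locus are
   excluded (unique-locus rule), and per-library mapping rates are
   reported.
3. **Differential expression** — normalize counts to tags per ten thousand
   (TPT), replace TPT values of zero by 0.05 so all-or-nothing genes get a
   finite fold change, test each gene with an uncorrected 2×2 Pearson
   chi-squared statistic, bin genes by fold thresholds, and summarize the
   tissue overlap of expressed genes.
4. **qRT-PCR validation analytics** — average technical duplicates, rank
   candidate reference genes by the geNorm stability measure M with
   stepwise exclusion and the pairwise-variation series V(n/n+1), compute
   delta-delta-Ct expression ratios normalized by the geometric mean of
   three reference genes, and cluster the log2 ratio matrix hierarchically
   with Euclidean distances.

A synthetic-data generator produces transcriptomes, ground-truth abundance
vectors, barcoded di-tag FASTQ libraries and Ct tables with known truth, so
each stage — and the pipeline end to end — is validated by parameter
recovery rather than by fixtures.

## Statistical model

Let $c_{gA}$ and $c_{gB}$ be the tag counts of gene $g$ in libraries $A$
(root) and $B$ (nodule) with totals $N_A$, $N_B$ (unambiguously assigned
tags by default). TPT normalization is
$\mathrm{TPT}_{g\ell} = 10^4\, c_{g\ell} / N_\ell$; a TPT of exactly zero
is replaced by the pseudo-count 0.05 before forming
$\mathrm{fold}_g = \mathrm{TPT}^{adj}_{gB} / \mathrm{TPT}^{adj}_{gA}$, so a
gene seen only in one tissue gets a finite, depth-dependent fold rather
than an infinity. Significance is the Pearson chi-squared statistic on
$[[c_{gA}, N_A - c_{gA}], [c_{gB}, N_B - c_{gB}]]$ with one degree of
freedom and no continuity correction, testing equality of the gene's tag
proportion across libraries. Raw p-values are thresholded at
$\alpha = 0.01$ for the headline calls; a Benjamini–Hochberg column is
emitted for completeness but deliberately not used for the
threshold-table layout, which follows the raw-p convention of tag-based
profiling reports.

For the validation analytics, relative quantities assume amplification
efficiency 2 throughout: $Q = 2^{-\Delta C_t}$. geNorm's stability of gene
$j$ is $M_j = \frac{1}{G-1}\sum_{k \ne j} \mathrm{SD}_s\!\left(\log_2 Q_{js}/Q_{ks}\right)$;
the least stable gene is excluded and M recomputed until two remain (the
final pair is ordered by full-panel M, since a two-gene panel cannot
separate them). $V(n/n{+}1)$ is the standard deviation across samples of
the log2 change in normalization factors (geometric means of the $n$ vs.
$n{+}1$ most stable genes). The delta-delta-Ct ratio normalizes a target's
Ct by the *arithmetic mean* Ct of the references — which at efficiency 2
is exactly the log2 of the geometric mean of their quantities — and uses
the sign convention that positive log2 ratios mean nodule-upregulated.

## What the simulator emulates, and what it does not

The generator's defaults are the study conditions the analysis is built
for: two libraries of 25,160 (root) and 26,380 (nodule) filtered di-tag
reads, 1,800 gene loci, barcode length 4 (ACAC/TGTG; prefix-free — the
actual barcodes of any given experiment are configurable), 26-bp tags with
the CATG anchor, and a fold ladder `c(2, 4, 8, 64, 128, 256, Inf)`
matching the fold-threshold bins of the report layout, with `Inf` encoding
all-or-nothing genes that exercise the 0.05 zero adjustment. Artifact
rates — 10% PCR duplicates, 2% poly-A reads — and the 20% rate of tags
from unannotated loci are not printed in tag-profiling reports; they were
chosen once as values that place the unique-mapping fraction in the
70–80% band typical of genome-anchored tag assignment, and are not tuned
thereafter.

Design choices worth knowing:

* **Di-tag geometry.** The insert is `tag1 + reverse_complement(tag2)`,
  split at the midpoint — the standard head-to-head ligation geometry; it
  is configurable because library protocols differ.
* **Canonical tag.** The tag starts at the 3′-most anchor occurrence that
  leaves room for a full 26-mer, mirroring NlaIII/EcoP15I excision.
  Mapping is exact-match against transcript-derived canonical tags: at
  26 bp this is the reproducible desk-scale equivalent of
  default-stringency genomic short-read alignment, and it makes the
  unique-locus exclusion rule a pure set operation.
* **DE placement.** Differentially expressed genes are drawn from the
  upper half of the abundance distribution, because tag-based DE calls at
  these depths concern well-expressed loci (an 8-fold change on a
  one-count gene is undetectable by any test). The high tissue keeps the
  baseline abundance and the low tissue is knocked down by the fold, so
  fold magnitudes do not inflate library totals.
* **Duplicate coincidences.** Independent draws of the same tag pair are
  collapsed exactly like true PCR duplicates — the analysis cannot tell
  them apart, and neither can the real protocol. Round-trip tests
  therefore derive expected counts from the simulator's draw ledger after
  applying the same dedup rule.

The simulator does **not** model sequencing errors beyond the poly-A
contaminant class (no homopolymer miscalls, no per-base error profile),
does not model tissue-specific expression breadth beyond the all-or-nothing
DE class (so the shared fraction of expressed genes is much higher in
simulation than in real tissue pairs), and fills FASTQ qualities with a
constant score because the analysis never consumes them. Passing tests
therefore demonstrate the correctness of the *computational* pipeline
under its stated assumptions, not robustness to instrument-specific error
modes.

## Numerical and degenerate-case conventions

* Fold change with both TPTs zero is 1 ("flat"): such genes are "not
  expressed" and excluded from DE tables by presence filtering anyway.
* The chi-squared statistic with both counts zero (or both at the total)
  is 0 with p = 1 — no evidence, not an error.
* Unique-assignment percentages are reported both truncated and rounded
  to one decimal place; tag-profiling reports conventionally truncate
  (17,909 / 25,160 prints as 71.1, though it rounds to 71.2).
* Duplicate collapse keeps the first occurrence; filter order (duplicates
  then poly-A, or the reverse) changes only the attribution of removed
  counts, never the surviving tag multiset — property-tested.
* Duplicate collapse is per-library (after demultiplexing); identical
  inserts in *different* libraries are biological coincidence, not PCR
  copies. This is configurable in principle but the per-library reading
  is the standard one.
* Clustering uses average linkage (the common viewer default; only the
  Euclidean metric is fixed by convention) and mean-imputes missing log2
  ratios per gene with a warning.
* All randomness flows from one integer seed per invocation through
  locally scoped RNG state; reruns are byte-identical and the caller's
  RNG stream is never touched.

## Problem sizes used by the test suite

Unit and property tests run on libraries of 1,500–2,000 reads over
120–400 genes, which exercise every artifact class in under a second
each. The parameter-recovery checks use ten seeds of an 1,800-gene,
~25,000-assigned-tags-per-library simulation with DE folds of 8 and
above — sizes chosen so that recovery statistics are stable (binomial
standard errors on sensitivity and false-positive rate of well under one
percentage point) while the whole suite stays fast. The geNorm recovery
check runs 100 seeded six-gene panels (three designated references with
0.05-cycle instability against three 0.5-cycle candidates, three
biological replicates), and the clustering check compares merge heights
against a brute-force $O(n^3)$ agglomeration oracle on 100 random
10×5 matrices.

## Known limitations

* The exact-match index cannot absorb sequencing errors in the tag body;
  a one-mismatch mode would be the natural extension but is off by
  design, since error simulation is also out of scope.
* Only one transcript per gene is modeled ("first transcript wins");
  alternative 3′ isoforms that move the anchored tag are not represented.
* The chi-squared test is asymptotic; for genes with very few counts at
  small depths its p-values are approximate (the all-or-nothing case at
  study-scale depths is fine, as the oracle-equivalence tests show).
* The compositional effect of strongly asymmetric DE between tissues is
  only partially balanced by the generator's symmetric up/down
  assignment; extreme one-sided regulation would shift flat genes'
  apparent proportions slightly.
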