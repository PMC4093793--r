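Package: supersage
Title: Tag-Based Expression Profiling with SuperSAGE Di-Tag Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for deepSuperSAGE tag-based expression
    profiling of two-condition experiments: demultiplexing of barcoded di-tag
    reads, PCR-duplicate and poly-A homopolymer filtering, anchored 26-bp tag
    extraction and unique-locus assignment against a transcript set,
    tags-per-ten-thousand (TPT) normalization with pseudo-count-adjusted fold
    changes, per-gene chi-squared differential-expression tests, and qRT-PCR
    validation analytics (geNorm reference-gene stability, geometric-mean
    normalized delta-delta-Ct ratios, hierarchical clustering of expression
    ratios). Includes a synthetic-data generator that emulates barcoded
    di-tag sequencing libraries and Ct tables with known ground truth, so
    every stage of the analysis can be exercised and validated end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
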