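Package: nadrna
Title: Spike-In Anchored Analysis of NAD-Capped RNA Enrichment Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for epitranscriptome-wide identification of NAD-capped
    RNAs from paired enrichment/input sequencing libraries. Provides
    spike-in anchored median-of-ratios normalization, fold-enrichment
    calling at tiered cutoffs, a chromosome-stratified permutation test
    for physical clusters of NAD-capped genes, Z-score identification of
    stage-specific epitranscriptome signatures, and structural feature
    analyses (enrichment deciles versus gene length, UTR-length
    comparisons, expression-capping correlation). Includes a seeded
    negative-binomial count simulator with planted ground truth and
    three spike-in classes for validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
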