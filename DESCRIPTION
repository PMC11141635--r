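Package: complexdep
Title: Protein-Complex-Level Selective Dependency Analysis for CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering protein-complex-level selective
    dependencies in genome-wide CRISPR knockout screens. Implements
    two-class differential dependency with an empirical-Bayes moderated
    t-statistic, preranked gene set enrichment (weighted Kolmogorov-Smirnov
    running sum with a gene-label permutation null), single-sample GSEA
    metagene scores with cross-line z-standardization, set-overlap tests,
    a rule-based MYCN amplification-status classifier, a paralog-redundancy
    screen correlating gene dependency with genome-wide expression, and
    spike-in calibrated ChIP-seq region quantification (scale factors,
    AUC-based peak curation, blacklist filtering, and differential-region
    classification with a negative-binomial likelihood-ratio test).
    A seeded synthetic-data generator reproduces the statistical structure
    of public dependency-screen releases so every stage is testable
    without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    edgeR,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
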