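Package: sgbMeta
Title: Cross-Cohort Meta-Analysis of Diet-Associated Gut Microbiome Species
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links species-level genome bins (SGBs) of the mouse gut
    microbiome to high- versus low-fat dietary regimens across multiple
    independent cohorts. Provides parsing and filtering of merged
    taxonomic relative-abundance profiles, covariate-adjusted per-dataset
    linear models converted to standardized mean differences, random- and
    fixed-effects pooling with Paule-Mandel heterogeneity, Fisher-Z
    partial Spearman correlation meta-analysis, Bray-Curtis diversity and
    PERMANOVA variance partitioning, a random-forest cross-validation /
    transfer / leave-one-dataset-out classification harness, and a
    multi-cohort synthetic data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    ranger
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Metagenomics, Microbiome, DifferentialAbundance, Classification
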