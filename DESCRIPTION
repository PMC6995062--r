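Package: methmark
Title: Discovery of Blood-Based Tumor-Specific CpG Methylation Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A discovery pipeline for blood-based, tumor-specific CpG
    methylation markers from Illumina 450K-style beta-value matrices.
    Classifies beta values into unmethylated/indeterminate/low/high bins,
    computes per-cohort subset percentage metrics, evaluates declarative
    threshold-filter chains (including the five-filter breast-cancer
    preset) across multi-cohort panels, stratifies tumors into high/low
    methylation subsets at mean +/- 1 SD for weighted Kolmogorov-Smirnov
    gene-set enrichment with a phenotype-permutation null, and quantifies
    marker association with expression and clinical covariates. Ships a
    seeded multi-cohort synthetic data generator so every stage is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
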