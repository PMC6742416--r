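Package: gram
Title: Cell-Type-Specific Prediction of Expression-Modulating Non-Coding Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A generalized multi-step model that predicts whether a non-coding
    single-nucleotide variant modulates reporter-gene expression in a
    cell-type-specific manner. The model combines cell-type-independent
    transcription-factor binding scores (e.g. from in vitro SELEX-derived
    sequence models) with cell-type-specific TF expression profiles in three
    steps: a random-forest universal regulatory-activity score per allele, two
    random-forest cell-type modifier scores (binding arm and rank-reordered
    expression arm), and an L1-regularized logistic integration producing a
    per-variant, per-sample molecular-effect score. The package also provides
    the supporting MPRA statistics (allelic log-skew, the Vodds variability
    statistic, expression-modulating-variant labels, quartile-based modifier
    labels), a LASSO-stability-selection plus random-forest feature-importance
    framework, leakage-free multi-step cross-validation, a synthetic-data
    generator for end-to-end testing, and an eQTL fine-mapping pipeline that
    scores cohort samples and ranks candidate causal variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    data.table,
    randomForest,
    ranger,
    glmnet,
    e1071,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    pheatmap,
    vcfR
Config/testthat/edition: 3
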