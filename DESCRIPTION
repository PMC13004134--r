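Package: senoscope
Title: Cataloging and Scoring Cellular Senescence Across Cell Types and Triggers
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building senescence marker catalogs from multi-model
    bulk transcriptomic and proteomic differential-expression results, for
    deriving consensus machine-learning senescence signatures by
    leave-one-cell-type-out L1-penalized logistic regression with unpenalized
    refitting and coefficient averaging, and for scoring single-cell or
    single-nucleus RNA-seq data in situ with rank-recovery (AUCell-style)
    gene-set scores, spline-based sequencing-depth correction and
    reference-percentile thresholding. Includes seeded synthetic-data
    generators that plant shared and cell-type-specific senescence markers in
    negative-binomial count matrices and log-normal protein intensities, and a
    planted senescent subpopulation with a library-depth confound in
    multinomial single-cell counts, so that every stage of the pipeline can be
    validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    splines,
    Matrix,
    glmnet,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Transcriptomics, SingleCell, GeneExpression, Classification
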