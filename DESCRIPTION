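Package: fosmap
Title: Whole-Brain c-Fos Activation Mapping at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection, consolidation and classification of fluorescent c-Fos
    puncta in 3D cleared-tissue volumes; mapping of detected cells through a
    deformation field onto a hierarchical brain atlas; region-wise density
    aggregation across a cohort; and a region-selection plus linear-model
    inference stack (random-forest pre-selection, per-region factorial models
    with a mouse random intercept, variance-standardized Cohen's d with
    confidence intervals, Benjamini-Hochberg FDR) that classifies brain regions
    as treatment-responsive with time and sex interactions. Includes a
    synthetic-phantom generator (Gaussian puncta, imaging artifacts, factorial
    cohorts with injected effects) so the entire workflow is testable without
    any imaging data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    tiff,
    jsonlite,
    yaml,
    igraph,
    lme4,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
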