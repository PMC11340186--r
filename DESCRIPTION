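Package: cfdnaStack
Title: Multiomics Cell-Free DNA Feature Extraction and Stacked Logistic
    Classification for Blood-Based Cancer Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds blood-based cancer screening classifiers from plasma
    cell-free DNA (cfDNA) multiomics profiles. Implements four feature
    extractors (targeted DNA methylation ratios, 5' end-motif frequency
    spectra, GC-corrected arm-level copy-number log2 ratios, and a
    filtered binary mutation score), rank-sum plus random-forest marker
    selection on a training cohort, per-omics ridge-logistic sub-models
    with stratified tenfold cross-validation, and a stacked integrated
    logistic model combining out-of-fold sub-model probabilities with the
    mutation score. Includes ROC/AUC evaluation with DeLong and bootstrap
    confidence intervals, exact binomial proportions, stage-stratified
    sensitivity, and a synthetic two-arm cohort simulator with
    stage-dependent tumor fractions for end-to-end testing of the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    randomForest,
    pROC,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Classification, Epigenetics, CopyNumberVariation,
    SomaticMutation, Sequencing
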