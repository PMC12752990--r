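Package: dmrpredict
Title: Differentially Methylated Region Discovery and Predictive
    Modelling from Whole-Genome Bisulfite Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A case/control analysis pipeline for whole-genome bisulfite
    sequencing of blood: per-CpG methylation count import and coverage
    filtering, principal component and principal variance component
    analysis, covariate-adjusted differential methylation testing with a
    permutation-null false-positive filter, merging of differentially
    methylated cytosines into regions with confounder-region subtraction
    and sex-chromosome censoring, k-means clustering with gene mapping
    and hypergeometric term enrichment, and held-out predictive models of
    disease status (per-region logistic models with bootstrap AU-ROC
    screening, L0+L2 sparse logistic regression, and cluster-wise
    decision-tree feature selection feeding a random forest). Includes a
    synthetic cohort generator with planted regions of known effect so
    the whole chain is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    lme4,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
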