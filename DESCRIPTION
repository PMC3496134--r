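Package: snpRiskAssess
Title: Two-Stage SNP Screening, Polygenic Risk Scores and Absolute
    Breast Cancer Risk Assessment
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for case-control assessment of breast cancer risk from a
    small panel of susceptibility SNPs and reproductive risk factors. Covers
    the full workflow of a two-stage association study: exact Hardy-Weinberg
    and Fisher-Freeman-Halton genotype tests, covariate-adjusted logistic
    odds ratios under additive, dominant, recessive and genotype codings,
    two-stage significance screening, cumulative risk models (risk-allele
    counting and odds-ratio-weighted risk scores with control-quartile
    grouping), modified Gail absolute-risk projection with competing
    mortality, and model discrimination by ROC/AUC with DeLong's test and
    stratified cross-validation. A calibrated synthetic-data generator
    emulates the two-stage study design so every stage is testable without
    subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    deSolve,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SNP, GenomeWideAssociation, Epidemiology, Classification
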