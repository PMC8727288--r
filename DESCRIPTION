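Package: cllprs
Title: Polygenic Risk Score Pipeline for CLL and Monoclonal B-Cell Lymphocytosis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction and evaluation of the 41-SNP chronic lymphocytic
    leukemia (CLL) polygenic risk score and its association with CLL and
    monoclonal B-cell lymphocytosis (MBL) risk. Provides genotype input and
    allele harmonization, variant- and sample-level quality control including
    an exact Hardy-Weinberg test, supervised admixture-based ancestry
    classification, weighted and unweighted score computation with
    reference-based quintile stratification, age- and sex-adjusted logistic
    association models, a polytomous heterogeneity trend test across outcome
    categories, concordance statistics with confidence intervals, and a
    synthetic genotype-phenotype cohort generator so every stage is testable
    without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
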