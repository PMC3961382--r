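Package: gwasrisk
Title: Construction and Prospective Validation of GWAS-Based Risk
    Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end construction and validation of polygenic risk
    prediction models for binary disease outcomes from case-control
    genotype data. Ranks SNPs by the Cochran-Armitage trend test, the
    asymptotic Bayes factor under a normal effect-size prior, and sure
    independence screening; prunes linkage-disequilibrium proxies by
    pairwise r-squared; selects the number of SNPs carried into a
    penalized logistic model (ridge, elastic net, lasso) by nested
    10-fold cross-validated AUC; screens pairwise interactions among
    genetic and clinical risk factors by likelihood-ratio tests; and
    validates fitted models in a longitudinal cohort with tertile risk
    categories, Kaplan-Meier curves and a log-rank trend test. Includes
    a seeded synthetic-data generator with configurable allele
    frequencies, LD blocks, causal effects, case-control covariate
    shifts and score-dependent survival, so the whole pipeline is
    testable without access to individual-level study data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    survival,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    withr
Config/testthat/edition: 3
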