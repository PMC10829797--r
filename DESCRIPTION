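Package: proteosubtype
Title: Proteogenomic Subtyping and Drug-Response Modeling for AML Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multiomic subtype discovery and drug-response
    analysis in acute myeloid leukemia cohorts profiled by TMT proteomics,
    phosphoproteomics and RNA-seq. Implements quantitative preprocessing
    (reporter-ratio relative abundance, missingness filters, median polish,
    KNN imputation, empirical-Bayes correction of loading-mass and plex
    effects), signed-split non-negative matrix factorization with consensus
    clustering and cophenetic model selection, a multinomial elastic-net
    proteomic subtype classifier, preranked GSEA and kinase-substrate
    enrichment (KSEA), ex vivo drug-sensitivity stratification by mutation and
    subtype (Welch tests, Fisher enrichment, Kaplan-Meier survival), and
    per-drug AUC regression with elastic net and gradient-boosted trees.
    Ships a synthetic-cohort generator emulating the statistical structure of
    such studies so every stage is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    survival,
    tools,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
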