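Package: amsbiomarkers
Title: Cross-Cohort Transcriptomic Biomarker Discovery for Acute Mountain Sickness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for discovering and validating blood
    transcriptomic biomarkers of severe acute mountain sickness (AMS) from
    paired sea-level / high-altitude RNA-seq cohorts. Provides count
    preprocessing (sample-level quality filtering, low-count masking with
    K-nearest-neighbour imputation, trimmed-mean-of-M-values normalization,
    principal-component outlier checks), sex-adjusted negative-binomial
    differential expression with prior-weighted dispersion shrinkage, a
    four-contrast biomarker taxonomy (diagnostic, predictive, pathogenic,
    protective) with same-direction cross-cohort replication filtering, and
    Gini-importance-ranked forward panel selection evaluated by ROC AUC and
    Youden-index operating points on an independent cohort. A synthetic
    two-cohort study generator with planted effects makes the whole pipeline
    runnable and testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    randomForest,
    e1071,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    pROC,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
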