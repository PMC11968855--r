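Package: smokemark
Title: Methylation-Based Smoking Biomarkers and Bayesian EWAS Toolkit
Version: 0.1.0
Authors@R:
    person("Smokemark", "Developers", email = "smokemark@example.org",
           role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies (EWAS) of
    cumulative smoking exposure measured in pack years. Implements a
    Bayesian penalised linear-regression EWAS with a spike-at-origin plus
    four-component Gaussian mixture prior sampled by Gibbs (posterior
    inclusion probabilities and posterior variance explained), per-site
    marginal EWAS with genomic inflation diagnostics, coverage-based
    quality-control filters for sequencing-derived methylation (targeted
    short-read bedGraph and long-read bedMethyl dialects), age- and
    sex-matched case-control selection, an elastic-net methylation
    biomarker of pack years with cross-cohort projection, score
    evaluation (incremental R-squared, correlations, ROC and
    precision-recall areas), a desk-scale genotype association scan with
    Haseman-Elston heritability, and a synthetic-cohort generator that
    emulates the statistical structure of questionnaire-derived smoking
    phenotypes, array and sequencing methylation, and genotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    glmnet,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
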