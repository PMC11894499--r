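Package: connpred
Title: Connectome-Based Predictive Modeling of Longitudinal Symptom Severity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for connectome-based predictive modeling (CPM) of
    longitudinal clinical outcomes from functional connectivity matrices.
    Builds Fisher-z connectomes from node time series, selects edges by
    confound-controlled partial correlation, fits summed-strength linear
    models under repeated k-fold cross-validation scored by Spearman rank
    correlation, assesses significance with permutation nulls and
    false-discovery-rate correction across symptom-cluster models, and
    attributes predictions to canonical functional networks via virtual
    lesion analysis. Includes a synthetic cohort generator with planted
    brain-behavior effects, longitudinal trajectory classes, ordinal
    symptom scales, and follow-up dropout, so the whole pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
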