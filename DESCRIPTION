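Package: DDIsignal
Title: Propensity Score-Adjusted Mixture Modelling for Drug-Drug
    Interaction Signal Detection in Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Disproportionality analysis of spontaneous adverse-event
    reports for drug-drug interaction (DDI) signal detection. Implements a
    propensity score-adjusted three-component mixture model (PS-3CMM) that
    models observed and expected report frequencies through an empirical
    Bayes gamma mixture and reports a local false discovery rate per
    drug-drug-ADE combination, with expected frequencies adjusted for
    comedication confounding through principal-component propensity
    scores. Also provides the Omega shrinkage statistic with its additive
    odds baseline and gamma-posterior credibility bound, proportional
    reporting ratios (PRR) with confidence-interval lower bounds and the
    associated interaction signal rule, a report-level simulator for
    benchmarking signal-detection operating characteristics, and ROC/AUC
    evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), withr, pROC, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
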