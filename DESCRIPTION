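Package: pgspower
Title: Power and Predictive Accuracy of Polygenic Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic power and accuracy calculations for two-stage polygenic
    score analyses, in which per-marker effects estimated in a training sample
    are used to build a weighted score that is tested for association, or used
    for risk prediction, in an independent replication sample.  Given a genetic
    architecture (explained variance, proportion of null markers, cross-trait
    effect correlation) and a study design (sample sizes, P-value selection
    window, estimator), the package computes the expected squared correlation,
    mean square error, non-centrality parameter, association power, and AUC of
    the score, on the observed and liability scales, with support for binary
    traits under prospective or case/control sampling.  The association
    statistic can be inverted to estimate the variance explained by the marker
    panel, or the effect correlation between two traits, with confidence
    intervals.  Design solvers give required sample sizes, optimal
    training/replication splits and optimal P-value selection thresholds.
    A marker-level simulator of two-sample studies validates every analytic
    quantity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
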