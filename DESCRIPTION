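Package: mhscreen
Title: Information-Theoretic Screening of Primary-Care Records for
    Complex Mental Health Difficulties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening primary-care electronic health records for
    features associated with a records-based definition of complex mental
    health difficulties. Provides a synthetic cohort generator with a planted
    latent complexity status and configurable diagnostic under-coding, a
    caseness phenotyping algorithm over a hierarchical clinical code
    vocabulary (inclusion and exclusion diagnosis lists plus a recent
    medication criterion), multi-level feature-set construction (component
    features, eight feature families with five count levels, and wildcard
    feature-family combinations), ranking of feature sets by mutual
    information scaled to the entropy of the caseness variable (plug-in
    estimator for discrete features, a nearest-neighbour mixed
    discrete-continuous estimator for continuous features), temporal entropy
    features of appointment non-attendance (sample entropy, spectral entropy,
    average quarterly entropy, active information), and contingency-table
    evaluation statistics with statistical disclosure control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
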