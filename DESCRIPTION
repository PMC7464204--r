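Package: coresig
Title: Cross-Cohort Signature Projection with a Bayesian Compound
    Covariate Predictor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives "core" gene-expression signatures by intersecting
    differential-expression lists across multiple tumor cohorts stratified
    with a Bayesian compound covariate predictor (BCCP), projects such
    signatures onto new cohorts, and runs the downstream statistics that
    tie subgroup calls to outcome: metagene and probability-based
    signature scores, Kaplan-Meier / log-rank survival comparison,
    chi-square association tests, and Pearson correlation. Ships a
    multi-cohort synthetic-study generator with planted shared and
    cohort-specific differential expression, reference panels, correlated
    survival and subtype labels, so the whole pipeline is testable
    end-to-end on known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
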