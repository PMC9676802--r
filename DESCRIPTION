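Package: panelselect
Title: Consensus Item Selection and Cross-Validated Evaluation of
    Abbreviated Diagnostic Screening Batteries
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Distils a short screening panel from a multi-item binary
    test battery, as used to abbreviate the 40-item smell-identification
    test for Parkinson's disease screening. Items are ranked by five
    statistics (Fisher exact p, diagnostic odds ratio, single-item
    AUC, ridge-penalised logistic-regression weights, regularised
    linear-discriminant weights); items selected into the top-k list
    by at least m of the five methods form the panel, which is then
    evaluated against the full battery by stratified cross-validation
    of PLS-DA and CART classifiers (pooled confusion matrices with the
    full diagnostic-accuracy metric suite) and by a Youden-index
    sum-score cut-off. Includes a calibrated per-class Bernoulli
    item-response simulator so the whole pipeline runs without
    external data, and utilities to reconstruct integer confusion
    matrices from rounded published accuracy metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
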