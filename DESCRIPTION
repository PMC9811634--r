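Package: agonistics
Title: Resampling Analysis of Agonistic Encounters in Reef Fish Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing agonistic encounter data collected on
    communities of territorial reef fishes before and after a resource
    depletion event. Implements per-individual aggregation of ordinal
    proximity categories, Monte-Carlo permutation Mann-Whitney and
    chi-squared tests, bootstrap resampling of one encounter per focal
    individual, signed and modified signed-likelihood ratio tests for
    equality of coefficients of variation of chase distances, and
    comparative regressions of pairwise behaviour on patristic distance
    and body-size difference. Includes a synthetic encounter-data
    generator with known ground-truth effects for calibration and
    parameter-recovery testing, and an end-to-end pipeline that emits a
    deterministic machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
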