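Package: fuzzylis
Title: Fuzzy Inference Re-Reading of the Murray Lung Injury Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a weighted Sugeno fuzzy inference system for grading acute
    lung injury severity from physician-survey data: membership functions are
    fitted by nonlinear least squares to the vote densities of a panel's
    three-category partitions of the Murray variables (PaO2/FiO2, respiratory
    compliance, PEEP), chest-film consolidation uses generalized bell
    functions, and severity rules carry weights proportional to how often the
    panel ticked each level. The fitted system is evaluated against the crisp
    Murray score on a factorial grid of hypothetical patients, with agreement
    analysed through difference histograms, contingency tables, Cohen's kappa
    and band-wise discrepancy with two-proportion tests. A synthetic physician
    panel simulator with configurable frontier jitter and diagnostic weighting
    makes the full pipeline reproducible without the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
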