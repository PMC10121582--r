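Package: lineup2ht
Title: Two-High-Threshold Multinomial Processing Tree Analysis of
    Eyewitness Lineup Identifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the two-high-threshold (2-HT) eyewitness identification
    model, a multinomial processing tree model over lineup identification
    outcomes (suspect identification, filler identification, lineup
    rejection in culprit-present and culprit-absent lineups), to
    condition-wise contingency tables by maximum likelihood.  Provides an
    EM fitter with a box-constrained quasi-Newton cross-check,
    likelihood-ratio goodness-of-fit tests (G-squared), nested-model
    comparisons on individual process parameters, standard errors from
    the expected Fisher information, noncentral chi-square power and
    sensitivity analysis (Cohen's w), multinomial data simulation and
    parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
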