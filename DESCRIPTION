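Package: vteprophy
Title: Counterfactual Evaluation of Venous Thromboembolism Prophylaxis Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the clinical impact and efficiency of
    pharmacological venous thromboembolism (VTE) prophylaxis policies in
    medical inpatients. Given per-patient predicted VTE and major-bleeding
    probabilities, point scores (Padua, IMPROVE) and observed prescribing,
    the package assigns prophylaxis under rule-based strategies, adjusts
    risks by the relative efficacy and harm of anticoagulant prophylaxis,
    computes expected event rates per 1,000 patients, derives the
    incremental number-needed-to-treat efficiency frontier across
    strategies, and sweeps a sensitivity grid over efficacy and harm
    assumptions. A calibrated synthetic cohort generator emulates the risk
    distributions and physician prescribing behaviour the analysis assumes,
    and a Monte-Carlo simulator provides an independent check of the
    analytic expectations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
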