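Package: acsmarkov
Title: Decision-Analytic Markov Model of Adjunctive Chinese Herbal
    Medicine After PCI in Acute Coronary Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two-component decision-analytic model for long-term outcome
    projection in acute coronary syndrome (ACS) patients after
    percutaneous coronary intervention (PCI): a one-year decision tree
    over five clinical outcomes feeding an eight-state Markov cohort
    model with tunnel states for first-year post-event risks, run to a
    ten-year horizon. Compares six months of adjunctive Chinese herbal
    medicine (CHM) plus conventional treatment against conventional
    treatment alone in terms of survival, discounted quality-adjusted
    life years (QALYs) with half-cycle correction, and per-1000-patient
    event counts. Includes univariate (tornado) sensitivity analysis
    over the published parameter ranges, a YAML parameter format with
    validation, and generators for randomised and degenerate parameter
    scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
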