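Package: hfspanel
Title: Health Financing System Transitions and Health System Outcomes in
    Country-Year Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how transitions between predominant health
    financing systems (out-of-pocket, social health insurance, government
    financed) affect health system outcomes in long country-year panels.
    Classifies country-years into financing systems by k-means clustering on
    expenditure shares, detects durable financing transitions, estimates
    two-way fixed-effects difference-in-differences models with
    cluster-robust inference, and runs a battery of specification tests:
    random-trend (Clogg-style) coefficient comparisons, differential-trend
    nonlinear parallel-trend restrictions, lead-based reverse-causality
    tests, and a Goodman-Bacon timing decomposition. Includes a synthetic
    panel generator with planted regimes, transition schedules and known
    treatment effects for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
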