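Package: cuewheel
Title: Simulation and Hierarchical Bayesian Analysis of Spatial-Cueing
    Colour-Wheel Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continuous-report (colour-wheel) Posner cueing
    experiments. Generates counterbalanced trial schedules for endogenous
    (central symbolic cue) and exogenous (peripheral flash) designs,
    simulates trial-level responses under a uniform + von Mises mixture
    for colour report and a lognormal model for reaction time, applies
    standard trial-exclusion rules (practice, misses, false alarms,
    pre-target responses, 5xMADM reaction-time outliers), fits a
    hierarchical Bayesian mixed-effects model that separates the
    probability and the fidelity of colour encoding by cue condition,
    and summarises cueing effects with highest-density intervals and a
    credibility classification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
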