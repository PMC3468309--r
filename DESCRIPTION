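Package: smokesim
Title: Continuous-Time Life-Course Microsimulation of Smoking and
    Competing Causes of Death
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A continuous-time, individual-level life-course model of
    cigarette smoking and 20+ competing causes of death. Smoking
    initiation (constant hazard through age 24) and age-banded cessation
    are simulated as an absorbing multistate process; death age and cause
    are drawn by exact inversion sampling over piecewise-constant
    cause-specific hazards modified by smoking-state relative risks.
    Includes a deterministic survival oracle, a counterfactual scenario
    engine (attributable deaths, life-expectancy decompositions,
    timing-of-benefit gain curves), direct age standardization,
    calibration of initiation and cessation rates to cross-sectional
    survivor prevalence, a piecewise-exponential proportional-hazards
    estimator of smoking relative risks, and a synthetic-input generator
    for hazard tables, relative-risk tables and linked survey-like
    records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
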