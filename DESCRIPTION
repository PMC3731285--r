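Package: strokecea
Title: Before/After Cost-Effectiveness Modelling of Centralized Acute Stroke Care
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-analytic pipeline for comparative-effectiveness and
    cost-effectiveness evaluation of hospital stroke-pathway reconfiguration.
    Provides a synthetic stroke-register generator, Kaplan-Meier, Cox and
    Weibull survival estimation, two time-dependent Markov cohort models (an
    admission-to-90-day model on ward and discharge states with daily cycles,
    and a 90-day-to-10-year model on residence and disability states with
    90-day cycles), national-trend adjustments to mortality and stroke-unit
    length of stay, cost and QALY accrual with discounting, deterministic
    scenario analysis, and probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    stats,
    jsonlite,
    yaml,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
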