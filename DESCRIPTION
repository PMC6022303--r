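Package: wlmcea
Title: Long-Term Outcomes and Cost-Effectiveness of Weight-Management Programmes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for the long-term follow-up of a men's
    weight-management trial: longitudinal within- and between-group change
    estimation with missing-data sensitivity analyses (baseline-carried-forward,
    last-observation-carried-forward), construction of hypothetical
    'no active intervention' counterfactual scenarios by weight-trajectory
    extrapolation, within-trial cost and QALY accumulation, a simplified
    risk-factor-driven state-transition model for lifetime extrapolation, and
    probabilistic sensitivity analysis with cost-effectiveness acceptability
    curves. A seeded synthetic-cohort generator calibrated to published summary
    statistics stands in for the (non-public) individual-level trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
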