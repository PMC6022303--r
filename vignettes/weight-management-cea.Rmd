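---
title: "Methods: long-term outcomes and cost-effectiveness of a weight-management programme"
author: "wlmcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term outcomes and cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What this package models

A men's group-based weight-management programme delivered through 13
professional football clubs was followed up 3.5 years after trial baseline.
The original comparison group took up the programme right after its
12-month measures, so no concurrent control exists beyond 12 months. The
analysis chain this package implements is therefore:

1. **Longitudinal change estimation** — within- and between-group weight
   (and SBP) changes at 3.5 years, responder proportions (≥ 5% loss,
   inclusive threshold), annualized regain, and missing-data sensitivity
   analyses (baseline-carried-forward, last-observation-carried-forward)
   over the full randomized denominators.
2. **Counterfactual construction** — six hypothetical 'no active
   intervention' control scenarios obtained by extrapolating
   comparison-group weights linearly from an anchor (trial baseline or the
   12-month measures) at either an average population weight-gain rate
   (0.46 kg/year) or the intervention group's own 12-month→3.5-year regain
   rate, optionally excluding the comparison-group men who had already lost
   ≥ 5% at 12 months.
3. **Within-trial cost–utility** — discounted (3.5%/year) per-participant
   costs (programme delivery, recall-window NHS resource use, £16 per
   BMI-unit-year imputation on BMI increases) and QALYs (trapezoidal
   integration of utilities on the grid {0, 0.23, 1, 3.5} years), giving an
   incremental cost-effectiveness ratio per scenario.
4. **Lifetime extrapolation** — a simplified four-state annual-cycle cohort
   Markov model (well → CVD → CVD death / other-cause death) in which BMI
   and SBP are the modifiable risk factors multiplying the CVD-incidence
   hazard.
5. **Uncertainty** — probabilistic sensitivity analysis through the
   lifetime model and cost-effectiveness acceptability curves under the
   net-monetary-benefit rule, plus a limited-effect sensitivity analysis
   (risk-factor benefit confined to 5.5 years from baseline).

Because the study's individual-level data are not public, a seeded
synthetic-cohort generator calibrated to the published summary statistics
stands in for them; all downstream code consumes its participant-level
tables and would equally consume real data with the same schema.

## The synthetic cohort: what it emulates and what it does not

The generator reproduces, by construction:

* baseline moments — weight 109.5 (SD 17.3) kg, SBP 140.3 (16.3) mmHg, age
  47.1 (8.0) y, 374 + 373 men in 13 clubs;
* marginal weight-change distributions at 12 months and 3.5 years per
  group, with SDs back-computed from the published 95% CIs
  (SD = half-width/1.96 × √n), e.g. the intervention 3.5-year change
  −2.90 (−4.02, −1.78) at n = 233 gives SD 8.72 kg;
* the attrition pattern — consent probability 665/747, then logistic
  attendance on the baseline-weight z-score (intercept 1.10 ≈
  logit(488/665), slope −0.35) so that non-attenders are heavier, matching
  the published 112.6 vs 107.8 kg contrast; a 37/488 chance of providing
  weight-only data at 3.5 years;
* a latent linear utility–BMI law (intercept 1.05, slope −0.008/BMI unit,
  residual SD 0.05 on the SF-6D-like scale) and Poisson resource-use counts
  per 12-week recall window.

Design choices where the publication is silent, fixed once:

* **Joint trajectory model.** Per-person changes at the three follow-up
  points are multivariate normal with exchangeable correlation 0.8 — only
  marginal summaries are published; 0.8 reflects the strong tracking of
  repeated adult weights and is exposed as a configuration field.
* **Height** is simulated once per person (N(1.76, 0.07) m; never
  published) so BMI = weight/height² tracks weight deterministically.
* **No 12-week measurement for the comparison group** (none was conducted);
  QALY integration runs over each participant's observed sub-grid.
* **Resource-use rates** (GP 1.2, practice nurse 0.5, physiotherapist 0.15,
  A&E 0.08, inpatient day 0.04, outpatient 0.30, prescriptions 2.0 per
  12-week window) were chosen, together with the illustrative unit-cost
  table in `inst/extdata/unit_costs.csv`, so that the expected discounted
  3.5-year cost per intervention participant is close to the published
  ≈ £2450 mean. Both arms share the same rates: the generator takes no
  stance on whether the programme changes health-care-seeking behaviour.

Consequences worth knowing: the published 11% responder fraction in the
comparison group at 12 months is *not* reproduced by the default world —
a normal change distribution with the CI-derived SD (5.25 kg) implies ≈ 18%.
The two published figures cannot be reconciled under normality; we keep the
CI-derived SD as the primary calibration and exercise the 11% figure with a
purpose-calibrated spec in the tests. Similarly, because both arms share
resource-use rates, the within-trial incremental cost is dominated by the
programme cost (£61,700/374 = £164.97) minus the counterfactual's
BMI-linked imputation, and is small and noisy across seeds — unlike the
published £532–£740, which reflects unpublished between-arm differences in
observed resource use. The published ICER bands are therefore not
reproduction targets; the qualitative orderings (lifetime more favourable
than within-trial; CEAC crossing far below £20,000/QALY) are.

## Statistical choices

* Within-group changes use the paired t (CI and p), with the Wilcoxon
  signed-rank p alongside; between-group contrasts use Welch's t with the
  Mann-Whitney p alongside. The source report mixes the two families
  between its methods and table footnotes, so both are always emitted.
* The responder threshold is inclusive (≥ 5.000%).
* Elapsed-time constants follow the measurement labels: baseline→12 m =
  1.0 y, 12 m→42 m = 2.5 y.
* The repeated-measures model is `change ~ baseline (centred) + timepoint
  [+ group × timepoint]` with random intercepts for participant and club
  (lme4, REML); adjusted means are evaluated at the mean baseline, and
  contrasts use Wald 95% intervals. Singular fits (a variance component at
  zero) are tolerated, matching the reduction-to-OLS limit.
* The attender/non-attender comparison chooses Welch t, Mann-Whitney, or
  chi-squared per declared variable type, switching to Fisher's exact when
  any expected cell is ≤ 5 (the conservative variant of the usual rule).
* No multiplicity adjustment anywhere, mirroring the source analysis.
* The utility–BMI regression is OLS with CR1 cluster-robust standard errors
  on participant (M/(M−1) × (N−1)/(N−K) small-sample factor); linear in
  BMI — the minimal reading of "regressed against BMI"; age is excluded as
  it was dropped in the source analysis. Predictions clamp to [0, 1].

## Costing conventions

* Discounting is annual-compound with fractional exponents,
  `x/(1.035)^t`; the compounding convention is unstated in the source and
  continuous-in-t annual compounding is the NICE-consistent default.
* Each measurement's 12-week recall window is treated as representative of
  the inter-measurement period it closes; window costs are scaled by
  period/window length and discounted at the period midpoint. Missing
  questionnaires contribute the arm-mean window cost (mean imputation), so
  the ledger is defined for every randomized participant. The baseline
  window (pre-trial) is excluded.
* The £16 per BMI-unit-year imputation applies to BMI *increases* only over
  12 m→3.5 y; decreases impute £0 (no negative costs — the source does not
  say whether savings were credited).
* Counterfactual controls carry no programme cost; their background
  resource use is the comparison group's own, and their extrapolated
  segment incurs the BMI-linked imputation on the counterfactual BMI rise.
* £61,700/374 = £164.97, which rounds to £165, not the published £164; the
  exact quotient is used and the rounding discrepancy left alone.

## The lifetime model

The original proprietary CVD policy model is out of scope; this module is
an openly parameterized simplification with the same interface role.
States: well, CVD, CVD death, other-cause death (dead states absorbing).
Baseline annual transition probabilities are an illustrative fixture by
5-year age band (50–95+), rising with age with the qualitative shape of
population rates (`default_transition_table()`); they are *synthetic* and
clearly labelled so. Risk-factor modification converts the well→CVD
probability to a hazard, multiplies by
`hr_per_bmi_unit^ΔBMI × hr_per_mmhg_sbp^ΔSBP` (defaults 1.05 and 1.015,
within the range of published cohort estimates), and converts back:
`p' = 1 − (1 − p)^HR`. Well-state utility follows the fitted utility–BMI
line; CVD carries a 0.15 decrement; state costs are £300 (well) and £2200
(CVD) per year.

Numerical conventions (all unstated in the source, all configurable):
annual cycles; half-cycle correction (trapezoid of successive occupancies,
discounted at the cycle midpoint); terminal age 100; cohort-level
deterministic traces run per observed starting age and averaged with
empirical weights. A constant-mortality check places the half-cycle life
expectancy at 9.5 years against the geometric-series value of 10 for
p = 0.1, inside the conventional 8.5–9.5 correction band. An
individual-level microsimulation mode was considered and rejected: the PSA
already propagates parameter uncertainty, and a deterministic trace keeps
the engine exactly verifiable against a matrix-power oracle.

The limited-effect sensitivity analysis confines the intervention arm's
risk-factor advantage to `total_effect_years − 3.5` beyond model start
(default 5.5 − 3.5 = 2 years), after which the arm reverts to the control
profile; its incremental gain can never exceed the lifelong-effect run.

## PSA and acceptability curves

Uncertain parameters are drawn from support-respecting families (lognormal
hazard ratios, normal risk-factor advantages and utility slope, gamma CVD
state cost, normal within-trial incremental cost; ~10–20% coefficients of
variation, illustrative). Each draw reruns the deterministic lifetime model
for both arms. The CEAC is the fraction of draws with positive net monetary
benefit λ·ΔQ − ΔC at each willingness-to-pay λ on a £0–£50,000 grid in
£250 steps (covering UK decision thresholds); the 50% crossing is located
by linear interpolation between bracketing grid points, reporting the first
grid point when the curve starts above target and a sentinel `NA` when it
never reaches it. The NMB formulation avoids the ICER's quadrant ambiguity;
the deterministic ICER itself is reported with dominance labels
(`dominant`, `dominated`, `undefined`) rather than exceptions.

## Degenerate inputs and tie-breaks

Zero-variance change pairs are flagged (`zero_variance`) with a degenerate
CI rather than an error; zero SDs anywhere in the generator are legal (the
covariance square root uses a symmetric eigendecomposition, so
semidefinite cases including correlation 1 are handled); extreme hazard
deltas clamp the adjusted probability just below 1; a missing anchor weight
skips the participant with a logged warning; an unpriced resource type is a
named error, as is a single-cluster utility regression.

## What a green test run establishes — and what it does not

The tests verify exact in-study arithmetic (annualized regain, imputation
means, responder fractions, the SBP rule), moment calibration of the
generator, parameter recovery for the mixed model and the utility
regression, machine-precision agreement of the Markov engine with a
matrix-power oracle, closed-form discounting and CEAC limit identities, and
the qualitative economic orderings on the calibrated synthetic world. They
do not — and cannot — establish the published ICER bands or QALY gains,
which depend on unpublished individual-level data and a proprietary
lifetime parameterization; those quantities are reported by the pipeline
for the synthetic world and should be read as method demonstrations, not
replications.
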