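#' Impute a systolic blood pressure change from a fractional weight change
#'
#' Linear scaling of the systematic-review finding that a 10% weight loss
#' equates to a 6.1 mmHg drop in SBP: delta_SBP = 61 * weight_change_fraction
#' (so -0.10 -> -6.1 mmHg, +0.10 -> +6.1 mmHg).
#'
#' @param weight_change_fraction Fractional weight change in (-1, 1);
#'   negative = loss.
#' @return SBP change in mmHg (negative = drop).
#' @export
impute_sbp_change <- function(weight_change_fraction) {
  if (any(abs(weight_change_fraction) >= 1, na.rm = TRUE))
    stop("weight_change_fraction must be in (-1, 1)")
  -6.1 * (-weight_change_fraction / 0.10)
}

#' Illustrative baseline annual transition probabilities by 5-year age band
#'
#' A simplified, openly parameterized stand-in for a proprietary
#' cardiovascular policy model: synthetic, illustrative values with the
#' qualitative shape of population rates (incidence and mortality rising
#' with age). Columns: `age_band_start` and annual probabilities
#' `p_well_cvd`, `p_well_dead_other`, `p_cvd_dead_cvd`, `p_cvd_dead_other`.
#'
#' @return Data.frame, one row per 5-year band from age 50 to 95.
#' @export
default_transition_table <- function() {
  data.frame(
    age_band_start = seq(50, 95, 5),
    p_well_cvd = c(0.006, 0.009, 0.013, 0.019, 0.028, 0.040,
                   0.058, 0.082, 0.115, 0.160),
    p_well_dead_other = c(0.003, 0.005, 0.008, 0.013, 0.021, 0.034,
                          0.056, 0.092, 0.150, 0.250),
    p_cvd_dead_cvd = c(0.040, 0.045, 0.050, 0.055, 0.060, 0.070,
                       0.080, 0.100, 0.130, 0.170),
    p_cvd_dead_other = c(0.004, 0.006, 0.010, 0.016, 0.025, 0.041,
                         0.067, 0.110, 0.180, 0.300)
  )
}

#' Parameters of the lifetime state-transition model
#'
#' Four states: `well`, `cvd`, `dead_cvd`, `dead_other`; dead states
#' absorbing. BMI and SBP are the modifiable risk factors: they multiply the
#' `well -> cvd` hazard via per-unit hazard ratios relative to the reference
#' risk profile at which the baseline transition table is defined. Well-state
#' utility follows the fitted utility-vs-BMI line; CVD carries a utility
#' decrement. The default numeric parameterization is illustrative (see
#' [default_transition_table()]).
#'
#' @param transitions Transition table as in [default_transition_table()].
#' @param hr_per_bmi_unit Hazard ratio on `well -> cvd` per BMI unit above
#'   reference.
#' @param hr_per_mmhg_sbp Hazard ratio on `well -> cvd` per mmHg SBP above
#'   reference.
#' @param ref_bmi,ref_sbp Reference risk profile of the baseline table.
#' @param utility_intercept,utility_slope Well-state utility line in BMI.
#' @param cvd_utility_decrement Utility lost in the CVD state.
#' @param state_costs Annual costs (GBP/year) named `well`, `cvd` (dead
#'   states cost 0).
#' @param discount_rate Annual discount rate (default 0.035).
#' @param max_age Terminal model age (default 100).
#' @param effect_duration_years Years beyond model start during which the
#'   intervention arm keeps its own risk profile before reverting to the
#'   control profile; `Inf` = lifelong.
#' @param half_cycle Apply half-cycle correction (default TRUE).
#' @return `lifetime_params` list.
#' @export
lifetime_params <- function(transitions = default_transition_table(),
                            hr_per_bmi_unit = 1.05,
                            hr_per_mmhg_sbp = 1.015,
                            ref_bmi = 35, ref_sbp = 140,
                            utility_intercept = 1.05,
                            utility_slope = -0.008,
                            cvd_utility_decrement = 0.15,
                            state_costs = c(well = 300, cvd = 2200),
                            discount_rate = 0.035,
                            max_age = 100,
                            effect_duration_years = Inf,
                            half_cycle = TRUE) {
  p <- list(transitions = transitions, hr_per_bmi_unit = hr_per_bmi_unit,
            hr_per_mmhg_sbp = hr_per_mmhg_sbp, ref_bmi = ref_bmi,
            ref_sbp = ref_sbp, utility_intercept = utility_intercept,
            utility_slope = utility_slope,
            cvd_utility_decrement = cvd_utility_decrement,
            state_costs = state_costs, discount_rate = discount_rate,
            max_age = max_age, effect_duration_years = effect_duration_years,
            half_cycle = half_cycle)
  stopifnot(hr_per_bmi_unit > 0, hr_per_mmhg_sbp > 0,
            all(unlist(transitions[, -1]) >= 0),
            all(unlist(transitions[, -1]) <= 1),
            all(transitions$p_well_cvd + transitions$p_well_dead_other <= 1),
            all(transitions$p_cvd_dead_cvd + transitions$p_cvd_dead_other <= 1),
            discount_rate > -1, max_age > 0)
  class(p) <- "lifetime_params"
  p
}

#' Adjust a baseline transition probability by risk-factor hazard ratios
#'
#' Probability -> hazard -> multiply by
#' `hr_per_bmi_unit^bmi_delta * hr_per_mmhg_sbp^sbp_delta` -> probability:
#' p' = 1 - (1 - p)^(HR product). Exact for constant hazards within a cycle.
#'
#' @param baseline_prob Annual probability in [0, 1).
#' @param bmi_delta BMI units above the reference profile.
#' @param sbp_delta mmHg above the reference profile.
#' @param params A [lifetime_params()].
#' @return Adjusted probability in [0, 1).
#' @export
adjust_transition <- function(baseline_prob, bmi_delta, sbp_delta, params) {
  stopifnot(all(baseline_prob >= 0), all(baseline_prob < 1))
  hr <- params$hr_per_bmi_unit^bmi_delta * params$hr_per_mmhg_sbp^sbp_delta
  # clamp just below 1 so the result stays a usable probability even when
  # extreme deltas drive the hazard to floating-point saturation
  pmin(1 - (1 - baseline_prob)^hr, 1 - .Machine$double.eps)
}

transition_row <- function(params, age) {
  tb <- params$transitions
  i <- findInterval(age, tb$age_band_start)
  i <- pmin(pmax(i, 1), nrow(tb))
  tb[i, , drop = FALSE]
}

# Annual-cycle Markov trace for one arm at one starting age.
# bmi/sbp: functions of cycle time (years since model start) giving the arm's
# current risk-factor values. Returns discounted QALYs, costs, life-years.
trace_one_age <- function(start_age, bmi_fun, sbp_fun, params) {
  n_cycles <- max(0, floor(params$max_age - start_age))
  occ <- c(well = 1, cvd = 0, dead_cvd = 0, dead_other = 0)
  qaly <- cost <- ly <- 0
  trace <- matrix(NA_real_, n_cycles + 1, 4,
                  dimnames = list(NULL, names(occ)))
  trace[1, ] <- occ
  for (k in seq_len(n_cycles)) {
    t0 <- k - 1
    age <- start_age + t0
    tr <- transition_row(params, age)
    bmi <- bmi_fun(t0); sbp <- sbp_fun(t0)
    p_wc <- adjust_transition(tr$p_well_cvd, bmi - params$ref_bmi,
                              sbp - params$ref_sbp, params)
    p_wd <- tr$p_well_dead_other
    p_cd <- tr$p_cvd_dead_cvd
    p_co <- tr$p_cvd_dead_other
    # guard: adjusted CVD incidence cannot push the row sum past 1
    p_wc <- min(p_wc, 1 - p_wd)
    P <- rbind(well = c(1 - p_wc - p_wd, p_wc, 0, p_wd),
               cvd = c(0, 1 - p_cd - p_co, p_cd, p_co),
               dead_cvd = c(0, 0, 1, 0),
               dead_other = c(0, 0, 0, 1))
    occ_next <- drop(occ %*% P)
    u_well <- min(max(params$utility_intercept + params$utility_slope * bmi, 0), 1)
    u <- c(u_well, max(u_well - params$cvd_utility_decrement, 0), 0, 0)
    cst <- c(params$state_costs[["well"]], params$state_costs[["cvd"]], 0, 0)
    alive <- c(1, 1, 0, 0)
    w <- if (params$half_cycle) (occ + occ_next) / 2 else occ_next
    df <- 1 / (1 + params$discount_rate)^(t0 + 0.5)
    qaly <- qaly + df * sum(w * u)
    cost <- cost + df * sum(w * cst)
    ly <- ly + df * sum(w * alive)
    occ <- occ_next
    trace[k + 1, ] <- occ
  }
  list(qaly = qaly, cost = cost, life_years = ly, trace = trace)
}

#' Markov occupancy trace for a single starting age and fixed risk profile
#'
#' Exposes the raw annual-cycle trace (state occupancy per cycle) for
#' inspection and for verifying conservation/absorption properties.
#'
#' @param start_age Starting age.
#' @param bmi,sbp Constant risk-factor values for the whole horizon.
#' @param params A [lifetime_params()].
#' @return List `(qaly, cost, life_years, trace)`; `trace` is a matrix of
#'   occupancies (rows = cycles incl. start, cols = states).
#' @export
markov_trace <- function(start_age, bmi, sbp, params) {
  trace_one_age(start_age, function(t) bmi, function(t) sbp, params)
}

#' Run the lifetime model for both arms and report incremental results
#'
#' Cohort-level deterministic Markov trace from the 3.5-year follow-up to
#' `max_age`, annual cycles, discounted QALY/cost accumulation with
#' half-cycle correction. Each arm's risk profile is its mean BMI and SBP at
#' follow-up; the intervention arm keeps its profile for
#' `effect_duration_years` after model start, then reverts to the control
#' profile (lifelong when `Inf`). The control arm always uses its own
#' profile.
#'
#' @param profiles List with elements `intervention` and `control`, each a
#'   list `(bmi, sbp)` of mean risk-factor values at follow-up.
#' @param params A [lifetime_params()].
#' @param start_ages Integer vector of starting ages (age at the 3.5-year
#'   follow-up), one per participant or a weighted sample; traces are run per
#'   unique age and averaged with the empirical weights.
#' @return `lifetime_result`: list with per-arm discounted `qaly`, `cost`,
#'   `life_years`, and `incremental` (intervention minus control) for each.
#' @export
run_cohort_lifetime <- function(profiles, params, start_ages = 51) {
  stopifnot(inherits(params, "lifetime_params"),
            all(c("intervention", "control") %in% names(profiles)))
  ages <- round(start_ages)
  wt <- table(ages) / length(ages)
  uages <- as.numeric(names(wt))

  ctrl <- profiles$control
  intv <- profiles$intervention
  dur <- params$effect_duration_years
  arm_funs <- list(
    intervention = list(
      bmi = function(t) if (t < dur) intv$bmi else ctrl$bmi,
      sbp = function(t) if (t < dur) intv$sbp else ctrl$sbp),
    control = list(
      bmi = function(t) ctrl$bmi,
      sbp = function(t) ctrl$sbp)
  )
  arm_res <- lapply(arm_funs, function(f) {
    per_age <- lapply(uages, function(a) trace_one_age(a, f$bmi, f$sbp, params))
    list(qaly = sum(vapply(per_age, `[[`, 0, "qaly") * wt),
         cost = sum(vapply(per_age, `[[`, 0, "cost") * wt),
         life_years = sum(vapply(per_age, `[[`, 0, "life_years") * wt))
  })
  structure(list(
    intervention = arm_res$intervention,
    control = arm_res$control,
    incremental = list(
      qaly = arm_res$intervention$qaly - arm_res$control$qaly,
      cost = arm_res$intervention$cost - arm_res$control$cost,
      life_years = arm_res$intervention$life_years - arm_res$control$life_years)
  ), class = "lifetime_result")
}

#' Limited-effect-duration sensitivity analysis
#'
#' Reruns the lifetime model with the intervention's risk-reduction impact
#' limited to `total_effect_years` in total (counted from trial baseline);
#' the model starts at the 3.5-year follow-up, so the arm keeps its profile
#' for `total_effect_years - 3.5` years and then reverts. The default 5.5
#' years corresponds to 2 years beyond follow-up. Incremental QALY gain is
#' necessarily no larger than with an unlimited duration.
#'
#' @param profiles,params,start_ages As in [run_cohort_lifetime()].
#' @param total_effect_years Total effect duration from baseline; >= 3.5.
#' @return `lifetime_result`.
#' @export
limited_effect_sensitivity <- function(profiles, params, start_ages = 51,
                                       total_effect_years = 5.5) {
  stopifnot(total_effect_years >= 3.5)
  params$effect_duration_years <- total_effect_years - 3.5
  run_cohort_lifetime(profiles, params, start_ages)
}
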