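#' The six hypothetical 'no active intervention' scenarios
#'
#' The comparison group undertook the programme right after its 12-month
#' measures, so it cannot serve as a 3.5-year control. Six counterfactual
#' scenarios are constructed instead, crossed over (a) the anchor from which
#' comparison-group data are extrapolated (trial baseline, or the 12-month
#' measures), (b) the assumed annual weight-gain rate (average population
#' trajectory, 0.46 kg/year, or the intervention group's own 12-month to
#' 3.5-year regain rate), and (c) whether the ~11% of comparison-group men
#' who had already lost >= 5% of baseline weight at 12 months are excluded.
#'
#' @param population_rate Population weight-gain rate, kg/year (default 0.46).
#' @param responder_threshold_pct Exclusion threshold, percent (default 5).
#' @return Data.frame of six `ScenarioSpec` rows: `scenario_id`, `anchor`,
#'   `rate_source`, `exclude_12m_responders`, `responder_threshold_pct`,
#'   `population_rate`.
#' @export
list_scenarios <- function(population_rate = 0.46,
                           responder_threshold_pct = 5) {
  data.frame(
    scenario_id = c("base", "s1", "s2", "s3", "s4", "s5"),
    anchor = c("baseline", "baseline", rep("month12", 4)),
    rate_source = rep(c("population", "ffit_regain"), 3),
    exclude_12m_responders = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    responder_threshold_pct = responder_threshold_pct,
    population_rate = population_rate,
    stringsAsFactors = FALSE
  )
}

#' Intervention-group annual regain rate between 12 months and 3.5 years
#'
#' Mean 12-month to 42-month weight change among intervention participants
#' with both measurements, divided by 2.5 years. In the emulated study this
#' is 2.59 kg / 2.5 y = 1.04 kg/year, the rate used to build the
#' `ffit_regain` counterfactual trajectories.
#'
#' @param cohort Wide cohort data.frame.
#' @return kg/year (scalar).
#' @export
ffit_regain_rate <- function(cohort) {
  d <- cohort[cohort$group == "intervention", ]
  ok <- !is.na(d$weight_m12) & !is.na(d$weight_m42)
  if (!any(ok)) stop("intervention group needs both 12 m and 42 m weights")
  annualized_rate(mean(d$weight_m42[ok] - d$weight_m12[ok]), 2.5)
}

#' Remove comparison-group participants with >= threshold% loss at 12 months
#'
#' @param cohort Wide cohort data.frame (rows restricted to the comparison
#'   group by the caller or internally — only comparison rows are filtered).
#' @param threshold_pct Loss threshold, percent (default 5; inclusive).
#' @return List `(cohort, excluded_ids, excluded_fraction)`; the fraction is
#'   relative to comparison-group members with observed 12-month weight.
#' @export
apply_responder_exclusion <- function(cohort, threshold_pct = 5) {
  comp <- cohort$group == "comparison"
  loss_frac <- (cohort$weight_baseline - cohort$weight_m12) /
    cohort$weight_baseline
  is_resp <- comp & !is.na(loss_frac) & loss_frac >= threshold_pct / 100
  denom <- sum(comp & !is.na(loss_frac))
  list(cohort = cohort[!is_resp, ],
       excluded_ids = cohort$participant_id[is_resp],
       excluded_fraction = if (denom > 0) sum(is_resp) / denom else 0)
}

#' Extrapolate counterfactual weights along a linear trajectory
#'
#' weight(t) = anchor_weight + rate * (t - anchor_time) for t beyond the
#' anchor; before the anchor, observed data are retained as-is (for
#' month12-anchored scenarios the observed baseline-to-12-month segment is
#' kept). BMI is recomputed from the person's height.
#'
#' @param anchor_weight Weight at the anchor (kg).
#' @param anchor_time Anchor time (years since baseline).
#' @param rate Weight-gain rate (kg/year).
#' @param t Evaluation times (years since baseline), each >= anchor_time.
#' @return Extrapolated weights (kg).
#' @export
extrapolate_weight <- function(anchor_weight, anchor_time, rate, t) {
  stopifnot(all(t >= anchor_time - 1e-9))
  anchor_weight + rate * (t - anchor_time)
}

#' Build a counterfactual cohort under one scenario
#'
#' Takes the comparison group, applies the scenario's responder exclusion if
#' any, and extrapolates each participant's weight from the scenario anchor
#' to 3.5 years (plus any requested intermediate cycle times) at the
#' scenario's rate. Counterfactual BMI is recomputed from height;
#' counterfactual SBP at 3.5 years is the baseline SBP adjusted by the linear
#' SBP imputation rule applied to the weight change fraction
#' ([impute_sbp_change()]); counterfactual utility comes from the fitted
#' utility-vs-BMI regression when `utility_model` is supplied.
#'
#' Participants without an observed anchor weight are skipped with a warning.
#'
#' @param cohort Wide cohort data.frame.
#' @param scenario One row of [list_scenarios()] (data.frame or list).
#' @param regain_rate kg/year used when `rate_source == "ffit_regain"`;
#'   typically [ffit_regain_rate()] of the same cohort.
#' @param times Evaluation times (years since baseline) at which
#'   counterfactual weights are produced; default the follow-up grid plus
#'   endpoint.
#' @param utility_model Optional [fit_utility_bmi()] model for counterfactual
#'   utilities.
#' @return Long data.frame: `participant_id`, `scenario_id`, `time_years`,
#'   `weight`, `bmi`, `sbp`, `utility`, `observed` (TRUE where the value is
#'   retained observed data rather than extrapolation).
#' @export
build_counterfactual <- function(cohort, scenario, regain_rate = NULL,
                                 times = c(0, 12 / 52, 1, 3.5),
                                 utility_model = NULL) {
  if (is.data.frame(scenario)) scenario <- as.list(scenario[1, ])
  comp <- cohort[cohort$group == "comparison", ]
  if (isTRUE(scenario$exclude_12m_responders)) {
    comp <- apply_responder_exclusion(
      comp, scenario$responder_threshold_pct)$cohort
  }
  rate <- if (scenario$rate_source == "population") {
    scenario$population_rate
  } else {
    if (is.null(regain_rate)) regain_rate <- ffit_regain_rate(cohort)
    regain_rate
  }
  anchor_time <- if (scenario$anchor == "baseline") 0 else 1
  anchor_col <- if (scenario$anchor == "baseline") "weight_baseline" else "weight_m12"
  miss <- is.na(comp[[anchor_col]])
  if (any(miss)) {
    warning(sum(miss), " participant(s) skipped: anchor weight missing")
    comp <- comp[!miss, ]
  }
  out <- do.call(rbind, lapply(times, function(t) {
    if (t < anchor_time - 1e-9) {
      # observed segment retained (month12-anchored scenarios): linear in t
      # between the observed baseline and 12-month weights
      w <- comp$weight_baseline +
        (comp$weight_m12 - comp$weight_baseline) * t
      observed <- TRUE
    } else {
      w <- extrapolate_weight(comp[[anchor_col]], anchor_time, rate, t)
      observed <- abs(t - anchor_time) < 1e-9
    }
    data.frame(participant_id = comp$participant_id,
               scenario_id = scenario$scenario_id,
               time_years = t, weight = w, bmi = w / comp$height^2,
               observed = observed, stringsAsFactors = FALSE)
  }))
  # counterfactual SBP: baseline SBP shifted by the imputation rule on the
  # weight change fraction relative to baseline
  base_w <- comp$weight_baseline[match(out$participant_id, comp$participant_id)]
  base_sbp <- comp$sbp_baseline[match(out$participant_id, comp$participant_id)]
  frac <- (out$weight - base_w) / base_w
  out$sbp <- base_sbp + impute_sbp_change(pmin(pmax(frac, -0.99), 0.99))
  out$utility <- if (!is.null(utility_model)) {
    predict_utility(utility_model, out$bmi)
  } else NA_real_
  rownames(out) <- NULL
  out
}
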