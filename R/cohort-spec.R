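#' Specification of a synthetic trial cohort
#'
#' Bundles the parameters that govern the synthetic-cohort generator:
#' group sizes, baseline moments, per-group weight-change trajectories,
#' within-person correlation, the attrition (dropout) model, the latent
#' utility-vs-BMI model, and per-window resource-use rates.
#'
#' Defaults are calibrated to the published summary statistics of a 3.5-year
#' follow-up of a men's weight-management trial: 374 + 373 participants in 13
#' clubs; baseline weight 109.5 (SD 17.3) kg; systolic blood pressure 140.3
#' (SD 16.3) mmHg; age 47.1 (SD 8.0) years; intervention-group mean weight
#' change of -5.49 kg at 12 months and -2.90 kg at 3.5 years; comparison-group
#' change of -0.68 kg at 12 months and -2.71 kg at 3.5 years. Change SDs are
#' back-computed from the printed 95% confidence intervals at the printed n.
#'
#' The comparison group has no post-programme (12-week) measurement in the
#' emulated study; its 12-week change defaults to `NA` (absent).
#'
#' @param n_intervention,n_comparison Randomized group sizes.
#' @param n_clubs Number of delivery clubs (shared random-effect grouping).
#' @param baseline_weight_mean,baseline_weight_sd Baseline weight moments (kg).
#' @param baseline_sbp_mean,baseline_sbp_sd Baseline systolic BP (mmHg).
#' @param baseline_age_mean,baseline_age_sd Baseline age (years).
#' @param height_mean,height_sd Height (m); never reported in the emulated
#'   study, simulated once per person so BMI tracks weight deterministically.
#' @param change_profile Named list `intervention`/`comparison`, each a list
#'   with numeric vectors `mean` and `sd` of weight change (kg) at the
#'   timepoints `w12`, `m12`, `m42`. `NA` mean marks an unmeasured timepoint.
#' @param within_person_correlation Exchangeable correlation of a person's
#'   weight changes across timepoints, in [0, 1].
#' @param dropout_model List `(intercept, slope)`: logistic model of 3.5-year
#'   attendance on the baseline-weight z-score. Negative slope makes heavier
#'   men less likely to attend, as observed (112.6 vs 107.8 kg).
#' @param consent_prob Probability of consent to long-term follow-up (665/747).
#' @param weight_only_prob Probability an attender provides weight-only data
#'   (37/488).
#' @param utility_model_true List `(intercept, slope, resid_sd)` of the latent
#'   linear utility-vs-BMI model on the SF-6D-like [0, 1] scale.
#' @param resource_use_rates Named numeric vector: mean count per 12-week
#'   recall window, by resource type. Names must match a unit-cost table.
#' @param sbp_change_per_kg mmHg change in SBP per kg weight change used when
#'   simulating follow-up SBP (observational coupling, distinct from the
#'   counterfactual imputation rule).
#' @param seed Integer seed; the generator is fully reproducible given it.
#'
#' @return An object of class `cohort_spec` (validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_intervention = 374L,
                        n_comparison = 373L,
                        n_clubs = 13L,
                        baseline_weight_mean = 109.5,
                        baseline_weight_sd = 17.3,
                        baseline_sbp_mean = 140.3,
                        baseline_sbp_sd = 16.3,
                        baseline_age_mean = 47.1,
                        baseline_age_sd = 8.0,
                        height_mean = 1.76,
                        height_sd = 0.07,
                        change_profile = default_change_profile(),
                        within_person_correlation = 0.8,
                        dropout_model = list(intercept = 1.10, slope = -0.35),
                        consent_prob = 665 / 747,
                        weight_only_prob = 37 / 488,
                        utility_model_true = list(intercept = 1.05,
                                                  slope = -0.008,
                                                  resid_sd = 0.05),
                        resource_use_rates = default_resource_rates(),
                        sbp_change_per_kg = 0.55,
                        seed = 20150301L) {
  spec <- list(
    n_intervention = as.integer(n_intervention),
    n_comparison = as.integer(n_comparison),
    n_clubs = as.integer(n_clubs),
    baseline_weight_mean = baseline_weight_mean,
    baseline_weight_sd = baseline_weight_sd,
    baseline_sbp_mean = baseline_sbp_mean,
    baseline_sbp_sd = baseline_sbp_sd,
    baseline_age_mean = baseline_age_mean,
    baseline_age_sd = baseline_age_sd,
    height_mean = height_mean,
    height_sd = height_sd,
    change_profile = change_profile,
    within_person_correlation = within_person_correlation,
    dropout_model = dropout_model,
    consent_prob = consent_prob,
    weight_only_prob = weight_only_prob,
    utility_model_true = utility_model_true,
    resource_use_rates = resource_use_rates,
    sbp_change_per_kg = sbp_change_per_kg,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

#' Default per-group weight-change trajectory profile
#'
#' Means at 12 weeks, 12 months and 42 months (3.5 years) on the change scale
#' (follow-up minus baseline; negative = loss). Change SDs are back-computed
#' from printed 95% CIs: SD = half-width / 1.96 * sqrt(n), e.g. the
#' intervention 3.5-year CI (-4.02, -1.78) at n = 233 gives SD 8.72 kg.
#' The intervention 12-week mean (-4.8 kg, SD 4.5) reflects typical
#' end-of-programme loss preceding the 12-month -5.49; it is not printed in
#' the follow-up report. The comparison group has no 12-week measurement.
#'
#' @return Named list with `intervention` and `comparison` elements.
#' @export
default_change_profile <- function() {
  list(
    intervention = list(
      mean = c(w12 = -4.8, m12 = -5.49, m42 = -2.90),
      sd = c(w12 = 4.5, m12 = 7.94, m42 = 8.72)
    ),
    comparison = list(
      mean = c(w12 = NA_real_, m12 = -0.68, m42 = -2.71),
      sd = c(w12 = NA_real_, m12 = 5.25, m42 = 8.64)
    )
  )
}

#' Default mean resource-use counts per 12-week recall window
#'
#' Chosen so that, with the illustrative unit costs shipped in
#' `inst/extdata/unit_costs.csv`, the expected discounted 3.5-year cost per
#' intervention participant (programme cost included) is close to the
#' published mean of about 2450 GBP. See the methods vignette.
#'
#' @return Named numeric vector of mean counts per window.
#' @export
default_resource_rates <- function() {
  c(gp_visit = 1.2,
    practice_nurse = 0.5,
    physiotherapist = 0.15,
    ae_attendance = 0.08,
    inpatient_day = 0.04,
    outpatient_appointment = 0.30,
    prescription = 2.0)
}

#' @rdname cohort_spec
#' @param x Object to validate.
#' @export
validate_cohort_spec <- function(x) {
  stopifnot(inherits(x, "cohort_spec"))
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid cohort_spec field '", field, "': ", msg,
                          call. = FALSE)
  }
  chk(x$n_intervention >= 0L, "n_intervention", "must be >= 0")
  chk(x$n_comparison >= 0L, "n_comparison", "must be >= 0")
  chk(x$n_clubs >= 1L, "n_clubs", "must be >= 1")
  for (f in c("baseline_weight_sd", "baseline_sbp_sd", "baseline_age_sd",
              "height_sd")) {
    chk(is.numeric(x[[f]]) && x[[f]] >= 0, f, "SD must be >= 0")
  }
  chk(x$baseline_weight_mean > 0, "baseline_weight_mean", "must be > 0")
  chk(x$height_mean > 0, "height_mean", "must be > 0")
  chk(x$within_person_correlation >= 0 && x$within_person_correlation <= 1,
      "within_person_correlation", "must be in [0, 1]")
  chk(is.finite(x$dropout_model$slope), "dropout_model", "slope must be finite")
  chk(x$consent_prob >= 0 && x$consent_prob <= 1, "consent_prob",
      "must be in [0, 1]")
  chk(x$weight_only_prob >= 0 && x$weight_only_prob <= 1, "weight_only_prob",
      "must be in [0, 1]")
  chk(x$utility_model_true$resid_sd >= 0, "utility_model_true",
      "resid_sd must be >= 0")
  chk(all(x$resource_use_rates >= 0), "resource_use_rates",
      "rates must be >= 0")
  for (g in c("intervention", "comparison")) {
    p <- x$change_profile[[g]]
    chk(!is.null(p) && identical(names(p$mean), c("w12", "m12", "m42")),
        "change_profile", paste0(g, " must have mean at w12, m12, m42"))
    chk(all(p$sd >= 0, na.rm = TRUE), "change_profile",
        paste0(g, " SDs must be >= 0"))
  }
  invisible(x)
}

#' Follow-up timepoints, in years since baseline
#'
#' 12 weeks = 0.23 y, 12 months = 1 y, 42 months = 3.5 y. Elapsed-time
#' constants used throughout: baseline to 12 m = 1.0 y, 12 m to 42 m = 2.5 y.
#'
#' @return Named numeric vector `(baseline, w12, m12, m42)`.
#' @export
timepoint_years <- function() {
  c(baseline = 0, w12 = 12 / 52, m12 = 1, m42 = 3.5)
}
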