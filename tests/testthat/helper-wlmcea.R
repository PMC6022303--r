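# shared fixtures: all generated in code, no stored data

unit_costs_fixture <- function() {
  read_unit_costs(system.file("extdata", "unit_costs.csv", package = "wlmcea"))
}

# small cohort for fast structural tests
small_spec <- function(seed = 1L, ...) {
  cohort_spec(n_intervention = 120L, n_comparison = 120L, n_clubs = 6L,
              seed = seed, ...)
}

# hand-built wide cohort with fully controlled weights (no generator)
manual_cohort <- function(group, w_base, w_m12, w_m42, height = 1.76) {
  n <- length(group)
  data.frame(
    participant_id = sprintf("M%03d", seq_len(n)),
    group = group, club_id = rep(c("C01", "C02"), length.out = n),
    age = 47, height = height,
    weight_baseline = w_base, weight_w12 = NA_real_,
    weight_m12 = w_m12, weight_m42 = w_m42,
    sbp_baseline = 140, sbp_w12 = NA_real_, sbp_m12 = 138, sbp_m42 = 137,
    consented_followup = TRUE, attended_42m = !is.na(w_m42),
    weight_only_42m = FALSE,
    stringsAsFactors = FALSE
  )
}

# toy lifetime parameterization with a single flat age band
flat_params <- function(p_well_cvd = 0, p_well_dead_other = 0,
                        p_cvd_dead_cvd = 0, p_cvd_dead_other = 0,
                        ...) {
  lifetime_params(
    transitions = data.frame(age_band_start = 0,
                             p_well_cvd = p_well_cvd,
                             p_well_dead_other = p_well_dead_other,
                             p_cvd_dead_cvd = p_cvd_dead_cvd,
                             p_cvd_dead_other = p_cvd_dead_other),
    ...)
}
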