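#' Default pipeline configuration
#'
#' Nested list mirroring the JSON configuration file: the cohort
#' specification (flat keys as in [cohort_spec()]), scenario selection,
#' unit-cost table path, lifetime and PSA parameter blocks, and the
#' top-level seed from which every stage seed is derived.
#'
#' @param seed Top-level seed.
#' @return Configuration list.
#' @export
default_config <- function(seed = 20150301L) {
  list(
    seed = as.integer(seed),
    cohort = list(),                      # overrides for cohort_spec()
    scenarios = "all",                    # or subset of base, s1..s5
    unit_costs_path = system.file("extdata", "unit_costs.csv",
                                  package = "wlmcea"),
    programme_total_cost = 61700,
    programme_n = 374,
    discount_rate = 0.035,
    bmi_cost_rate = 16,
    lifetime = list(),                    # overrides for lifetime_params()
    psa = list(n_draws = 1000,
               wtp_max = 50000, wtp_step = 250)
  )
}

#' Read a pipeline configuration from a JSON file
#'
#' Flat keys as named in the cohort specification; unknown keys are an
#' error. Values present in the file override [default_config()].
#'
#' @param path JSON file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(base, cfg)
}

#' Table-2-style change table
#'
#' One row per outcome: per-group n, mean 42-month change with 95% CI and
#' paired-t p (rank p alongside), plus the between-group difference column
#' (Welch CI, Mann-Whitney p alongside).
#'
#' @param cohort Wide cohort data.frame.
#' @param outcomes Measurement prefixes to report.
#' @return Data.frame, one row per outcome.
#' @export
make_change_table <- function(cohort, outcomes = c("weight", "sbp")) {
  if (length(outcomes) == 0) {
    return(data.frame(outcome = character(), n_intervention = integer(),
                      mean_intervention = numeric(), ci_low_intervention = numeric(),
                      ci_high_intervention = numeric(), p_intervention = numeric(),
                      n_comparison = integer(), mean_comparison = numeric(),
                      ci_low_comparison = numeric(), ci_high_comparison = numeric(),
                      p_comparison = numeric(), difference = numeric(),
                      diff_ci_low = numeric(), diff_ci_high = numeric(),
                      diff_p = numeric()))
  }
  rows <- lapply(outcomes, function(oc) {
    base <- cohort[[paste0(oc, "_baseline")]]
    m42 <- cohort[[paste0(oc, "_m42")]]
    gi <- cohort$group == "intervention"
    wi <- within_group_change(base[gi], m42[gi])
    wc <- within_group_change(base[!gi], m42[!gi])
    bg <- between_group_difference((m42 - base)[gi], (m42 - base)[!gi])
    data.frame(outcome = oc,
               n_intervention = wi$n, mean_intervention = wi$mean_change,
               ci_low_intervention = wi$ci_low, ci_high_intervention = wi$ci_high,
               p_intervention = wi$p_value,
               n_comparison = wc$n, mean_comparison = wc$mean_change,
               ci_low_comparison = wc$ci_low, ci_high_comparison = wc$ci_high,
               p_comparison = wc$p_value,
               difference = bg$mean_change, diff_ci_low = bg$ci_low,
               diff_ci_high = bg$ci_high, diff_p = bg$p_value)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

scenario_anchor <- function(scenario_id) {
  s <- list_scenarios()
  s$anchor[s$scenario_id == scenario_id]
}

#' Within-trial cost-effectiveness for one counterfactual scenario
#'
#' deltaC = mean discounted cost per intervention participant minus mean
#' discounted cost per counterfactual control; deltaQ = mean discounted
#' within-trial QALY per intervention participant (observed utilities) minus
#' per counterfactual control (model-predicted utilities along the
#' extrapolated BMI trajectory).
#'
#' @param cohort Wide cohort data.frame.
#' @param cf Counterfactual long table from [build_counterfactual()] (with
#'   utilities filled in).
#' @param scenario_id Scenario identifier (for the anchor and the report
#'   row).
#' @param unit_costs Named unit-cost vector.
#' @param programme_cost GBP per intervention participant.
#' @param discount_rate,bmi_rate Costing parameters.
#' @return One-row data.frame: `scenario_id`, `cost_intervention`,
#'   `cost_control`, `delta_cost`, `qaly_intervention`, `qaly_control`,
#'   `delta_qaly`, `icer`, `icer_label`.
#' @export
within_trial_cea <- function(cohort, cf, scenario_id, unit_costs,
                             programme_cost = 61700 / 374,
                             discount_rate = 0.035, bmi_rate = 16) {
  ledger <- total_cost(cohort, unit_costs, programme_cost = programme_cost,
                       annual_rate = discount_rate, bmi_rate = bmi_rate)
  cost_int <- mean(ledger$discounted_total[ledger$group == "intervention"])
  cfc <- counterfactual_cost(cf, cohort, unit_costs,
                             annual_rate = discount_rate, bmi_rate = bmi_rate,
                             anchor = scenario_anchor(scenario_id))
  cost_ctl <- mean(cfc$discounted_total)

  q <- cohort_qalys(cohort, discount_rate)
  qaly_int <- mean(q$qaly[q$group == "intervention"], na.rm = TRUE)
  cf_ord <- cf[order(cf$participant_id, cf$time_years), ]
  qaly_ctl <- mean(vapply(split(cf_ord, cf_ord$participant_id), function(d) {
    qaly_auc(d$utility, d$time_years, discount_rate)
  }, numeric(1)), na.rm = TRUE)

  ic <- icer(cost_int - cost_ctl, qaly_int - qaly_ctl)
  data.frame(scenario_id = scenario_id, cost_intervention = cost_int,
             cost_control = cost_ctl, delta_cost = cost_int - cost_ctl,
             qaly_intervention = qaly_int, qaly_control = qaly_ctl,
             delta_qaly = qaly_int - qaly_ctl,
             icer = ic$icer, icer_label = ic$label,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' simulate -> trajectories -> counterfactuals -> within-trial costs/QALYs ->
#' lifetime extrapolation -> PSA/CEAC, writing delimited result tables and a
#' machine-readable run manifest to `out_dir`. Deterministic given
#' `config$seed` (every stage seed is derived from it via [stage_seed()]).
#'
#' @param config Configuration list ([default_config()] or [read_config()]).
#' @param out_dir Output directory (created if absent); `NULL` = no files
#'   written, results only returned.
#' @return Invisible list with elements `cohort`, `change_table`,
#'   `utility_model`, `counterfactuals`, `within_trial`, `lifetime`,
#'   `lifetime_limited`, `psa`, `ceac`, `ceac_crossing`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  spec <- do.call(cohort_spec, c(config$cohort, list(seed = seed)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", generate_cohort(spec))
  change_table <- stage("trajectories", make_change_table(cohort))

  # utility regression on all observed person-timepoints, clustered on person
  lc <- cohort_long(cohort)
  um <- stage("utility_model",
              fit_utility_bmi(lc$bmi, lc$utility, lc$participant_id))

  scen <- list_scenarios()
  if (!identical(config$scenarios, "all"))
    scen <- scen[scen$scenario_id %in% config$scenarios, ]
  regain <- ffit_regain_rate(cohort)
  unit_costs <- read_unit_costs(config$unit_costs_path)
  prog_cost <- programme_cost_per_participant(config$programme_total_cost,
                                              config$programme_n)

  cfs <- stage("counterfactuals", lapply(seq_len(nrow(scen)), function(i) {
    build_counterfactual(cohort, scen[i, ], regain_rate = regain,
                         utility_model = um)
  }))
  names(cfs) <- scen$scenario_id

  within_trial <- stage("within_trial_cea", do.call(rbind,
    lapply(scen$scenario_id, function(sid) {
      within_trial_cea(cohort, cfs[[sid]], sid, unit_costs,
                       programme_cost = prog_cost,
                       discount_rate = config$discount_rate,
                       bmi_rate = config$bmi_cost_rate)
    })))

  # lifetime: base-case counterfactual profile vs intervention profile
  lt_params <- do.call(lifetime_params,
                       c(config$lifetime,
                         list(discount_rate = config$discount_rate,
                              utility_intercept = um$intercept,
                              utility_slope = um$slope)))
  gi <- cohort$group == "intervention" & !is.na(cohort$weight_m42)
  prof_int <- list(bmi = mean((cohort$weight_m42 / cohort$height^2)[gi]),
                   sbp = mean(cohort$sbp_m42[gi], na.rm = TRUE))
  base_cf <- cfs[[if ("base" %in% names(cfs)) "base" else names(cfs)[1]]]
  cf_end <- base_cf[abs(base_cf$time_years - 3.5) < 1e-9, ]
  prof_ctl <- list(bmi = mean(cf_end$bmi), sbp = mean(cf_end$sbp))
  start_ages <- round(cohort$age[gi] + 3.5)
  base_sid <- if ("base" %in% within_trial$scenario_id) "base" else
    within_trial$scenario_id[1]
  wt_row <- within_trial[within_trial$scenario_id == base_sid, ]
  lifetime <- stage("lifetime",
                    run_cohort_lifetime(list(intervention = prof_int,
                                             control = prof_ctl),
                                        lt_params, start_ages))
  lifetime_limited <- stage("lifetime_limited",
                            limited_effect_sensitivity(
                              list(intervention = prof_int, control = prof_ctl),
                              lt_params, start_ages, total_effect_years = 5.5))

  # lifetime totals include the within-trial increments (base scenario)
  lt_delta_cost <- wt_row$delta_cost[1] + lifetime$incremental$cost
  lt_delta_qaly <- wt_row$delta_qaly[1] + lifetime$incremental$qaly
  lt_icer <- icer(lt_delta_cost, lt_delta_qaly)
  lifetime_cea <- data.frame(
    horizon = c("within_trial", "lifetime", "lifetime_5.5y_effect"),
    delta_cost = c(wt_row$delta_cost[1], lt_delta_cost,
                   wt_row$delta_cost[1] + lifetime_limited$incremental$cost),
    delta_qaly = c(wt_row$delta_qaly[1], lt_delta_qaly,
                   wt_row$delta_qaly[1] + lifetime_limited$incremental$qaly),
    stringsAsFactors = FALSE)
  lifetime_cea$icer <- lifetime_cea$delta_cost / lifetime_cea$delta_qaly

  dists <- default_psa_distributions(
    lt_params,
    bmi_advantage = prof_ctl$bmi - prof_int$bmi,
    sbp_advantage = prof_ctl$sbp - prof_int$sbp,
    delta_cost_trial = wt_row$delta_cost[1])
  psa <- stage("psa", run_psa(
    list(intervention = prof_int, control = prof_ctl),
    lt_params, dists, n_draws = config$psa$n_draws,
    seed = stage_seed(seed, "psa"),
    start_ages = round(mean(start_ages))))
  # PSA QALY increments are post-follow-up; add the within-trial gain
  psa$delta_qaly <- psa$delta_qaly + wt_row$delta_qaly[1]
  curve <- ceac(psa, seq(0, config$psa$wtp_max, by = config$psa$wtp_step))
  crossing <- threshold_crossing(curve, 0.5)

  manifest <- list(package_version = as.character(utils::packageVersion("wlmcea")),
                   r_version = R.version.string,
                   seed = seed,
                   scenarios = scen$scenario_id,
                   n_participants = nrow(cohort),
                   config = config[setdiff(names(config), "cohort")])

  result <- list(cohort = cohort, change_table = change_table,
                 utility_model = um, counterfactuals = cfs,
                 within_trial = within_trial, lifetime = lifetime,
                 lifetime_limited = lifetime_limited,
                 lifetime_cea = lifetime_cea,
                 psa = psa, ceac = curve, ceac_crossing = crossing,
                 manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(d, f) utils::write.csv(d, file.path(out_dir, f),
                                            row.names = FALSE, na = "")
    wcsv(cohort, "cohort_wide.csv")
    wcsv(cohort_long(cohort), "cohort_long.csv")
    wcsv(change_table, "change_table.csv")
    for (sid in names(cfs)) wcsv(cfs[[sid]], paste0("counterfactual_", sid, ".csv"))
    wcsv(within_trial, "within_trial_cea.csv")
    wcsv(lifetime_cea, "lifetime_cea.csv")
    wcsv(psa, "psa_draws.csv")
    wcsv(curve, "ceac.csv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    grDevices::pdf(file.path(out_dir, "ceac.pdf"), width = 6, height = 4)
    plot(curve$wtp, curve$prob_cost_effective, type = "l",
         xlab = "Willingness to pay (GBP/QALY)",
         ylab = "P(cost-effective)", ylim = c(0, 1),
         main = "Cost-effectiveness acceptability curve")
    graphics::abline(h = 0.5, lty = 2)
    grDevices::dev.off()
  }
  invisible(result)
}
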