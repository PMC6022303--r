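#' Seeded Monte-Carlo draws of uncertain parameters
#'
#' Each uncertain parameter is described by a distribution respecting its
#' support: `normal(mean, sd)`, `lognormal(meanlog, sdlog)` for hazard
#' ratios, `beta(shape1, shape2)` for probabilities, `gamma(shape, scale)`
#' for costs, or `fixed(value, )` for degenerate parameters. Zero-variance
#' normal/lognormal/fixed draws collapse to the location.
#'
#' @param dists Named list; each element a list
#'   `(family, p1, p2)`.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Data.frame of `n` rows, one column per parameter.
#' @export
draw_parameters <- function(dists, n, seed) {
  set.seed(seed)
  cols <- lapply(dists, function(d) {
    switch(d$family,
           normal = rnorm(n, d$p1, d$p2),
           lognormal = stats::rlnorm(n, d$p1, d$p2),
           beta = stats::rbeta(n, d$p1, d$p2),
           gamma = stats::rgamma(n, shape = d$p1, scale = d$p2),
           fixed = rep(d$p1, n),
           stop("unknown distribution family: ", d$family))
  })
  as.data.frame(cols)
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' deltaC / deltaQ when deltaQ > 0; the label `"dominant"` when the
#' intervention is cheaper and more effective (deltaC < 0, deltaQ > 0);
#' `"dominated"` when dearer and less effective; `"undefined"` when
#' deltaQ = 0. Returns a list rather than raising for the labelled quadrants.
#'
#' @param delta_cost Incremental cost (GBP).
#' @param delta_qaly Incremental QALYs.
#' @return List `(icer, label)`: `icer` is GBP/QALY or `NA` for labelled
#'   quadrants with no meaningful ratio; `label` is `"icer"`, `"dominant"`,
#'   `"dominated"` or `"undefined"`.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) return(list(icer = NA_real_, label = "undefined"))
  if (delta_qaly > 0 && delta_cost < 0)
    return(list(icer = delta_cost / delta_qaly, label = "dominant"))
  if (delta_qaly < 0 && delta_cost > 0)
    return(list(icer = NA_real_, label = "dominated"))
  list(icer = delta_cost / delta_qaly, label = "icer")
}

#' Cost-effectiveness acceptability curve from PSA draws
#'
#' At each willingness-to-pay lambda, the probability of cost-effectiveness
#' is the fraction of draws with positive net monetary benefit
#' lambda * deltaQ - deltaC > 0 (NMB formulation, avoiding ICER quadrant
#' ambiguity).
#'
#' @param draws Data.frame with columns `delta_cost`, `delta_qaly`.
#' @param wtp_grid Willingness-to-pay grid (GBP/QALY); default 0 to 50,000
#'   in steps of 250, covering usual UK thresholds.
#' @return Data.frame `wtp`, `prob_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = seq(0, 50000, by = 250)) {
  if (length(wtp_grid) == 0) stop("empty willingness-to-pay grid")
  stopifnot(nrow(draws) >= 1)
  p <- vapply(wtp_grid, function(l) {
    mean(l * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = p)
}

#' Willingness-to-pay at which the CEAC reaches a target probability
#'
#' Smallest lambda with probability >= target, linearly interpolated between
#' the bracketing grid points; the first grid point if already above target
#' there; `NA` (sentinel) if the curve never reaches the target.
#'
#' @param curve A [ceac()] data.frame.
#' @param probability Target probability (default 0.5).
#' @return GBP/QALY, or `NA_real_` if never reached.
#' @export
threshold_crossing <- function(curve, probability = 0.5) {
  stopifnot(nrow(curve) > 0)
  above <- which(curve$prob_cost_effective >= probability)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  if (i == 1) return(curve$wtp[1])
  x0 <- curve$wtp[i - 1]; x1 <- curve$wtp[i]
  y0 <- curve$prob_cost_effective[i - 1]; y1 <- curve$prob_cost_effective[i]
  if (y1 == y0) return(x1)
  x0 + (probability - y0) / (y1 - y0) * (x1 - x0)
}

#' Default PSA distributions over the lifetime-model parameters
#'
#' Hazard ratios lognormal around their point estimates; the intervention's
#' BMI and SBP advantages normal; state costs gamma; well-state utility
#' slope normal. Spread magnitudes are illustrative (roughly 10-20%
#' coefficients of variation), exposed for configuration.
#'
#' @param params A [lifetime_params()] providing point estimates.
#' @param bmi_advantage,sbp_advantage Point estimates of the intervention
#'   arm's risk-factor advantage (control minus intervention; positive =
#'   intervention better).
#' @param delta_cost_trial Within-trial incremental cost (GBP) carried into
#'   the lifetime totals; given a 15% normal SE.
#' @return Named list of distribution specs for [draw_parameters()].
#' @export
default_psa_distributions <- function(params, bmi_advantage, sbp_advantage,
                                      delta_cost_trial) {
  list(
    hr_per_bmi_unit = list(family = "lognormal",
                           p1 = log(params$hr_per_bmi_unit), p2 = 0.02),
    hr_per_mmhg_sbp = list(family = "lognormal",
                           p1 = log(params$hr_per_mmhg_sbp), p2 = 0.005),
    bmi_advantage = list(family = "normal", p1 = bmi_advantage,
                         p2 = abs(bmi_advantage) * 0.20),
    sbp_advantage = list(family = "normal", p1 = sbp_advantage,
                         p2 = abs(sbp_advantage) * 0.20),
    utility_slope = list(family = "normal", p1 = params$utility_slope,
                         p2 = abs(params$utility_slope) * 0.15),
    cost_cvd = list(family = "gamma",
                    p1 = 25, p2 = params$state_costs[["cvd"]] / 25),
    delta_cost_trial = list(family = "normal", p1 = delta_cost_trial,
                            p2 = abs(delta_cost_trial) * 0.15)
  )
}

#' Probabilistic sensitivity analysis of the lifetime comparison
#'
#' Propagates parameter uncertainty through the lifetime model: for each
#' draw, the hazard ratios, risk-factor advantages, utility slope, CVD state
#' cost and within-trial incremental cost are set to their drawn values, the
#' deterministic cohort model is run for both arms, and the incremental
#' discounted cost (within-trial increment + lifetime state-cost increment)
#' and QALYs are recorded.
#'
#' @param profiles Arm risk profiles as in [run_cohort_lifetime()]
#'   (`control` fixed; the intervention profile is reconstructed per draw
#'   from the drawn advantages).
#' @param params A [lifetime_params()].
#' @param dists Distributions, e.g. [default_psa_distributions()].
#' @param n_draws Number of Monte-Carlo draws (default 1000).
#' @param seed Integer seed.
#' @param start_ages As in [run_cohort_lifetime()].
#' @return Data.frame of draws: `delta_cost`, `delta_qaly`.
#' @export
run_psa <- function(profiles, params, dists, n_draws = 1000, seed = 1,
                    start_ages = 51) {
  par_draws <- draw_parameters(dists, n_draws, seed)
  out <- vapply(seq_len(n_draws), function(i) {
    p <- params
    p$hr_per_bmi_unit <- par_draws$hr_per_bmi_unit[i]
    p$hr_per_mmhg_sbp <- par_draws$hr_per_mmhg_sbp[i]
    p$utility_slope <- par_draws$utility_slope[i]
    p$state_costs[["cvd"]] <- par_draws$cost_cvd[i]
    prof <- list(
      control = profiles$control,
      intervention = list(
        bmi = profiles$control$bmi - par_draws$bmi_advantage[i],
        sbp = profiles$control$sbp - par_draws$sbp_advantage[i])
    )
    res <- run_cohort_lifetime(prof, p, start_ages)
    c(par_draws$delta_cost_trial[i] + res$incremental$cost,
      res$incremental$qaly)
  }, numeric(2))
  data.frame(delta_cost = out[1, ], delta_qaly = out[2, ])
}
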