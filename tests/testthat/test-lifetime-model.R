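test_that("SBP imputation is the stated linear rule", {
  expect_equal(impute_sbp_change(-0.10), -6.1)
  expect_equal(impute_sbp_change(0), 0)
  expect_equal(impute_sbp_change(-0.05), -3.05)
  expect_equal(impute_sbp_change(0.10), 6.1)    # gain raises SBP symmetrically
  expect_error(impute_sbp_change(1.2), "fraction")
})

test_that("hazard-ratio adjustment of transition probabilities is exact", {
  p <- lifetime_params()
  expect_equal(adjust_transition(0.04, 0, 0, p), 0.04)
  # HR product 2 via one BMI unit at HR 2: 1 - (1 - 0.010)^2
  p2 <- lifetime_params(hr_per_bmi_unit = 2)
  expect_equal(adjust_transition(0.010, 1, 0, p2), 1 - 0.99^2,
               tolerance = 1e-14)
  expect_equal(adjust_transition(0, 3, 10, p2), 0)
  # adjusted value stays a probability for extreme deltas
  expect_lt(adjust_transition(0.5, 10, 50, p2), 1)
})

test_that("the Markov engine equals a matrix-power oracle to machine precision", {
  prm <- flat_params(p_well_cvd = 0.08, p_well_dead_other = 0.03,
                     p_cvd_dead_cvd = 0.12, p_cvd_dead_other = 0.05,
                     utility_intercept = 0.9, utility_slope = 0,
                     cvd_utility_decrement = 0.2,
                     state_costs = c(well = 100, cvd = 1000),
                     discount_rate = 0.035, max_age = 53, half_cycle = TRUE)
  res <- markov_trace(50, bmi = prm$ref_bmi, sbp = prm$ref_sbp, prm)

  # independent oracle: explicit transition matrix powers
  P <- rbind(c(1 - 0.08 - 0.03, 0.08, 0, 0.03),
             c(0, 1 - 0.12 - 0.05, 0.12, 0.05),
             c(0, 0, 1, 0),
             c(0, 0, 0, 1))
  occ <- rbind(c(1, 0, 0, 0),
               c(1, 0, 0, 0) %*% P,
               c(1, 0, 0, 0) %*% P %*% P,
               c(1, 0, 0, 0) %*% P %*% P %*% P)
  expect_equal(unname(res$trace), unname(occ), tolerance = 1e-14)

  u <- c(0.9, 0.7, 0, 0); cst <- c(100, 1000, 0, 0)
  qaly_o <- cost_o <- 0
  for (k in 1:3) {
    w <- (occ[k, ] + occ[k + 1, ]) / 2
    df <- 1.035^-(k - 0.5)
    qaly_o <- qaly_o + df * sum(w * u)
    cost_o <- cost_o + df * sum(w * cst)
  }
  expect_equal(res$qaly, qaly_o, tolerance = 1e-14)
  expect_equal(res$cost, cost_o, tolerance = 1e-14)
})

test_that("closed-form limits: immortal cohort and constant mortality", {
  # no mortality, utility 1, rate 0, 10-year horizon: exactly 10 QALYs
  prm <- flat_params(utility_intercept = 1, utility_slope = 0,
                     discount_rate = 0, max_age = 60, half_cycle = TRUE)
  res <- markov_trace(50, prm$ref_bmi, prm$ref_sbp, prm)
  expect_equal(res$qaly, 10)
  expect_equal(res$life_years, 10)

  # constant annual mortality 0.1: geometric life expectancy 10, half-cycle
  # places the estimate at 9.5 (within the 8.5-9.5 correction band)
  prm2 <- flat_params(p_well_dead_other = 0.1, utility_intercept = 1,
                      utility_slope = 0, discount_rate = 0, max_age = 500,
                      half_cycle = TRUE)
  res2 <- markov_trace(50, prm2$ref_bmi, prm2$ref_sbp, prm2)
  expect_equal(res2$life_years, 9.5, tolerance = 1e-3)
})

test_that("traces conserve mass, absorb death, and respect discounting", {
  prm <- lifetime_params()
  res <- markov_trace(55, 36, 145, prm)
  expect_true(all(abs(rowSums(res$trace) - 1) < 1e-12))
  dead <- res$trace[, "dead_cvd"] + res$trace[, "dead_other"]
  expect_true(all(diff(dead) >= -1e-14))

  # QALYs monotone non-increasing in the discount rate
  q <- vapply(c(0, 0.015, 0.035, 0.06), function(r) {
    prm$discount_rate <- r
    markov_trace(55, 36, 145, prm)$qaly
  }, numeric(1))
  expect_true(all(diff(q) < 0))

  # life-years >= QALYs when utilities <= 1
  expect_gte(res$life_years, res$qaly)
})

test_that("identical risk profiles give exactly zero increment", {
  prm <- lifetime_params()
  prof <- list(intervention = list(bmi = 34, sbp = 138),
               control = list(bmi = 34, sbp = 138))
  res <- run_cohort_lifetime(prof, prm, start_ages = c(50, 55, 61))
  expect_identical(res$incremental$qaly, 0)
  expect_identical(res$incremental$cost, 0)
  expect_identical(res$incremental$life_years, 0)
})

test_that("a healthier risk profile yields more QALYs and fewer CVD costs", {
  prm <- lifetime_params()
  prof <- list(intervention = list(bmi = 33.5, sbp = 135),
               control = list(bmi = 35.5, sbp = 141))
  res <- run_cohort_lifetime(prof, prm, start_ages = 51)
  expect_gt(res$incremental$qaly, 0)
  expect_gt(res$incremental$life_years, 0)
  expect_lt(res$incremental$cost, 0)   # fewer CVD-state years
})

test_that("limited effect duration interpolates between no effect and lifelong", {
  prm <- lifetime_params()
  prof <- list(intervention = list(bmi = 33.5, sbp = 135),
               control = list(bmi = 35.5, sbp = 141))
  unlimited <- run_cohort_lifetime(prof, prm, 51)
  lim <- limited_effect_sensitivity(prof, prm, 51, total_effect_years = 5.5)
  expect_lte(lim$incremental$qaly, unlimited$incremental$qaly)
  expect_gt(lim$incremental$qaly, 0)

  # no effect beyond follow-up: intervention trace collapses onto control
  none <- limited_effect_sensitivity(prof, prm, 51, total_effect_years = 3.5)
  expect_equal(none$incremental$qaly, 0, tolerance = 1e-12)
  expect_equal(none$incremental$cost, 0, tolerance = 1e-9)

  # infinite total duration reproduces the unlimited run exactly
  inf <- limited_effect_sensitivity(prof, prm, 51, total_effect_years = Inf)
  expect_identical(inf$incremental, unlimited$incremental)
})
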