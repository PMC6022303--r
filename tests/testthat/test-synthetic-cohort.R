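test_that("generation is deterministic given spec and seed", {
  spec <- small_spec(seed = 7L)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  c2 <- generate_cohort(small_spec(seed = 8L))
  expect_false(identical(a$weight_baseline, c2$weight_baseline))
})

test_that("degenerate SDs give exact baseline values", {
  spec <- small_spec(baseline_weight_sd = 0)
  coh <- generate_cohort(spec, with_attrition = FALSE,
                         with_costs_utilities = FALSE)
  expect_true(all(coh$weight_baseline == 109.5))
})

test_that("baseline and change moments are recovered (calibration)", {
  # default trial-sized cohort: mean baseline weight near the configured 109.5
  spec <- cohort_spec(seed = 11L)
  coh <- generate_cohort(spec, with_attrition = FALSE,
                         with_costs_utilities = FALSE)
  se <- spec$baseline_weight_sd / sqrt(nrow(coh))
  expect_lt(abs(mean(coh$weight_baseline) - 109.5), 3 * se)

  # large-n override: every configured mean/SD within 3 standard errors
  big <- cohort_spec(n_intervention = 10000L, n_comparison = 10000L,
                     seed = 12L)
  coh <- generate_cohort(big, with_attrition = FALSE,
                         with_costs_utilities = FALSE)
  for (g in c("intervention", "comparison")) {
    d <- coh[coh$group == g, ]
    prof <- big$change_profile[[g]]
    for (tp in c("m12", "m42")) {
      ch <- d[[paste0("weight_", tp)]] - d$weight_baseline
      se_m <- prof$sd[[tp]] / sqrt(nrow(d))
      expect_lt(abs(mean(ch) - prof$mean[[tp]]), 3 * se_m)
      se_s <- prof$sd[[tp]] / sqrt(2 * (nrow(d) - 1))
      expect_lt(abs(sd(ch) - prof$sd[[tp]]), 3 * se_s)
    }
    # exchangeable within-person correlation recovered
    r <- cor(d$weight_m12 - d$weight_baseline,
             d$weight_m42 - d$weight_baseline)
    expect_lt(abs(r - big$within_person_correlation), 0.03)
  }
})

test_that("comparison group has no 12-week measurement by default", {
  coh <- generate_cohort(small_spec())
  expect_true(all(is.na(coh$weight_w12[coh$group == "comparison"])))
  expect_true(all(!is.na(coh$weight_w12[coh$group == "intervention"])))
})

test_that("attrition follows the logistic dropout model", {
  spec <- cohort_spec(seed = 3L)
  coh <- generate_cohort(spec)

  # negative slope: non-attenders heavier on average
  expect_gt(mean(coh$weight_baseline[!coh$attended_42m]),
            mean(coh$weight_baseline[coh$attended_42m]))

  # probability clamp: huge intercept means everyone attends
  all_in <- apply_attrition(coh, list(intercept = 50, slope = -0.35),
                            seed = 5L, consent_prob = 1)
  expect_true(all(all_in$attended_42m))

  # slope 0, intercept logit(0.65): attendance fraction near 0.65
  # (3x binomial SE over pooled draws across seeds)
  n <- nrow(coh)
  fracs <- vapply(1:5, function(s) {
    a <- apply_attrition(coh, list(intercept = qlogis(0.65), slope = 0),
                         seed = s, consent_prob = 1)
    mean(a$attended_42m)
  }, numeric(1))
  se <- sqrt(0.65 * 0.35 / (n * length(fracs)))
  expect_lt(abs(mean(fracs) - 0.65), 3 * se)

  # masking: missing pattern consistent with flags
  expect_true(all(is.na(coh$weight_m42[!coh$attended_42m])))
  expect_true(all(is.na(coh$sbp_m42[coh$weight_only_42m])))
  expect_true(all(is.na(coh$utility_m42[coh$weight_only_42m])))
})

test_that("utilities follow the configured line and resource counts the rates", {
  # deterministic line: BMI 35 everywhere, no noise -> utility exactly 0.70
  h <- sqrt(109.5 / 35)
  spec <- small_spec(baseline_weight_sd = 0, height_mean = h, height_sd = 0,
                     utility_model_true = list(intercept = 1.05,
                                               slope = -0.01, resid_sd = 0))
  coh <- generate_cohort(spec, with_attrition = FALSE)
  expect_equal(unique(coh$utility_baseline), 0.70, tolerance = 1e-12)

  # all rates zero -> no resource use anywhere
  spec0 <- small_spec(resource_use_rates = c(gp_visit = 0, prescription = 0))
  coh0 <- generate_cohort(spec0, with_attrition = FALSE)
  expect_true(all(coh0$ru_gp_visit_baseline == 0))
  expect_true(all(coh0$ru_prescription_m12 == 0))

  # law of large numbers: configured mean 1.2 GP visits per window
  big <- cohort_spec(n_intervention = 8000L, n_comparison = 0L, seed = 9L)
  cohb <- generate_cohort(big, with_attrition = FALSE)
  se <- sqrt(1.2 / 8000)
  expect_lt(abs(mean(cohb$ru_gp_visit_baseline) - 1.2), 3 * se)
})

test_that("no impossible values under randomized valid specs", {
  set.seed(99)
  for (i in 1:8) {
    spec <- cohort_spec(
      n_intervention = sample(20:80, 1), n_comparison = sample(20:80, 1),
      baseline_weight_mean = runif(1, 60, 140),
      baseline_weight_sd = runif(1, 0, 30),
      within_person_correlation = runif(1),
      utility_model_true = list(intercept = runif(1, 0.5, 1.3),
                                slope = runif(1, -0.02, 0),
                                resid_sd = runif(1, 0, 0.2)),
      seed = i)
    coh <- generate_cohort(spec)
    w <- unlist(coh[, grep("^weight_(baseline|w12|m12|m42)$", names(coh))])
    expect_true(all(w > 0, na.rm = TRUE))
    u <- unlist(coh[, grep("^utility_", names(coh))])
    expect_true(all(u >= 0 & u <= 1, na.rm = TRUE))
    ru <- unlist(coh[, grep("^ru_", names(coh))])
    expect_true(all(ru >= 0, na.rm = TRUE))
  }
})

test_that("invalid specs fail naming the offending field", {
  expect_error(cohort_spec(baseline_weight_sd = -1), "baseline_weight_sd")
  expect_error(cohort_spec(within_person_correlation = 1.5),
               "within_person_correlation")
  expect_error(cohort_spec(n_clubs = 0), "n_clubs")
})
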