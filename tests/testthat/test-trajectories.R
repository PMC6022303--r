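test_that("within-group change matches the hand paired-t computation", {
  # pairs (100,98),(90,87),(80,78): d = (-2,-3,-2)
  # mean -7/3; sd(d) = 0.5773503; se = 0.3333333; t crit qt(.975, 2) = 4.302653
  est <- within_group_change(c(100, 90, 80), c(98, 87, 78))
  expect_equal(est$n, 3)
  expect_equal(est$mean_change, -7 / 3, tolerance = 1e-12)
  expect_equal(est$ci_low, -7 / 3 - 4.302653 * 1 / 3, tolerance = 1e-6)
  expect_equal(est$ci_high, -7 / 3 + 4.302653 * 1 / 3, tolerance = 1e-6)
  expect_true(est$ci_low <= est$mean_change && est$mean_change <= est$ci_high)

  # identical pre/post: degenerate, flagged
  z <- within_group_change(c(1, 2, 3), c(1, 2, 3))
  expect_true(z$zero_variance)
  expect_equal(z$mean_change, 0)
  expect_equal(c(z$ci_low, z$ci_high), c(0, 0))

  expect_error(within_group_change(c(1, NA), c(2, 3)), "insufficient")
})

test_that("within-group change on a cohort calibrated to the 3.5-year loss", {
  # intervention attenders configured at mean -2.90 with CI-derived SD:
  # estimate lands within 3 standard errors of the configured truth
  spec <- cohort_spec(seed = 21L)
  coh <- generate_cohort(spec)
  gi <- coh$group == "intervention"
  est <- within_group_change(coh$weight_baseline[gi], coh$weight_m42[gi])
  se <- spec$change_profile$intervention$sd[["m42"]] / sqrt(est$n)
  expect_lt(abs(est$mean_change - (-2.90)), 3 * se)
})

test_that("between-group difference is Welch-based with rank companion", {
  expect_equal(between_group_difference(c(1, 2, 3), c(2, 3, 4))$mean_change, 1)
  ident <- between_group_difference(c(5, 5, 5), c(5, 5, 5))
  expect_equal(ident$mean_change, 0)
  set.seed(4)
  a <- rnorm(60, -2.90, 8); b <- rnorm(60, -2.71, 8)
  est <- between_group_difference(a, b)
  expect_true(est$ci_low <= est$mean_change & est$mean_change <= est$ci_high)
  expect_true(is.finite(est$p_rank))
  expect_error(between_group_difference(1, c(1, 2)), "insufficient")
})

test_that("responder proportion uses an inclusive threshold and scales freely", {
  expect_equal(responder_proportion(100, 95)$count, 1)   # boundary inclusive
  expect_equal(responder_proportion(c(1, 2), c(1, 2))$proportion, 0)
  set.seed(8)
  base <- runif(50, 80, 140); fol <- base * runif(50, 0.85, 1.1)
  p1 <- responder_proportion(base, fol)
  p2 <- responder_proportion(base * 2.7, fol * 2.7)  # scale invariance
  expect_identical(p1, p2)
  expect_error(responder_proportion(NA, NA), "no complete pairs")
})

test_that("annualized rate is change/elapsed and linear in change", {
  expect_equal(round(annualized_rate(2.59, 2.5), 2), 1.04)
  expect_equal(annualized_rate(0, 3), 0)
  expect_equal(annualized_rate(-2.03, 2.5), -0.812)
  expect_equal(annualized_rate(2 * 2.59, 2.5), 2 * annualized_rate(2.59, 2.5))
  expect_error(annualized_rate(1, 0), "elapsed")
})

test_that("BCF and LOCF complete the randomized denominator", {
  # 3 observed at -2.90, 2 missing with last observed change -5.49
  coh <- manual_cohort(group = rep("intervention", 5),
                       w_base = rep(100, 5),
                       w_m12 = rep(100 - 5.49, 5),
                       w_m42 = c(rep(100 - 2.90, 3), NA, NA))
  bcf <- impute_bcf(coh, "intervention")
  expect_equal(mean(bcf), 3 * -2.90 / 5, tolerance = 1e-12)
  locf <- impute_locf(coh, "intervention")
  expect_equal(locf[4:5], c(-5.49, -5.49))
  # no missingness: identical to complete case
  full <- manual_cohort(rep("intervention", 4), rep(100, 4),
                        rep(99, 4), rep(98, 4))
  expect_equal(impute_bcf(full, "intervention"),
               full$weight_m42 - full$weight_baseline)
  # property: |BCF mean| <= |complete-case mean| when imputing zeros
  cc <- coh$weight_m42 - coh$weight_baseline
  expect_lte(abs(mean(bcf)), abs(mean(cc, na.rm = TRUE)))
})

test_that("repeated-measures model recovers a known group x time interaction", {
  # build a profile whose comparison-group 42 m change differs by delta
  delta <- 2.0
  prof <- default_change_profile()
  prof$comparison$mean[["w12"]] <- -1; prof$comparison$sd[["w12"]] <- 3
  prof$comparison$mean[["m42"]] <- prof$intervention$mean[["m42"]] + delta
  spec <- cohort_spec(change_profile = prof, seed = 31L)
  coh <- generate_cohort(spec, with_attrition = FALSE,
                         with_costs_utilities = FALSE)
  lt <- long_change_table(coh)
  fit <- fit_repeated_measures(lt, include_group_interaction = TRUE)
  ctr <- fit$contrasts[fit$contrasts$timepoint == "m42", ]
  # contrast is intervention minus comparison (groups sorted), true value
  # -delta at 42 months
  expect_lt(abs(ctr$difference - (-delta)), 3 * ctr$se)
  expect_true(all(fit$variance_components >= 0))
})

test_that("repeated-measures adjusted mean agrees with the paired-t mean on balanced data", {
  spec <- cohort_spec(n_intervention = 400L, n_comparison = 0L, seed = 33L)
  coh <- generate_cohort(spec, with_attrition = FALSE,
                         with_costs_utilities = FALSE)
  lt <- long_change_table(coh)
  fit <- fit_repeated_measures(lt)
  am42 <- fit$adjusted_means$mean[fit$adjusted_means$timepoint == "m42"]
  raw <- mean(coh$weight_m42 - coh$weight_baseline)
  se <- sd(coh$weight_m42 - coh$weight_baseline) / sqrt(nrow(coh))
  expect_lt(abs(am42 - raw), 3 * se)
  expect_error(fit_repeated_measures(transform(lt, club_id = "C01")),
               "clubs")
})

test_that("non-response comparison picks the declared test per variable", {
  # identical subgroups: p = 1
  coh <- manual_cohort(rep("intervention", 6), rep(c(100, 110, 120), 2),
                       rep(99, 6), c(rep(98, 3), rep(NA, 3)))
  out <- nonresponse_comparison(coh, c(weight_baseline = "continuous_normal"))
  expect_equal(out$p_value, 1, tolerance = 1e-12)

  # Fisher 2x2 (10,0 / 0,10): exact two-sided p = 2 / choose(20, 10),
  # verified by hypergeometric enumeration
  coh2 <- manual_cohort(rep("intervention", 20), rep(100, 20), rep(99, 20),
                        c(rep(98, 10), rep(NA, 10)))
  coh2$sexvar <- c(rep("a", 10), rep("b", 10))
  out2 <- nonresponse_comparison(coh2, c(sexvar = "categorical"))
  p_enum <- sum(dhyper(c(0, 10), 10, 10, 10))  # only the two extreme tables
  expect_equal(out2$p_value, p_enum, tolerance = 1e-10)
  expect_equal(out2$test, "fisher")

  # heavier dropouts flagged significant at trial size
  coh3 <- generate_cohort(cohort_spec(seed = 35L))
  out3 <- nonresponse_comparison(coh3)
  expect_lt(out3$p_value[out3$variable == "weight_baseline"], 0.05)
  expect_gt(out3$mean_not_attended[out3$variable == "weight_baseline"],
            out3$mean_attended[out3$variable == "weight_baseline"])

  expect_error(nonresponse_comparison(transform(coh3, attended_42m = TRUE)),
               "non-empty")
})

test_that("study power for a 2.5% change is computable", {
  # monotone in n, and high at the realized follow-up sizes
  expect_gt(power_within_group(233), power_within_group(100))
  expect_gt(power_within_group(233), 0.6)
})
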