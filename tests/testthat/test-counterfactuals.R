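test_that("exactly six scenarios with the stated anchor/rate/exclusion design", {
  s <- list_scenarios()
  expect_equal(nrow(s), 6)
  expect_equal(s$anchor[s$scenario_id == "base"], "baseline")
  expect_equal(s$rate_source[s$scenario_id == "base"], "population")
  expect_equal(s$anchor[s$scenario_id %in% c("s2", "s3", "s4", "s5")],
               rep("month12", 4))
  expect_equal(s$rate_source[s$scenario_id %in% c("s1", "s3", "s5")],
               rep("ffit_regain", 3))
  expect_identical(s$exclude_12m_responders,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unique(s$population_rate), 0.46)
})

test_that("regain rate is mean 12m->42m change over 2.5 years", {
  coh <- manual_cohort(rep("intervention", 4), rep(100, 4),
                       rep(95, 4), 95 + c(2, 3, 2.5, 2.9))
  expect_equal(ffit_regain_rate(coh), mean(c(2, 3, 2.5, 2.9)) / 2.5)
  coh0 <- manual_cohort(rep("intervention", 3), rep(100, 3),
                        rep(95, 3), rep(95, 3))
  expect_equal(ffit_regain_rate(coh0), 0)
  coh5 <- manual_cohort(rep("intervention", 3), rep(100, 3),
                        rep(95, 3), rep(100, 3))
  expect_equal(ffit_regain_rate(coh5), 2.0)
})

test_that("weight extrapolation is the stated linear trajectory", {
  expect_equal(extrapolate_weight(100, 0, 0.46, 3.5), 101.61)
  expect_equal(extrapolate_weight(100, 1, 1.04, 3.5), 102.60)
  expect_equal(extrapolate_weight(87, 0, 0, c(1, 2, 3.5)), rep(87, 3))
  # affine: doubling the horizon doubles the increment
  inc1 <- extrapolate_weight(100, 1, 0.8, 2) - 100
  inc2 <- extrapolate_weight(100, 1, 0.8, 3) - 100
  expect_equal(inc2, 2 * inc1)
  expect_error(extrapolate_weight(100, 1, 0.46, 0.5), ">=")
})

test_that("responder exclusion removes exactly the 12-month responders", {
  w12m <- c(94, 95, 96, 99, 100, 101, 90, 97, 98, 95.0001)
  coh <- manual_cohort(rep("comparison", 10), rep(100, 10), w12m,
                       rep(99, 10))
  out <- apply_responder_exclusion(coh, 5)
  expect_equal(length(out$excluded_ids), 3)   # 94, 95 (inclusive), 90
  expect_equal(out$excluded_fraction, 0.3)
  none <- apply_responder_exclusion(coh, 100)
  expect_equal(nrow(none$cohort), 10)

  # spec calibrated so ~11% of the comparison group are 12-month responders
  prof <- default_change_profile()
  prof$comparison$sd[["m12"]] <-
    (0.05 * 109.5 + prof$comparison$mean[["m12"]]) / qnorm(0.89)
  spec <- cohort_spec(n_intervention = 0L, n_comparison = 8000L,
                      change_profile = prof, seed = 41L)
  coh2 <- generate_cohort(spec, with_attrition = FALSE,
                          with_costs_utilities = FALSE)
  frac <- apply_responder_exclusion(coh2, 5)$excluded_fraction
  expect_lt(abs(frac - 0.11), 0.02)
})

test_that("counterfactual construction honours anchors, rates and subsets", {
  spec <- small_spec(seed = 43L)
  coh <- generate_cohort(spec)
  scen <- list_scenarios()
  cfs <- lapply(seq_len(6), function(i)
    build_counterfactual(coh, scen[i, ], regain_rate = 1.04))
  names(cfs) <- scen$scenario_id

  # base case: anchor baseline, population rate
  base_cf <- cfs$base
  end <- base_cf[base_cf$time_years == 3.5, ]
  ids <- end$participant_id
  w0 <- coh$weight_baseline[match(ids, coh$participant_id)]
  expect_equal(end$weight, w0 + 0.46 * 3.5, tolerance = 1e-12)

  # s3: month12 anchor, regain rate; observed segment kept at 12 m
  s3 <- cfs$s3
  a <- s3[s3$time_years == 1, ]
  w12m <- coh$weight_m12[match(a$participant_id, coh$participant_id)]
  expect_equal(a$weight, w12m, tolerance = 1e-12)
  e3 <- s3[s3$time_years == 3.5, ]
  expect_equal(e3$weight,
               w12m[match(e3$participant_id, a$participant_id)] + 1.04 * 2.5,
               tolerance = 1e-12)

  # participant subsets: s4 within s2, s5 within s3, same excluded set
  id2 <- unique(cfs$s2$participant_id); id4 <- unique(cfs$s4$participant_id)
  id3 <- unique(cfs$s3$participant_id); id5 <- unique(cfs$s5$participant_id)
  expect_true(all(id4 %in% id2))
  expect_true(all(id5 %in% id3))
  expect_identical(setdiff(id2, id4), setdiff(id3, id5))

  # scenarios coincide when rates and anchors coincide and no exclusion
  s1_forced <- build_counterfactual(coh, scen[scen$scenario_id == "s1", ],
                                    regain_rate = 0.46)
  expect_equal(s1_forced$weight, cfs$base$weight, tolerance = 1e-12)

  # positivity and provenance
  expect_true(all(unlist(lapply(cfs, function(x) x$weight)) > 0))
  expect_equal(unique(cfs$s5$scenario_id), "s5")
})
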