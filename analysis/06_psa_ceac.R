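#!/usr/bin/env Rscript
# Stage 6 — probabilistic sensitivity analysis and acceptability curves.
#
# Propagates uncertainty in the hazard ratios, risk-factor advantages,
# utility slope, CVD state cost and within-trial incremental cost through
# the lifetime model (1000 seeded draws), then derives the CEAC by the
# net-monetary-benefit rule and locates the 50% willingness-to-pay crossing.

suppressPackageStartupMessages(library(wlmcea))

seed <- 20150301L
out_dir <- "results"
cohort <- read.csv(file.path(out_dir, "cohort_wide.csv"))
wt <- read.csv(file.path(out_dir, "within_trial_cea.csv"))
base_row <- wt[wt$scenario_id == "base", ]

lc <- cohort_long(cohort)
um <- fit_utility_bmi(lc$bmi, lc$utility, lc$participant_id)
prm <- lifetime_params(utility_intercept = um$intercept,
                       utility_slope = um$slope)

gi <- cohort$group == "intervention" & !is.na(cohort$weight_m42)
prof_int <- list(bmi = mean((cohort$weight_m42 / cohort$height^2)[gi]),
                 sbp = mean(cohort$sbp_m42[gi], na.rm = TRUE))
cf <- read.csv(file.path(out_dir, "counterfactual_base.csv"))
cf_end <- cf[cf$time_years == 3.5, ]
prof_ctl <- list(bmi = mean(cf_end$bmi), sbp = mean(cf_end$sbp))
prof <- list(intervention = prof_int, control = prof_ctl)

dists <- default_psa_distributions(
  prm, bmi_advantage = prof_ctl$bmi - prof_int$bmi,
  sbp_advantage = prof_ctl$sbp - prof_int$sbp,
  delta_cost_trial = base_row$delta_cost)

psa <- run_psa(prof, prm, dists, n_draws = 1000,
               seed = stage_seed(seed, "psa"),
               start_ages = round(mean(cohort$age[gi] + 3.5)))
psa$delta_qaly <- psa$delta_qaly + base_row$delta_qaly
write.csv(psa, file.path(out_dir, "psa_draws.csv"), row.names = FALSE)

curve <- ceac(psa)
write.csv(curve, file.path(out_dir, "ceac.csv"), row.names = FALSE)
crossing <- threshold_crossing(curve, 0.5)

pdf(file.path(out_dir, "ceac.pdf"), width = 6, height = 4)
plot(curve$wtp, curve$prob_cost_effective, type = "l",
     xlab = "Willingness to pay (GBP/QALY)", ylab = "P(cost-effective)",
     ylim = c(0, 1), main = "Cost-effectiveness acceptability curve")
abline(h = 0.5, lty = 2)
if (!is.na(crossing)) abline(v = crossing, lty = 3)
dev.off()

cat(sprintf("PSA: %d draws; mean dC %.0f GBP, mean dQ %.3f QALY\n",
            nrow(psa), mean(psa$delta_cost), mean(psa$delta_qaly)))
cat(sprintf("P(cost-effective) at 20,000 GBP/QALY: %.2f\n",
            curve$prob_cost_effective[curve$wtp == 20000]))
cat(sprintf("CEAC crosses 50%% at %s GBP/QALY\n",
            ifelse(is.na(crossing), "no crossing", sprintf("%.0f", crossing))))
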