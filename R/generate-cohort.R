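#' Derive a per-stage seed from a top-level seed
#'
#' A single top-level seed deterministically derives per-stage seeds by
#' hashing the stage name, so stages can be rerun in isolation without
#' sharing an RNG stream. Result always fits a 32-bit integer.
#'
#' @param seed Top-level integer seed.
#' @param stage Stage name (character).
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587)
}

timepoints_post <- c("w12", "m12", "m42")

#' Generate a synthetic trial cohort
#'
#' Draws participant-level data with the statistical structure the downstream
#' analysis assumes: baseline weight/SBP/age, per-person height (so BMI tracks
#' weight deterministically), correlated weight changes at 12 weeks, 12 months
#' and 42 months from a multivariate normal with exchangeable correlation on
#' the change scale, logistic attrition on the baseline-weight z-score, and
#' utility / resource-use fields. Fully reproducible given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param with_attrition Apply the attrition model (default `TRUE`).
#' @param with_costs_utilities Draw utilities and resource-use counts
#'   (default `TRUE`).
#' @return A wide data.frame, one row per participant, with columns
#'   `participant_id`, `group`, `club_id`, `age`, `height`,
#'   `weight_<tp>`, `sbp_<tp>`, `utility_<tp>`, `ru_<type>_<tp>` and the
#'   flags `consented_followup`, `attended_42m`, `weight_only_42m`.
#'   Unobserved fields are `NA`.
#' @export
generate_cohort <- function(spec, with_attrition = TRUE,
                            with_costs_utilities = TRUE) {
  validate_cohort_spec(spec)
  set.seed(stage_seed(spec$seed, "baseline"))

  n <- spec$n_intervention + spec$n_comparison
  group <- rep(c("intervention", "comparison"),
               c(spec$n_intervention, spec$n_comparison))
  cohort <- data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    group = group,
    club_id = sprintf("C%02d", sample.int(spec$n_clubs, n, replace = TRUE)),
    age = rnorm(n, spec$baseline_age_mean, spec$baseline_age_sd),
    height = pmax(rnorm(n, spec$height_mean, spec$height_sd), 1.2),
    stringsAsFactors = FALSE
  )
  cohort$weight_baseline <-
    pmax(rnorm(n, spec$baseline_weight_mean, spec$baseline_weight_sd), 1)
  cohort$sbp_baseline <-
    pmax(rnorm(n, spec$baseline_sbp_mean, spec$baseline_sbp_sd), 60)

  # correlated weight changes on the change scale, per group
  rho <- spec$within_person_correlation
  for (g in c("intervention", "comparison")) {
    idx <- which(cohort$group == g)
    prof <- spec$change_profile[[g]]
    obs <- which(!is.na(prof$mean))
    k <- length(obs)
    ch <- matrix(NA_real_, length(idx), 3,
                 dimnames = list(NULL, timepoints_post))
    if (k > 0) {
      R <- matrix(rho, k, k); diag(R) <- 1
      D <- diag(prof$sd[obs], k)
      S <- D %*% R %*% D
      # symmetric square root: robust to semidefinite cases (zero SDs, rho=1)
      E <- eigen(S, symmetric = TRUE)
      L <- E$vectors %*% diag(sqrt(pmax(E$values, 0)), k) %*% t(E$vectors)
      z <- matrix(rnorm(length(idx) * k), length(idx), k)
      ch[, obs] <- sweep(z %*% L, 2, prof$mean[obs], "+")
    }
    for (j in seq_along(timepoints_post)) {
      wt <- cohort$weight_baseline[idx] + ch[, j]
      cohort[idx, paste0("weight_", timepoints_post[j])] <-
        ifelse(is.na(wt), NA_real_, pmax(wt, 1))
    }
  }

  # follow-up SBP tracks weight change plus measurement noise
  for (tp in timepoints_post) {
    dw <- cohort[[paste0("weight_", tp)]] - cohort$weight_baseline
    cohort[[paste0("sbp_", tp)]] <-
      ifelse(is.na(dw), NA_real_,
             pmax(cohort$sbp_baseline + spec$sbp_change_per_kg * dw +
                    rnorm(n, 0, 6), 60))
  }

  if (with_attrition) {
    cohort <- apply_attrition(cohort, spec$dropout_model,
                              seed = stage_seed(spec$seed, "attrition"),
                              consent_prob = spec$consent_prob,
                              weight_only_prob = spec$weight_only_prob,
                              weight_mean = spec$baseline_weight_mean,
                              weight_sd = spec$baseline_weight_sd)
  } else {
    cohort$consented_followup <- TRUE
    cohort$attended_42m <- TRUE
    cohort$weight_only_42m <- FALSE
  }

  if (with_costs_utilities) {
    cohort <- generate_costs_and_utilities(
      cohort, spec, seed = stage_seed(spec$seed, "costs_utilities"))
  }
  cohort
}

#' Apply the attrition model to a cohort
#'
#' Sets `consented_followup` (Bernoulli at `consent_prob`) and, among
#' consenters, `attended_42m` from a logistic model on the baseline-weight
#' z-score: P(attend) = plogis(intercept + slope * z). A negative slope makes
#' heavier men less likely to attend, reproducing the observed pattern that
#' non-attenders were heavier at baseline (112.6 vs 107.8 kg). A fraction of
#' attenders provide weight-only data at 42 months (`weight_only_42m`).
#' Non-attenders have all 42-month fields blanked; weight-only attenders keep
#' weight but lose SBP (and later, utility/resource fields) at 42 months.
#'
#' @param cohort Wide cohort data.frame from [generate_cohort()].
#' @param dropout_model List `(intercept, slope)` on the z-score scale.
#' @param seed Integer seed.
#' @param consent_prob,weight_only_prob Flag probabilities.
#' @param weight_mean,weight_sd Standardization constants for the z-score;
#'   default to the cohort's own sample moments.
#' @return The cohort with flags set and 42-month fields masked accordingly.
#' @export
apply_attrition <- function(cohort, dropout_model, seed,
                            consent_prob = 1,
                            weight_only_prob = 0,
                            weight_mean = mean(cohort$weight_baseline),
                            weight_sd = stats::sd(cohort$weight_baseline)) {
  stopifnot(is.finite(dropout_model$slope), is.finite(dropout_model$intercept))
  set.seed(seed)
  n <- nrow(cohort)
  if (!is.finite(weight_sd) || weight_sd <= 0) weight_sd <- 1
  z <- (cohort$weight_baseline - weight_mean) / weight_sd
  p_attend <- stats::plogis(dropout_model$intercept + dropout_model$slope * z)
  cohort$consented_followup <- runif(n) < consent_prob
  cohort$attended_42m <- cohort$consented_followup & (runif(n) < p_attend)
  cohort$weight_only_42m <- cohort$attended_42m &
    (runif(n) < weight_only_prob)
  # masking: non-attenders contribute nothing at 42 m
  cohort$weight_m42[!cohort$attended_42m] <- NA_real_
  cohort$sbp_m42[!cohort$attended_42m | cohort$weight_only_42m] <- NA_real_
  cohort
}

#' Draw utilities and resource-use counts for a cohort
#'
#' Utility at each observed timepoint follows the latent linear model
#' `utility = intercept + slope * BMI + noise`, truncated to [0, 1]; BMI is
#' weight / height^2. Resource-use counts per 12-week recall window are
#' Poisson by resource type with the configured means, drawn at each observed
#' timepoint. Weight-only 42-month attenders have no questionnaire data, so
#' their 42-month utility and resource fields stay `NA`.
#'
#' @param cohort Wide cohort data.frame with attrition flags set.
#' @param spec The [cohort_spec()] (uses `utility_model_true`,
#'   `resource_use_rates`).
#' @param seed Integer seed.
#' @return The cohort augmented with `utility_<tp>` and `ru_<type>_<tp>`.
#' @export
generate_costs_and_utilities <- function(cohort, spec, seed) {
  stopifnot(all(spec$resource_use_rates >= 0))
  set.seed(seed)
  um <- spec$utility_model_true
  n <- nrow(cohort)
  tps <- c("baseline", timepoints_post)
  for (tp in tps) {
    w <- cohort[[paste0("weight_", tp)]]
    bmi <- w / cohort$height^2
    u <- um$intercept + um$slope * bmi + rnorm(n, 0, um$resid_sd)
    u <- pmin(pmax(u, 0), 1)
    u[is.na(w)] <- NA_real_
    if (tp == "m42") u[cohort$weight_only_42m] <- NA_real_
    cohort[[paste0("utility_", tp)]] <- u
  }
  for (type in names(spec$resource_use_rates)) {
    rate <- spec$resource_use_rates[[type]]
    for (tp in tps) {
      cnt <- rpois(n, rate)
      # questionnaire-based: absent wherever the visit yielded no weight,
      # and at 42 m for weight-only providers
      cnt[is.na(cohort[[paste0("weight_", tp)]])] <- NA_integer_
      if (tp == "m42") cnt[cohort$weight_only_42m] <- NA_integer_
      cohort[[paste0("ru_", type, "_", tp)]] <- cnt
    }
  }
  cohort
}

#' Reshape a wide cohort to long format (one row per participant-timepoint)
#'
#' @param cohort Wide cohort data.frame.
#' @return Long data.frame with columns `participant_id`, `group`, `club_id`,
#'   `timepoint`, `time_years`, `weight`, `bmi`, `sbp`, `utility` and one
#'   `ru_<type>` column per resource type. Rows for unobserved timepoints are
#'   retained with `NA` measurements.
#' @export
cohort_long <- function(cohort) {
  tps <- c("baseline", timepoints_post)
  ty <- timepoint_years()
  ru_types <- unique(sub("_(baseline|w12|m12|m42)$", "",
                         grep("^ru_", names(cohort), value = TRUE)))
  out <- do.call(rbind, lapply(tps, function(tp) {
    d <- data.frame(
      participant_id = cohort$participant_id,
      group = cohort$group,
      club_id = cohort$club_id,
      timepoint = tp,
      time_years = unname(ty[tp]),
      weight = cohort[[paste0("weight_", tp)]],
      bmi = cohort[[paste0("weight_", tp)]] / cohort$height^2,
      sbp = cohort[[paste0("sbp_", tp)]],
      utility = cohort[[paste0("utility_", tp)]],
      stringsAsFactors = FALSE
    )
    for (rt in ru_types) d[[rt]] <- cohort[[paste0(rt, "_", tp)]]
    d
  }))
  out$timepoint <- factor(out$timepoint, levels = tps)
  rownames(out) <- NULL
  out
}
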