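#' Within-group change from paired measurements
#'
#' Mean of per-person differences (follow-up minus baseline) with a t-based
#' 95% confidence interval (paired t-test). Negative mean change = loss;
#' reported "weight loss" is the negated mean change. A Wilcoxon signed-rank
#' p-value is reported alongside the parametric one, mirroring the mix of
#' tests quoted in trial reports.
#'
#' @param baseline,followup Numeric vectors of paired measurements; pairs with
#'   any `NA` are dropped (complete-case).
#' @param conf_level Confidence level (default 0.95).
#' @return A `change_estimate`: list with `n`, `mean_change`, `ci_low`,
#'   `ci_high`, `p_value` (paired t), `p_rank` (signed-rank), and
#'   `zero_variance` flag.
#' @export
within_group_change <- function(baseline, followup, conf_level = 0.95) {
  stopifnot(length(baseline) == length(followup))
  ok <- !is.na(baseline) & !is.na(followup)
  d <- followup[ok] - baseline[ok]
  if (length(d) < 2) stop("insufficient data: need >= 2 complete pairs")
  zero_var <- isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0
  if (zero_var) {
    est <- list(n = length(d), mean_change = mean(d), ci_low = mean(d),
                ci_high = mean(d),
                p_value = if (mean(d) == 0) 1 else 0,
                p_rank = NA_real_, zero_variance = TRUE)
  } else {
    tt <- stats::t.test(d, conf.level = conf_level)
    pr <- suppressWarnings(stats::wilcox.test(d)$p.value)
    est <- list(n = length(d), mean_change = unname(tt$estimate),
                ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                p_value = tt$p.value, p_rank = pr, zero_variance = FALSE)
  }
  structure(est, class = "change_estimate")
}

#' Between-group difference of change scores
#'
#' Welch (unequal-variance) two-sample t on per-person changes; the returned
#' difference is `mean(changes_b) - mean(changes_a)`. A Mann-Whitney rank
#' p-value is reported alongside.
#'
#' @param changes_a,changes_b Numeric change vectors (NA dropped).
#' @param conf_level Confidence level (default 0.95).
#' @return A `change_estimate` (n = total used; `p_rank` = Mann-Whitney).
#' @export
between_group_difference <- function(changes_a, changes_b, conf_level = 0.95) {
  a <- changes_a[!is.na(changes_a)]
  b <- changes_b[!is.na(changes_b)]
  if (length(a) < 2 || length(b) < 2)
    stop("insufficient data: each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    d <- mean(b) - mean(a)
    return(structure(list(n = length(a) + length(b), mean_change = d,
                          ci_low = d, ci_high = d,
                          p_value = if (d == 0) 1 else 0,
                          p_rank = NA_real_, zero_variance = TRUE),
                     class = "change_estimate"))
  }
  tt <- stats::t.test(b, a, var.equal = FALSE, conf.level = conf_level)
  pr <- suppressWarnings(stats::wilcox.test(b, a)$p.value)
  structure(list(n = length(a) + length(b),
                 mean_change = unname(tt$estimate[1] - tt$estimate[2]),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 p_value = tt$p.value, p_rank = pr, zero_variance = FALSE),
            class = "change_estimate")
}

#' Proportion of responders (at least `threshold_pct` weight loss)
#'
#' A responder weighs at least `threshold_pct`% less than baseline at
#' follow-up: (baseline - follow) / baseline >= threshold_pct / 100.
#' The threshold is inclusive. Complete pairs only.
#'
#' @param baseline,followup Paired weight vectors (kg).
#' @param threshold_pct Loss threshold in percent (default 5).
#' @return List `(n, count, proportion)`.
#' @export
responder_proportion <- function(baseline, followup, threshold_pct = 5) {
  ok <- !is.na(baseline) & !is.na(followup)
  if (!any(ok)) stop("no complete pairs")
  loss_frac <- (baseline[ok] - followup[ok]) / baseline[ok]
  count <- sum(loss_frac >= threshold_pct / 100)
  list(n = sum(ok), count = count, proportion = count / sum(ok))
}

#' Annualized rate of change
#'
#' @param change Change over the interval (e.g. kg).
#' @param elapsed_years Interval length in years; must be > 0.
#' @return change / elapsed_years (e.g. kg/year).
#' @export
annualized_rate <- function(change, elapsed_years) {
  if (any(elapsed_years <= 0)) stop("elapsed_years must be > 0")
  change / elapsed_years
}

#' Missing-data sensitivity imputation: baseline-carried-forward / LOCF
#'
#' Completes the 42-month change vector over the full randomized denominator
#' of one group. Baseline-carried-forward (BCF, "return to baseline") assigns
#' change 0 to participants with no 42-month weight; last-observation-carried-
#' forward (LOCF) assigns their last observed change (12 months, else
#' 12 weeks, else 0 at baseline).
#'
#' @param cohort Wide cohort data.frame.
#' @param group `"intervention"` or `"comparison"`.
#' @param method `"bcf"` or `"locf"`.
#' @return Numeric vector of completed 42-month changes, one per randomized
#'   participant in the group.
#' @export
impute_changes <- function(cohort, group = c("intervention", "comparison"),
                           method = c("bcf", "locf")) {
  group <- match.arg(group)
  method <- match.arg(method)
  d <- cohort[cohort$group == group, ]
  if (any(is.na(d$weight_baseline))) stop("every participant needs a baseline")
  ch42 <- d$weight_m42 - d$weight_baseline
  miss <- is.na(ch42)
  if (method == "bcf") {
    ch42[miss] <- 0
  } else {
    last <- ifelse(!is.na(d$weight_m12), d$weight_m12 - d$weight_baseline,
                   ifelse(!is.na(d$weight_w12),
                          d$weight_w12 - d$weight_baseline, 0))
    ch42[miss] <- last[miss]
  }
  ch42
}

#' @rdname impute_changes
#' @export
impute_bcf <- function(cohort, group) impute_changes(cohort, group, "bcf")

#' @rdname impute_changes
#' @export
impute_locf <- function(cohort, group) impute_changes(cohort, group, "locf")

#' Mixed-effects repeated-measures model of change from baseline
#'
#' Fits `change ~ baseline_centred + timepoint [+ group * timepoint]` with
#' random intercepts for participant and club (lme4), on the long change
#' table of post-baseline timepoints. Returns adjusted within-group means per
#' timepoint (at the mean baseline value) and, when `include_group_interaction`,
#' the between-group contrast per timepoint with Wald 95% CI.
#'
#' @param long_changes Data.frame with columns `participant_id`, `club_id`,
#'   `group`, `timepoint` (factor of post-baseline timepoints), `baseline`,
#'   `change`.
#' @param include_group_interaction Add group and group x timepoint fixed
#'   effects.
#' @return A `repeated_measures_result`: list with `fit`, `adjusted_means`
#'   (data.frame timepoint/group/mean), `contrasts` (per-timepoint
#'   group difference, CI, p; NULL unless interaction requested), and
#'   `variance_components` (participant, club, residual).
#' @export
fit_repeated_measures <- function(long_changes,
                                  include_group_interaction = FALSE) {
  d <- long_changes[!is.na(long_changes$change), ]
  d$timepoint <- droplevels(factor(d$timepoint))
  if (nlevels(d$timepoint) < 1) stop("no post-baseline timepoints")
  if (length(unique(d$club_id)) < 2)
    stop("need >= 2 clubs to estimate the club variance component")
  d$baseline_c <- d$baseline - mean(d$baseline)
  form <- if (include_group_interaction) {
    change ~ baseline_c + timepoint * group + (1 | participant_id) + (1 | club_id)
  } else {
    change ~ baseline_c + timepoint + (1 | participant_id) + (1 | club_id)
  }
  fit <- lme4::lmer(form, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular =
                                                  lme4::.makeCC("ignore", 1e-4)))
  fe <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  tps <- levels(d$timepoint)
  groups <- if (include_group_interaction) sort(unique(d$group)) else "all"

  contrast_row <- function(x) {  # x: coefficient weights
    est <- sum(x * fe)
    se <- sqrt(drop(t(x) %*% V %*% x))
    c(est = est, se = se, ci_low = est - 1.96 * se, ci_high = est + 1.96 * se,
      p = 2 * stats::pnorm(-abs(est / se)))
  }
  coef_weights <- function(tp, grp) {
    x <- setNames(numeric(length(fe)), names(fe))
    x["(Intercept)"] <- 1
    tn <- paste0("timepoint", tp)
    if (tn %in% names(x)) x[tn] <- 1
    if (include_group_interaction && grp == groups[2]) {
      gn <- grep("^group", names(x), value = TRUE)
      x[gn[!grepl(":", gn)]] <- 1
      int <- intersect(paste0(tn, ":", gn), names(x))
      x[int] <- 1
    }
    x
  }

  am <- do.call(rbind, lapply(tps, function(tp) {
    do.call(rbind, lapply(groups, function(g) {
      cr <- contrast_row(coef_weights(tp, g))
      data.frame(timepoint = tp, group = g, mean = cr["est"],
                 ci_low = cr["ci_low"], ci_high = cr["ci_high"],
                 row.names = NULL)
    }))
  }))

  contrasts <- NULL
  if (include_group_interaction) {
    contrasts <- do.call(rbind, lapply(tps, function(tp) {
      x <- coef_weights(tp, groups[2]) - coef_weights(tp, groups[1])
      cr <- contrast_row(x)
      data.frame(timepoint = tp, difference = cr["est"], se = cr["se"],
                 ci_low = cr["ci_low"], ci_high = cr["ci_high"], p = cr["p"],
                 row.names = NULL)
    }))
  }

  vc <- as.data.frame(lme4::VarCorr(fit))
  variance_components <- setNames(vc$vcov, vc$grp)
  structure(list(fit = fit, adjusted_means = am, contrasts = contrasts,
                 variance_components = variance_components),
            class = "repeated_measures_result")
}

#' Build the long change table consumed by [fit_repeated_measures()]
#'
#' @param cohort Wide cohort data.frame.
#' @param outcome Measurement prefix, e.g. `"weight"` or `"sbp"`.
#' @param timepoints Post-baseline timepoints to include.
#' @return Data.frame with `participant_id`, `club_id`, `group`, `timepoint`,
#'   `baseline`, `change`.
#' @export
long_change_table <- function(cohort, outcome = "weight",
                              timepoints = c("m12", "m42")) {
  base <- cohort[[paste0(outcome, "_baseline")]]
  out <- do.call(rbind, lapply(timepoints, function(tp) {
    data.frame(participant_id = cohort$participant_id,
               club_id = cohort$club_id, group = cohort$group,
               timepoint = tp, baseline = base,
               change = cohort[[paste0(outcome, "_", tp)]] - base,
               stringsAsFactors = FALSE)
  }))
  out$timepoint <- factor(out$timepoint, levels = timepoints)
  out
}

#' Compare baseline characteristics of attenders vs non-attenders
#'
#' Per variable, the test follows the declared type: `continuous_normal` uses
#' Welch's t; `continuous_skewed` uses Mann-Whitney; `categorical` uses
#' chi-squared, switching to Fisher's exact whenever any expected cell count
#' is 5 or below (the conservative variant of the usual small-cell rule).
#'
#' @param cohort Wide cohort data.frame with `attended_42m` set.
#' @param variables Named character vector mapping column name to type
#'   (`continuous_normal`, `continuous_skewed`, `categorical`).
#' @return Data.frame with `variable`, `test`, `statistic`, `p_value`,
#'   `mean_attended`, `mean_not_attended` (NA for categorical).
#' @export
nonresponse_comparison <- function(cohort,
                                   variables = c(weight_baseline = "continuous_normal",
                                                 sbp_baseline = "continuous_normal",
                                                 age = "continuous_normal")) {
  att <- cohort$attended_42m
  if (!any(att) || all(att)) stop("both subgroups must be non-empty")
  rows <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    x <- cohort[[v]][att]
    y <- cohort[[v]][!att]
    if (type == "continuous_normal") {
      tt <- stats::t.test(x, y)
      data.frame(variable = v, test = "welch_t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, mean_attended = mean(x, na.rm = TRUE),
                 mean_not_attended = mean(y, na.rm = TRUE))
    } else if (type == "continuous_skewed") {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      data.frame(variable = v, test = "mann_whitney",
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 mean_attended = stats::median(x, na.rm = TRUE),
                 mean_not_attended = stats::median(y, na.rm = TRUE))
    } else {
      tab <- table(cohort[[v]], att)
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected <= 5)) {
        ft <- stats::fisher.test(tab)
        data.frame(variable = v, test = "fisher", statistic = NA_real_,
                   p_value = ft$p.value, mean_attended = NA_real_,
                   mean_not_attended = NA_real_)
      } else {
        ct <- stats::chisq.test(tab)
        data.frame(variable = v, test = "chi_squared",
                   statistic = unname(ct$statistic), p_value = ct$p.value,
                   mean_attended = NA_real_, mean_not_attended = NA_real_)
      }
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power for detecting a within-group percent weight change
#'
#' One-sample two-sided t-test power at significance level `alpha`, for a
#' true mean percent change `delta_pct` against SD `sd_pct`.
#'
#' @param n Sample size.
#' @param delta_pct True mean percent change (e.g. 2.5).
#' @param sd_pct SD of percent change (e.g. 15).
#' @param alpha Two-sided significance level.
#' @return Power in [0, 1].
#' @export
power_within_group <- function(n, delta_pct = 2.5, sd_pct = 15, alpha = 0.05) {
  stats::power.t.test(n = n, delta = delta_pct, sd = sd_pct,
                      sig.level = alpha, type = "one.sample",
                      alternative = "two.sided")$power
}

#' @export
print.change_estimate <- function(x, ...) {
  cat(sprintf("change estimate: n=%d, mean %.3f (95%% CI %.3f, %.3f), p=%.4g\n",
              x$n, x$mean_change, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}
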