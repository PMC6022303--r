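#' Fit the utility-vs-BMI regression with cluster-robust standard errors
#'
#' Health utilities (SF-6D-like, [0, 1] scale) observed repeatedly per person
#' are regressed on BMI by ordinary least squares; standard errors are
#' cluster-robust on participant (CR1 sandwich with the usual small-sample
#' correction M/(M-1) * (N-1)/(N-K)), since each person contributes several
#' observations. Age is deliberately absent: it was dropped in the emulated
#' analysis as unassociated with utility.
#'
#' @param bmi,utility Numeric vectors of observations.
#' @param cluster Cluster id per observation (participant).
#' @return A `utility_bmi_model`: list with `intercept`, `slope`,
#'   `cluster_robust_se` (named, per coefficient), `n_obs`, `n_clusters`,
#'   `sigma` (residual SD).
#' @export
fit_utility_bmi <- function(bmi, utility, cluster) {
  ok <- !is.na(bmi) & !is.na(utility) & !is.na(cluster)
  bmi <- bmi[ok]; utility <- utility[ok]; cluster <- cluster[ok]
  if (length(unique(bmi)) < 2) stop("degenerate design: need >= 2 distinct BMI values")
  if (length(unique(cluster)) < 2) stop("need >= 2 clusters for cluster-robust SEs")
  fit <- stats::lm(utility ~ bmi)
  X <- stats::model.matrix(fit)
  e <- stats::residuals(fit)
  bread <- solve(crossprod(X))
  cl <- split(seq_along(e), cluster)
  meat <- Reduce(`+`, lapply(cl, function(idx) {
    s <- crossprod(X[idx, , drop = FALSE], e[idx])
    s %*% t(s)
  }))
  M <- length(cl); N <- length(e); K <- ncol(X)
  corr <- (M / (M - 1)) * ((N - 1) / (N - K))
  V <- corr * bread %*% meat %*% bread
  co <- stats::coef(fit)
  structure(list(intercept = unname(co[1]), slope = unname(co[2]),
                 cluster_robust_se = setNames(sqrt(diag(V)),
                                              c("intercept", "slope")),
                 n_obs = N, n_clusters = M,
                 sigma = stats::sigma(fit)),
            class = "utility_bmi_model")
}

#' Predict health utility from BMI
#'
#' intercept + slope * BMI, clamped to [0, 1]. An attribute `clamped` marks
#' predictions that hit the bounds.
#'
#' @param model A [fit_utility_bmi()] model (or any list with `intercept`,
#'   `slope`).
#' @param bmi BMI values.
#' @return Utilities in [0, 1], with logical attribute `clamped`.
#' @export
predict_utility <- function(model, bmi) {
  raw <- model$intercept + model$slope * bmi
  out <- pmin(pmax(raw, 0), 1)
  attr(out, "clamped") <- !is.na(raw) & (raw < 0 | raw > 1)
  out
}

#' Discounted quality-adjusted life years by trapezoidal integration
#'
#' Discounts the utility profile pointwise at `discount_rate`
#' (u(t) / (1 + r)^t) and integrates by the trapezoid rule over the observed
#' timepoint grid. `NA` utilities are dropped (integration over the observed
#' sub-grid).
#'
#' @param utilities Utility at each timepoint.
#' @param times Years since baseline, strictly increasing, starting at 0.
#' @param discount_rate Annual rate (default 0.035).
#' @return QALYs (scalar).
#' @export
qaly_auc <- function(utilities, times, discount_rate = 0.035) {
  stopifnot(length(utilities) == length(times))
  ok <- !is.na(utilities) & !is.na(times)
  u <- utilities[ok]; t <- times[ok]
  if (length(t) < 2) return(NA_real_)
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  du <- discount(u, t, discount_rate)
  sum(diff(t) * (head(du, -1) + du[-1]) / 2)
}

#' Mean incremental QALY between matched factual and counterfactual cohorts
#'
#' Per participant present in both sets, the QALY difference
#' (factual - counterfactual) over the within-trial horizon; returns the mean
#' and the paired components.
#'
#' @param factual Data.frame `participant_id`, `time_years`, `utility`
#'   (long).
#' @param counterfactual Same schema.
#' @param discount_rate Annual rate.
#' @return List `(mean_delta_qaly, per_participant)` where `per_participant`
#'   has `participant_id`, `qaly_factual`, `qaly_counterfactual`, `delta`.
#' @export
incremental_qaly <- function(factual, counterfactual, discount_rate = 0.035) {
  ids <- intersect(unique(factual$participant_id),
                   unique(counterfactual$participant_id))
  if (length(ids) == 0) stop("no matched participants between cohorts")
  one <- function(d, id) {
    di <- d[d$participant_id == id, ]
    di <- di[order(di$time_years), ]
    qaly_auc(di$utility, di$time_years, discount_rate)
  }
  qa <- vapply(ids, function(id) one(factual, id), numeric(1))
  qb <- vapply(ids, function(id) one(counterfactual, id), numeric(1))
  pp <- data.frame(participant_id = ids, qaly_factual = qa,
                   qaly_counterfactual = qb, delta = qa - qb,
                   stringsAsFactors = FALSE)
  list(mean_delta_qaly = mean(pp$delta, na.rm = TRUE), per_participant = pp)
}

#' Per-participant discounted within-trial QALYs for a wide cohort
#'
#' Integrates each participant's observed utility profile over the follow-up
#' grid (baseline, 12 weeks, 12 months, 3.5 years), via [qaly_auc()].
#' By default only participants whose observed grid spans the full horizon
#' (utility at baseline and at 3.5 years) get a QALY; others are `NA`, so
#' that partial-horizon integrals are never averaged with full-horizon ones.
#'
#' @param cohort Wide cohort data.frame with `utility_<tp>` columns.
#' @param discount_rate Annual rate.
#' @param require_full_horizon Set `NA` for participants without a 3.5-year
#'   utility (default `TRUE`).
#' @return Data.frame `participant_id`, `group`, `qaly`.
#' @export
cohort_qalys <- function(cohort, discount_rate = 0.035,
                         require_full_horizon = TRUE) {
  ty <- timepoint_years()
  U <- as.matrix(cohort[, paste0("utility_", names(ty))])
  qaly <- apply(U, 1, function(u) qaly_auc(u, unname(ty), discount_rate))
  if (require_full_horizon) {
    qaly[is.na(U[, "utility_baseline"]) | is.na(U[, "utility_m42"])] <- NA_real_
  }
  data.frame(participant_id = cohort$participant_id, group = cohort$group,
             qaly = qaly, stringsAsFactors = FALSE)
}
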