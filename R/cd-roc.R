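# Cumulative/dynamic (C/D) estimators: cases are subjects with an event
# in (0, t], controls are subjects event-free beyond t.

.cd_check_t <- function(t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0) stop("t must be a positive scalar")
}

#' Naive time-dependent ROC curve
#'
#' Empirical sensitivity over observed events before `t` and empirical
#' specificity over subjects observed beyond `t`; censored subjects
#' before `t` are simply discarded. Biased under censoring but the
#' reference point every other cumulative/dynamic estimator reduces to
#' on uncensored data.
#'
#' @param cohort A [baseline_cohort()].
#' @param t Evaluation time.
#' @return A `td_roc` object (see [auc_value()], [plot.td_roc()]).
#' @export
naive_roc <- function(cohort, t) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  case <- cohort$event == 1 & cohort$time <= t
  ctrl <- cohort$time > t
  if (!any(case) || !any(ctrl))
    stop("AUC undefined at t = ", t, ": empty case or control set")
  X <- cohort$marker
  grid <- .threshold_grid(X)
  sens <- .surv_curve(X[case], rep(1, sum(case)), grid)
  fpr <- .surv_curve(X[ctrl], rep(1, sum(ctrl)), grid)
  auc <- .pairwise_auc(X[case], rep(1, sum(case)), X[ctrl], rep(1, sum(ctrl)))
  new_td_roc(t, grid, sens, fpr, "naive", auc = auc)
}

#' Conditional Kaplan-Meier (Bayes) ROC estimator
#'
#' Sensitivity and specificity obtained from Bayes' theorem with
#' conditional Kaplan-Meier estimates on the threshold subsets
#' `X > c` and `X <= c` together with the empirical marker distribution.
#' The implied quadrant probabilities need not form a valid bivariate
#' distribution, so the raw sensitivity/specificity can be non-monotone
#' or exit `[0, 1]`; out-of-range values are flagged, never clipped.
#' The conditional Kaplan-Meier also assumes censoring does not depend
#' on the marker.
#'
#' @inheritParams naive_roc
#' @return A `td_roc` object; `$flags` records boundary violations.
#' @export
cd1_roc <- function(cohort, t) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  X <- cohort$marker; n <- nrow(cohort)
  S <- surv_at(km_curve(cohort), t)
  if (S <= 0 || S >= 1)
    stop("marginal survival at t must lie strictly inside (0,1)")
  Fx <- stats::ecdf(X)
  grid <- .threshold_grid(X)
  sens <- fpr <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    cc <- grid[k]
    hi <- X > cc; lo <- !hi
    s_hi <- if (any(hi)) surv_at(.wkm(cohort$time[hi], cohort$event[hi]), t) else NA_real_
    s_lo <- if (any(lo)) surv_at(.wkm(cohort$time[lo], cohort$event[lo]), t) else NA_real_
    sens[k] <- if (any(hi)) (1 - s_hi) * (1 - Fx(cc)) / (1 - S) else 0
    sp <- if (any(lo)) s_lo * Fx(cc) / S else 0
    fpr[k] <- 1 - sp
  }
  flags <- character(0)
  if (any(sens < -1e-12 | sens > 1 + 1e-12, na.rm = TRUE) ||
      any(fpr < -1e-12 | fpr > 1 + 1e-12, na.rm = TRUE))
    flags <- "sensitivity/specificity outside [0,1]"
  ok <- is.finite(sens) & is.finite(fpr)
  new_td_roc(t, grid[ok], sens[ok], fpr[ok], "cd1", flags = flags)
}

#' Nearest-neighbour bivariate-survival ROC estimator
#'
#' Plug-in of the Akritas nearest-neighbour estimator of the bivariate
#' survival function of (marker, event time):
#' `Se(c,t) = ((1 - F_X(c)) - S_l(c,t)) / (1 - S_l(t))` and
#' `Sp(c,t) = 1 - S_l(c,t)/S_l(t)`. Monotone, bounded in `[0, 1]`,
#' invariant to strictly increasing marker transformations, and robust
#' to marker-dependent censoring.
#'
#' @inheritParams naive_roc
#' @param lambda Nearest-neighbour half-width ([nne_config()] or a
#'   number); `NULL` gives the `0.25 n^(-1/3)` default.
#' @return A `td_roc` object.
#' @export
cd2_roc <- function(cohort, t, lambda = NULL) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  X <- cohort$marker; n <- nrow(cohort)
  surf <- nne_bivariate(cohort, lambda)
  s_i <- attr(surf, "cond_surv")(t)          # S_lambda(t | X_i) per subject
  St <- mean(s_i)                            # marginal S_lambda(t)
  if (St <= 0 || St >= 1)
    stop("smoothed marginal survival at t must lie strictly inside (0,1)")
  grid <- .threshold_grid(X)
  sens <- vapply(grid, function(cc) mean((X > cc) * (1 - s_i)), 0) / (1 - St)
  fpr <- vapply(grid, function(cc) mean((X > cc) * s_i), 0) / St
  new_td_roc(t, grid, sens, fpr, "cd2")
}

# per-event weights of the Kaplan-Meier-like recursion: each subject
# with an event at the k-th distinct event time <= t carries
# (S(t_{k-1}) - S(t_k)) / d_k, the KM mass of its increment.
.cd3_weights <- function(cohort, t) {
  km <- km_curve(cohort)
  ev <- cohort$event == 1 & cohort$time <= t
  if (!any(ev)) stop("no observed event at or before t = ", t)
  tev <- km$time[km$time <= t]
  Sk <- km$surv[km$time <= t]
  Sprev <- c(1, Sk[-length(Sk)])
  inc <- Sprev - Sk
  dk <- as.numeric(table(factor(cohort$time[ev], levels = tev)))
  w <- rep(0, nrow(cohort))
  w[ev] <- (inc / dk)[match(cohort$time[ev], tev)]
  list(w = w, S_tm = Sk[length(Sk)], ev = ev)
}

#' Kaplan-Meier-like recursive ROC estimator
#'
#' The closed-form revision of the Kaplan-Meier-like recursion:
#' sensitivity accumulates the marker indicators of the subjects dying
#' at each ordered event time, weighted by the Kaplan-Meier increment
#' of that time, normalised by `1 - S(t_m)` (with `t_m` the last event
#' time before `t`); specificity subtracts the same mass from the
#' marker's empirical distribution, normalised by `S(t_m)`. Sensitivity
#' is monotone and bounded; specificity can be non-monotone.
#'
#' @inheritParams naive_roc
#' @return A `td_roc` object.
#' @export
cd3_roc <- function(cohort, t) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  X <- cohort$marker; n <- nrow(cohort)
  cw <- .cd3_weights(cohort, t)
  grid <- .threshold_grid(X)
  denom <- 1 - cw$S_tm
  sens <- vapply(grid, function(cc) sum(cw$w * (X > cc)), 0) / denom
  Fx <- stats::ecdf(X)
  sp <- (Fx(grid) - vapply(grid, function(cc) sum(cw$w * (X <= cc)), 0)) / cw$S_tm
  new_td_roc(t, grid, sens, 1 - sp, "cd3")
}

#' Cox-model risk-weighted ROC estimator
#'
#' Model-based estimator that weights every subject by its conditional
#' absolute risk under a proportional-hazards fit of the marker:
#' `Se(c,t)` averages `1 - S(t|X_i)` over `X_i > c` and `Sp(c,t)`
#' averages `S(t|X_i)` over `X_i <= c` (expectations replaced by sample
#' means). Monotone when the marker is a survival-model score, but not
#' invariant to increasing marker transformations.
#'
#' @inheritParams naive_roc
#' @param fit Optional [ph_fit()]; fitted on `cohort` when `NULL`.
#' @return A `td_roc` object.
#' @export
cd4_roc <- function(cohort, t, fit = NULL) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  if (is.null(fit)) fit <- ph_fit(cohort)
  X <- cohort$marker
  risk <- cox_risk(fit, t, X)              # 1 - S(t | X_i)
  grid <- .threshold_grid(X)
  sens <- vapply(grid, function(cc) mean(risk * (X > cc)), 0) / mean(risk)
  fpr <- vapply(grid, function(cc) mean((1 - risk) * (X > cc)), 0) / mean(1 - risk)
  new_td_roc(t, grid, sens, fpr, "cd4")
}

# IPCW event weights delta_i / G(Z_i-) for events at or before t
.ipcw_weights <- function(cohort, t, cond_curves = NULL, left = TRUE) {
  ev <- cohort$event == 1 & cohort$time <= t
  if (!any(ev)) stop("no observed event at or before t = ", t)
  if (is.null(cond_curves)) {
    G <- censoring_km(cohort)
    g <- surv_at(G, cohort$time, left = left)
  } else {
    g <- vapply(seq_len(nrow(cohort)),
                function(i) surv_at(cond_curves[[i]], cohort$time[i], left = left), 0)
  }
  if (any(g[ev] <= 0))
    stop("zero censoring-survival weight before t; truncate t below the ",
         "largest observed time")
  w <- rep(0, nrow(cohort))
  w[ev] <- 1 / g[ev]
  list(w = w, ev = ev)
}

#' Inverse-probability-of-censoring-weighted ROC estimator
#'
#' Modifies the naive estimator by weighting each observed event before
#' `t` by the inverse of the censoring-distribution survival probability
#' at its event time (evaluated at the left limit by default);
#' specificity is the naive one. Monotone and bounded; its sensitivity
#' coincides with the Kaplan-Meier-like recursion's.
#'
#' @inheritParams naive_roc
#' @param left Evaluate the censoring curve at the left limit `Z_i-`
#'   (default) rather than at `Z_i`.
#' @return A `td_roc` object.
#' @export
cd5_roc <- function(cohort, t, left = TRUE) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  X <- cohort$marker
  ipw <- .ipcw_weights(cohort, t, left = left)
  ctrl <- cohort$time > t
  if (!any(ctrl)) stop("no subject observed beyond t = ", t)
  grid <- .threshold_grid(X)
  sens <- .surv_curve(X, ipw$w, grid)
  fpr <- .surv_curve(X[ctrl], rep(1, sum(ctrl)), grid)
  auc <- .pairwise_auc(X[ipw$ev], ipw$w[ipw$ev], X[ctrl], rep(1, sum(ctrl)))
  new_td_roc(t, grid, sens, fpr, "cd5", auc = auc)
}

# conditional censoring survival curves, one per subject
.cond_censor_curves <- function(cohort, model = c("nne", "ph"), lambda = NULL) {
  model <- match.arg(model)
  n <- nrow(cohort)
  if (model == "nne") {
    lam <- .nne_lambda(lambda, n)
    Fx <- stats::ecdf(cohort$marker)(cohort$marker)
    lapply(seq_len(n), function(i)
      .wkm_censor(cohort$time, cohort$event,
                  as.numeric(abs(Fx - Fx[i]) < lam)))
  } else {
    cfit <- ph_fit(baseline_cohort(cohort$id, cohort$time, 1 - cohort$event,
                                   cohort$marker))
    bh <- cfit$baseline_cumhaz
    lapply(seq_len(n), function(i) {
      haz <- bh$hazard * exp(cfit$gamma * cohort$marker[i])
      step_surv(bh$time, exp(-haz))
    })
  }
}

#' Conditional IPCW ROC estimator
#'
#' Inverse weighting by the conditional probability of being uncensored
#' given the marker: the sensitivity weights are
#' `delta_i / S_c(Z_i- | X_i)` and the specificity reweights survivors
#' by `1 / S_c(t | X_i)`. The conditional censoring survival is
#' estimated by the nearest-neighbour weighted Kaplan-Meier on censoring
#' times by default (a proportional-hazards censoring model is available
#' with `censoring_model = "ph"`). Robust to marker-dependent censoring.
#'
#' @inheritParams cd5_roc
#' @param censoring_model `"nne"` (default) or `"ph"`.
#' @param lambda Nearest-neighbour half-width for the censoring model.
#' @return A `td_roc` object.
#' @export
cd6_roc <- function(cohort, t, censoring_model = c("nne", "ph"),
                    lambda = NULL, left = TRUE) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  X <- cohort$marker; n <- nrow(cohort)
  curves <- .cond_censor_curves(cohort, match.arg(censoring_model), lambda)
  ipw <- .ipcw_weights(cohort, t, cond_curves = curves, left = left)
  ctrl <- cohort$time > t
  if (!any(ctrl)) stop("no subject observed beyond t = ", t)
  gt <- vapply(curves, surv_at, 0, t = t)
  if (any(gt[ctrl] <= 0))
    stop("zero conditional censoring-survival weight at t; truncate t")
  wq <- rep(0, n); wq[ctrl] <- 1 / gt[ctrl]
  grid <- .threshold_grid(X)
  sens <- .surv_curve(X, ipw$w, grid)
  fpr <- .surv_curve(X, wq, grid)
  auc <- .pairwise_auc(X[ipw$ev], ipw$w[ipw$ev], X[ctrl], wq[ctrl])
  new_td_roc(t, grid, sens, fpr, "cd6", auc = auc)
}

#' Interval-weighted cumulative/dynamic AUC
#'
#' Kaplan-Meier-increment-weighted average of a cumulative/dynamic AUC
#' over the distinct event times inside `(tau1, tau2]`. Increment
#' magnitudes are used as weights and normalised to sum to one, so a
#' constant AUC over the interval is returned unchanged.
#'
#' @inheritParams naive_roc
#' @param tau1,tau2 Interval bounds, `tau1 < tau2 <= max(Z)`.
#' @param base Base estimator: a method name among
#'   `"naive","cd1","cd2","cd3","cd4","cd5","cd6"` or a function
#'   `f(cohort, t)` returning something [auc_value()] understands.
#' @param ... Passed to the base estimator.
#' @return A `td_auc` object (at `t = tau2`), with the per-time table in
#'   attribute `"detail"`.
#' @export
cd7_weighted_auc <- function(cohort, tau1, tau2, base = "cd2", ...) {
  cohort <- .as_cohort(cohort)
  if (!(tau1 < tau2)) stop("tau1 must be smaller than tau2")
  if (tau2 > max(cohort$time)) stop("tau2 exceeds the largest observed time")
  km <- km_curve(cohort)
  tev <- km$time[km$time > tau1 & km$time <= tau2]
  if (!length(tev)) stop("no event times inside (tau1, tau2]")
  if (!(surv_at(km, tau1) > surv_at(km, tau2)))
    stop("no Kaplan-Meier mass inside (tau1, tau2]")
  f <- if (is.function(base)) base else .cd_method_fun(base)
  aucs <- vapply(tev, function(tt) auc_value(f(cohort, tt, ...)), 0)
  Sprev <- surv_at(km, c(tau1, tev[-length(tev)]))
  w <- abs(Sprev - surv_at(km, tev))
  w <- w / sum(w)
  out <- new_td_auc(tau2, sum(w * aucs),
                    paste0("cd7[", if (is.function(base)) "custom" else base, "]"))
  attr(out, "detail") <- data.frame(t = tev, auc = aucs, weight = w)
  out
}

.cd_method_fun <- function(name) {
  switch(name,
         naive = naive_roc, cd1 = cd1_roc, cd2 = cd2_roc, cd3 = cd3_roc,
         cd4 = cd4_roc, cd5 = cd5_roc, cd6 = cd6_roc,
         stop("unknown cumulative/dynamic method: ", name))
}

# rank form of the risk plug-in AUC: the U-statistic
# sum_{i != j} I(X_i > X_j) F_i (1 - F_j) / sum_{i != j} F_i (1 - F_j),
# computed in O(n log n) via cumulative sums on the marker order
# (half-weight ties handled by the explicit pairwise fall-back).
# Self-pairs are excluded from numerator and denominator alike, so a
# constant risk profile gives exactly 1/2 (exchangeability).
.risk_rank_auc <- function(X, F) {
  n <- length(X)
  denom <- sum(F) * sum(1 - F) - sum(F * (1 - F))
  if (anyDuplicated(X)) {
    num <- 0
    for (i in seq_len(n))
      num <- num + F[i] * sum(((X[i] > X) + 0.5 * (X[i] == X)) * (1 - F)) -
        0.5 * F[i] * (1 - F[i])
    return(num / denom)
  }
  o <- order(X)
  Fo <- F[o]
  num <- sum(Fo * (seq_len(n) - 1)) - sum(Fo * (cumsum(Fo) - Fo))
  num / denom
}

#' Conditional absolute-risk plug-in AUC
#'
#' Plug-in AUC built from an estimate of the conditional absolute risk
#' `F(t; x) = P(T <= t | X = x)` under one of three working models:
#' a Cox proportional-hazards model (`vl_cox`), an Aalen additive
#' hazards model (`vl_aalen`), or the nearest-neighbour conditional
#' Kaplan-Meier (`vl_km`, smoothing parameter `0.25 n^(-1/5)` by
#' default). The statistic is computed in a rank form equal to the
#' pairwise double sum
#' `sum_{i != j} I(X_i > X_j) F_i (1 - F_j) / sum_{i != j} F_i (1 - F_j)`.
#'
#' @inheritParams naive_roc
#' @param variant `"vl_cox"`, `"vl_aalen"` or `"vl_km"`.
#' @param lambda Smoothing half-width for `vl_km`.
#' @return A `td_auc` object with the per-subject risks in attribute
#'   `"risk"`.
#' @export
cd8_auc <- function(cohort, t, variant = c("vl_cox", "vl_aalen", "vl_km"),
                    lambda = NULL) {
  cohort <- .as_cohort(cohort); .cd_check_t(t)
  variant <- match.arg(variant)
  X <- cohort$marker; n <- nrow(cohort)
  F <- switch(variant,
    vl_cox = cox_risk(ph_fit(cohort), t, X),
    vl_aalen = {
      b <- additive_coef_at(additive_fit(cohort), t)
      pmin(pmax(1 - exp(-b["b0"] - b["b1"] * X), 0), 1)
    },
    vl_km = {
      lam <- .nne_lambda(lambda, n, default = 0.25 * n^(-1/5))
      surf <- nne_bivariate(cohort, nne_config(lam))
      1 - attr(surf, "cond_surv")(t)
    })
  Fbar <- mean(F)
  if (Fbar <= 0 || Fbar >= 1)
    stop("AUC undefined: conditional risks are degenerate (all 0 or all 1)")
  out <- new_td_auc(t, .risk_rank_auc(X, F), variant)
  attr(out, "risk") <- F
  out
}
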