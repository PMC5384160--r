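# Incident/static and longitudinal-marker methods: extended riskset Cox
# with static controls, landmark last-value nearest-neighbour
# estimation, and the induced-binormal / ROC-GLM models built on serial
# marker measurements.

#' Incident/static AUC with static controls
#'
#' Extends the riskset Cox-regression estimator to the incident/static
#' definition: cases are subjects with an event exactly at `t`, but the
#' controls are the static long-term survivors beyond a fixed follow-up
#' horizon `t_star` (`t < t_star`), instead of the dynamic controls
#' beyond `t`. Sensitivity uses the exponentially tilted weights of the
#' redefined risk set (cases plus static controls); specificity is
#' empirical over the static controls. With a longitudinal cohort the
#' marker is each subject's most recent value before `landmark`
#' ([last_value_cohort()]).
#'
#' @param cohort A [baseline_cohort()] or [longitudinal_cohort()].
#' @param t An observed event time, `t < t_star`.
#' @param t_star Fixed follow-up horizon defining the static controls.
#' @param landmark Landmark for the last-value marker (longitudinal
#'   cohorts only; default 0 keeps the earliest visit semantics via
#'   `landmark = NULL` -> baseline not allowed, supply a value).
#' @param tv A [smooth_tv_coef()] result, fixed number, or `NULL` to fit
#'   internally on the analysis cohort.
#' @return A `td_roc` object.
#' @export
is2_auc <- function(cohort, t, t_star, landmark = NULL, tv = NULL) {
  if (inherits(cohort, "longitudinal_cohort")) {
    if (is.null(landmark)) stop("a landmark is required for longitudinal input")
    cohort <- last_value_cohort(cohort, landmark)
  }
  cohort <- .as_cohort(cohort)
  if (!(t < t_star)) stop("t must be smaller than t_star")
  .require_event_time(cohort, t)
  case <- which(cohort$time == t & cohort$event == 1)
  ctrl <- which(cohort$time > t_star)
  if (!length(ctrl))
    stop("empty static control set: no subject observed beyond t_star = ", t_star)
  if (is.null(tv)) tv <- smooth_tv_coef(ph_fit(cohort))
  g <- tv_coef_at(tv, t)
  X <- cohort$marker
  idx <- c(case, ctrl)
  ew <- exp(g * X[idx] - max(g * X[idx]))
  pi_i <- ew / sum(ew)
  grid <- .threshold_grid(X[idx])
  sens <- vapply(grid, function(cc) sum(pi_i * (X[idx] > cc)), 0)
  xq <- X[ctrl]
  fpr <- .surv_curve(xq, rep(1, length(xq)), grid)
  auc <- .pairwise_auc(X[idx], pi_i, xq, rep(1, length(xq)))
  new_td_roc(t, grid, sens, fpr, "is2", auc = auc)
}

#' Landmark nearest-neighbour ROC for a longitudinal marker
#'
#' The nearest-neighbour bivariate-survival estimator ([cd2_roc()])
#' applied to the landmark last-value cohort: subjects at risk beyond
#' the landmark `s0`, each carrying its most recent marker value before
#' `s0`, evaluated at horizon `t > s0` on the original time scale.
#' Inherits the monotonicity, boundedness and transform-invariance of
#' the nearest-neighbour estimator. With single-baseline-visit data and
#' any landmark before the first event this reduces exactly to
#' [cd2_roc()] on the baseline cohort.
#'
#' @param lc A [longitudinal_cohort()].
#' @param landmark Landmark time `s0`.
#' @param t Horizon, `t > s0`.
#' @param lambda Nearest-neighbour half-width (see [nne_config()]).
#' @return A `td_roc` object.
#' @export
ecd2_roc <- function(lc, landmark, t, lambda = NULL) {
  if (!(t > landmark)) stop("t must exceed the landmark")
  bc <- last_value_cohort(lc, landmark)
  out <- cd2_roc(bc, t, lambda)
  out$method <- "ecd2"
  out
}

#' Assemble a case/control mixed-model fit from estimates
#'
#' Container for the parameters of the paired linear mixed-effects
#' models behind the induced binormal ROC: a case model with fixed
#' effects for visit time, time before event and their interaction, and
#' a control model with visit time only; both with correlated random
#' intercept and visit-time slope plus a residual SD. Useful both for
#' [ad1_fit()] output and for published estimates.
#'
#' @param case_fixef Case fixed effects `(b0, b_vt, b_tbe, b_vt:tbe)`.
#' @param control_fixef Control fixed effects `(b0, b_vt)`.
#' @param case_ranef_sd,control_ranef_sd Length-2 SDs of the random
#'   intercept and visit-time slope.
#' @param case_ranef_cor,control_ranef_cor Intercept-slope correlation.
#' @param case_resid_sd,control_resid_sd Residual SDs (> 0).
#' @return An object of class `mixed_model_fit` with per-group elements
#'   `beta`, `V` (2x2 random-effect covariance) and `sigma`.
#' @export
mixed_model_fit <- function(case_fixef, control_fixef,
                            case_ranef_sd, case_ranef_cor, case_resid_sd,
                            control_ranef_sd, control_ranef_cor,
                            control_resid_sd) {
  mk <- function(sd2, rho, sigma, beta, k) {
    if (length(beta) != k) stop("wrong number of fixed effects")
    if (sigma <= 0) stop("residual SD must be > 0")
    V <- matrix(c(sd2[1]^2, rho * sd2[1] * sd2[2],
                  rho * sd2[1] * sd2[2], sd2[2]^2), 2)
    if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      stop("random-effect covariance is not positive semi-definite")
    list(beta = as.numeric(beta), V = V, sigma = sigma)
  }
  structure(list(case = mk(case_ranef_sd, case_ranef_cor, case_resid_sd,
                           case_fixef, 4L),
                 control = mk(control_ranef_sd, control_ranef_cor,
                              control_resid_sd, control_fixef, 2L)),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat("Case/control linear mixed-effects fit\n")
  cat("  case fixed effects:   ", paste(signif(x$case$beta, 4), collapse = ", "),
      " (resid SD ", signif(x$case$sigma, 4), ")\n", sep = "")
  cat("  control fixed effects:", paste(signif(x$control$beta, 4), collapse = ", "),
      " (resid SD ", signif(x$control$sigma, 4), ")\n", sep = "")
  invisible(x)
}

#' Fit the case/control trajectory mixed models
#'
#' Maximum-likelihood fits of the two linear mixed-effects models that
#' induce the binormal ROC for a longitudinal marker: for cases
#' (subjects with an observed event) the marker is regressed on visit
#' time, time before event (`Z - s`) and their interaction; for
#' controls (censored subjects, retained as the event-free group) on
#' visit time only. Both carry a correlated random intercept and
#' visit-time slope per subject. Fitted with [lme4::lmer()]
#' (`REML = FALSE`).
#'
#' @param lc A [longitudinal_cohort()].
#' @return A [mixed_model_fit()] with the underlying `lmerMod` objects
#'   in attribute `"fits"`.
#' @export
ad1_fit <- function(lc) {
  stopifnot(inherits(lc, "longitudinal_cohort"))
  d <- as.data.frame(lc)
  d$tbe <- d$time - d$visit_time
  # fit on a rescaled time axis (days are numerically hostile for the
  # optimizer) and map estimates back to the original unit
  k <- max(d$visit_time, d$tbe, 1)
  d$vs <- d$visit_time / k
  d$ts <- d$tbe / k
  cases <- d[d$event == 1, ]
  ctrls <- d[d$event == 0, ]
  if (length(unique(cases$id)) < 2 || length(unique(ctrls$id)) < 2)
    stop("need at least 2 case and 2 control subjects")
  fit1 <- try(lme4::lmer(
    marker ~ vs * ts + (vs | id), data = cases, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")),
    silent = TRUE)
  fit0 <- try(lme4::lmer(
    marker ~ vs + (vs | id), data = ctrls, REML = FALSE,
    control = lme4::lmerControl(check.conv.singular = "ignore")),
    silent = TRUE)
  for (f in list(fit1, fit0)) if (inherits(f, "try-error"))
    stop("mixed-model fit failed: ", attr(f, "condition")$message,
         " (check variance components / visit counts)")
  vc <- function(f) {
    m <- as.matrix(lme4::VarCorr(f)$id)[1:2, 1:2]
    sds <- sqrt(diag(m)) / c(1, k)
    rho <- if (all(sds > 0)) m[1, 2] / prod(sqrt(diag(m))) else 0
    list(sd = sds, rho = rho)
  }
  v1 <- vc(fit1); v0 <- vc(fit0)
  b1 <- lme4::fixef(fit1)[c("(Intercept)", "vs", "ts", "vs:ts")] /
    c(1, k, k, k^2)
  b0 <- lme4::fixef(fit0)[c("(Intercept)", "vs")] / c(1, k)
  out <- mixed_model_fit(
    case_fixef = unname(b1), control_fixef = unname(b0),
    case_ranef_sd = unname(v1$sd), case_ranef_cor = v1$rho,
    case_resid_sd = stats::sigma(fit1),
    control_ranef_sd = unname(v0$sd), control_ranef_cor = v0$rho,
    control_resid_sd = stats::sigma(fit0))
  attr(out, "fits") <- list(case = fit1, control = fit0, time_scale = k)
  out
}

#' Model-implied marker moments at a visit time
#'
#' Evaluates the case and control marker mean and standard deviation at
#' visit time `s` and time before event `t` implied by a
#' [mixed_model_fit()]: means via the full fixed-effect design rows
#' `[1, s, t, st]` (case) and `[1, s]` (control); standard deviations
#' via the random-effect design `[1, s]` quadratic form plus the
#' residual variance (the random effects carry intercept and visit-time
#' slope only, so `t` does not enter the variance).
#'
#' @param fit A [mixed_model_fit()].
#' @param s Visit time (same unit as fitted, conventionally days).
#' @param t Time before event.
#' @return Named vector `mu_case`, `mu_control`, `sd_case`,
#'   `sd_control`.
#' @export
ad1_moments <- function(fit, s, t) {
  stopifnot(inherits(fit, "mixed_model_fit"))
  if (s < 0 || t < 0) stop("s and t must be non-negative")
  uD <- c(1, s, t, s * t)
  uC <- c(1, s)
  u2 <- c(1, s)
  c(mu_case = sum(uD * fit$case$beta),
    mu_control = sum(uC * fit$control$beta),
    sd_case = sqrt(fit$case$sigma^2 + drop(u2 %*% fit$case$V %*% u2)),
    sd_control = sqrt(fit$control$sigma^2 + drop(u2 %*% fit$control$V %*% u2)))
}

#' Induced binormal ROC from the mixed-model fit
#'
#' Gaussian location-scale induced ROC,
#' `ROC(p) = S_case[a0 + a1 S_control^{-1}(p)]` with
#' `a0 = (mu_control - mu_case)/sd_case` and `a1 = sd_control/sd_case`,
#' i.e. `ROC(p) = pnorm(-a0 + a1 qnorm(p))`, evaluated on a grid of
#' false-positive rates, together with the closed-form AUC
#' `pnorm(-a0 / sqrt(1 + a1^2))`.
#'
#' @param fit A [mixed_model_fit()].
#' @param s Visit time.
#' @param t Time before event.
#' @param p Grid of false-positive rates in (0, 1).
#' @return A `td_roc` object with attributes `a0`, `a1`; its `$auc` is
#'   the closed form.
#' @export
ad1_roc <- function(fit, s, t, p = seq(0.001, 0.999, length.out = 199)) {
  m <- ad1_moments(fit, s, t)
  if (m["sd_case"] <= 0) stop("case SD must be positive")
  a0 <- (m["mu_control"] - m["mu_case"]) / m["sd_case"]
  a1 <- m["sd_control"] / m["sd_case"]
  p <- c(0, sort(p), 1)
  sens <- stats::pnorm(-a0 + a1 * stats::qnorm(p))
  auc <- stats::pnorm(-a0 / sqrt(1 + a1^2))
  out <- new_td_roc(t, stats::qnorm(1 - p), sens, p, "ad1",
                    auc = unname(auc))
  attr(out, "a0") <- unname(a0); attr(out, "a1") <- unname(a1)
  out
}

#' ROC-GLM fit for a longitudinal marker
#'
#' Binormal ROC regression on time before event: every case visit is
#' paired with every control visit, the pair indicator
#' `I(Y_case >= Y_control)` is regressed, with a probit link, on the
#' normal quantile of the control observation's placement value (its
#' false-positive-rate position in the pooled control sample, midrank
#' ties) and on the case visit's time before event. Yields
#' `ROC(t, p) = pnorm(gamma0 + gamma1 qnorm(p) + alpha t)`.
#'
#' @param lc A [longitudinal_cohort()].
#' @param time_effect Include the linear time-before-event term; with
#'   `FALSE` the coefficient `alpha` is fixed at zero.
#' @param max_pairs Upper bound on the number of case-control pairs;
#'   larger pair sets are subsampled reproducibly.
#' @param seed Seed for the pair subsample.
#' @return An object of class `roc_glm_fit` with `gamma0`, `gamma1`,
#'   `alpha`, the `glm` object, and a `separated` flag.
#' @export
ad2_fit <- function(lc, time_effect = TRUE, max_pairs = 2e5, seed = 1L) {
  stopifnot(inherits(lc, "longitudinal_cohort"))
  d <- as.data.frame(lc)
  d$tbe <- d$time - d$visit_time
  yc <- d$marker[d$event == 1]; tc <- d$tbe[d$event == 1]
  yq <- d$marker[d$event == 0]
  if (!length(yc) || !length(yq))
    stop("need at least one case and one control measurement")
  # survival-scale placement: FPR of a threshold at each control value
  pl <- (vapply(yq, function(y) sum(yq > y), 0) + 0.5 *
           vapply(yq, function(y) sum(yq == y), 0)) / length(yq)
  eps <- 1 / (2 * length(yq))
  pl <- pmin(pmax(pl, eps), 1 - eps)
  ii <- rep(seq_along(yc), times = length(yq))
  jj <- rep(seq_along(yq), each = length(yc))
  if (length(ii) > max_pairs) {
    set.seed(seed)
    keep <- sample.int(length(ii), max_pairs)
    ii <- ii[keep]; jj <- jj[keep]
  }
  dat <- data.frame(D = as.numeric(yc[ii] >= yq[jj]),
                    q = stats::qnorm(pl[jj]), tbe = tc[ii])
  fml <- if (time_effect) D ~ q + tbe else D ~ q
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(link = "probit"), data = dat))
  co <- stats::coef(fit)
  # a constant covariate (identical time before event on every pair) is
  # dropped by glm; treat its effect as zero
  co[is.na(co)] <- 0
  separated <- !fit$converged || any(abs(co) > 20)
  if (separated) warning("probable complete separation in the ROC-GLM fit")
  structure(list(gamma0 = unname(co["(Intercept)"]),
                 gamma1 = unname(co["q"]),
                 alpha = if (time_effect) unname(co["tbe"]) else 0,
                 glm = fit, n_pairs = nrow(dat), separated = separated),
            class = "roc_glm_fit")
}

#' @export
print.roc_glm_fit <- function(x, ...) {
  cat(sprintf(
    "ROC-GLM (probit) fit on %d pairs:\n  gamma0 = %.4f, gamma1 = %.4f, alpha (per time unit) = %.3e\n",
    x$n_pairs, x$gamma0, x$gamma1, x$alpha))
  if (x$separated) cat("  flag: possible separation\n")
  invisible(x)
}

#' ROC curve from an ROC-GLM fit
#'
#' @param fit An [ad2_fit()] result.
#' @param t Time before event at which to evaluate the curve.
#' @param p Grid of false-positive rates in (0, 1).
#' @return A `td_roc` object; `$auc` is the closed-form binormal AUC
#'   `pnorm((gamma0 + alpha t) / sqrt(1 + gamma1^2))`.
#' @export
ad2_roc <- function(fit, t, p = seq(0.001, 0.999, length.out = 199)) {
  stopifnot(inherits(fit, "roc_glm_fit"))
  p <- c(0, sort(p), 1)
  sens <- stats::pnorm(fit$gamma0 + fit$gamma1 * stats::qnorm(p) +
                         fit$alpha * t)
  auc <- stats::pnorm((fit$gamma0 + fit$alpha * t) / sqrt(1 + fit$gamma1^2))
  new_td_roc(t, stats::qnorm(1 - p), sens, p, "ad2", auc = auc,
             flags = if (fit$separated) "separation" else character(0))
}
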