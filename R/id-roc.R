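# Incident/dynamic (I/D) estimators: cases have their event exactly at
# t, controls are event-free beyond t; both sides come from the risk set
# R(t) = {i : Z_i >= t}.

# risk set decomposition at an observed event time
.riskset <- function(cohort, t) {
  case <- cohort$time == t & cohort$event == 1
  ctrl <- cohort$time > t
  at_risk <- cohort$time >= t
  list(case = which(case), ctrl = which(ctrl), at_risk = which(at_risk))
}

.require_event_time <- function(cohort, t) {
  tev <- sort(unique(cohort$time[cohort$event == 1]))
  if (!any(tev == t)) {
    near <- tev[order(abs(tev - t))][seq_len(min(3, length(tev)))]
    stop("t = ", t, " is not an observed event time; nearest event times: ",
         paste(signif(near, 6), collapse = ", "))
  }
  tev
}

#' Riskset Cox-regression ROC estimator
#'
#' At an observed event time `t`, incident sensitivity is estimated with
#' exponentially tilted risk-set weights
#' `pi_i = exp(X_i gamma(t)) / sum_{j in R(t)} exp(X_j gamma(t))` under
#' a (possibly time-varying) proportional-hazards coefficient, and
#' dynamic specificity is the empirical distribution of the marker over
#' the controls `Z > t`. `gamma(t)` comes from [smooth_tv_coef()] (local
#' linear smoothing of the scaled Schoenfeld residuals); passing a
#' single number fixes the coefficient, `NULL` fits and smooths
#' internally.
#'
#' @param cohort A [baseline_cohort()].
#' @param t An observed event time.
#' @param tv A [smooth_tv_coef()] result, a fixed number, or `NULL`.
#' @return A `td_roc` object.
#' @export
id1_roc <- function(cohort, t, tv = NULL) {
  cohort <- .as_cohort(cohort)
  .require_event_time(cohort, t)
  if (is.null(tv)) tv <- smooth_tv_coef(ph_fit(cohort))
  rs <- .riskset(cohort, t)
  if (!length(rs$ctrl)) stop("empty control set at t = ", t)
  g <- tv_coef_at(tv, t)
  X <- cohort$marker
  xr <- X[rs$at_risk]
  ew <- exp(g * xr - max(g * xr))   # shifted to guard overflow
  pi_i <- ew / sum(ew)
  grid <- .threshold_grid(X[rs$at_risk])
  sens <- vapply(grid, function(cc) sum(pi_i * (xr > cc)), 0)
  xq <- X[rs$ctrl]
  fpr <- .surv_curve(xq, rep(1, length(xq)), grid)
  auc <- .pairwise_auc(xr, pi_i, xq, rep(1, length(xq)))
  new_td_roc(t, grid, sens, fpr, "id1", auc = auc)
}

#' Concordance summary over (0, tau)
#'
#' Weighted average of the incident/dynamic AUC over the event times in
#' `(0, tau]` with weights proportional to `2 f(t) S(t)`, normalised by
#' `1 - S(tau)^2`; estimated discretely with Kaplan-Meier increments
#' `f_k = S(t_{k-1}) - S(t_k)` and the exact telescoping weights
#' `w_k = f_k (S(t_{k-1}) + S(t_k)) / (1 - S(t_m)^2)`, which sum to one.
#' Interpretable as the probability that a random pair's predictions are
#' concordant given the smaller event time falls in `(0, tau)`.
#'
#' @param cohort A [baseline_cohort()].
#' @param auc_curve Per-event-time incident/dynamic AUC: a function
#'   `f(t)`, a data frame with columns `t` and `auc`, or `NULL` to use
#'   [id1_roc()] at every event time.
#' @param tau Upper limit, at most the largest observed time.
#' @return A `td_auc` object with the weight table in attribute
#'   `"detail"`.
#' @export
concordance_tau <- function(cohort, auc_curve = NULL, tau) {
  cohort <- .as_cohort(cohort)
  if (tau > max(cohort$time)) stop("tau exceeds the largest observed time")
  km <- km_curve(cohort)
  tev <- km$time[km$time <= tau]
  if (!length(tev)) stop("concordance undefined: no events in (0, tau]")
  Sk <- km$surv[km$time <= tau]
  Sprev <- c(1, Sk[-length(Sk)])
  w <- (Sprev - Sk) * (Sprev + Sk) / (1 - Sk[length(Sk)]^2)
  aucs <- if (is.null(auc_curve)) {
    tv <- smooth_tv_coef(ph_fit(cohort))
    a <- vapply(tev, function(tt)
      if (any(cohort$time > tt)) auc_value(id1_roc(cohort, tt, tv))
      else NA_real_, 0)
    # an event time with no remaining controls (at most the last one)
    # has undefined incident AUC; carry the last defined value forward
    if (anyNA(a)) {
      for (k in which(is.na(a))) a[k] <- if (k > 1) a[k - 1] else 0.5
    }
    a
  } else if (is.function(auc_curve)) {
    vapply(tev, function(tt) auc_value(auc_curve(tt)), 0)
  } else {
    stats::approx(auc_curve$t, auc_curve$auc, xout = tev, rule = 2)$y
  }
  out <- new_td_auc(tau, sum(w * aucs), "concordance")
  attr(out, "detail") <- data.frame(t = tev, auc = aucs, weight = w)
  out
}

# riskset U-statistic: P(case marker > control marker) at event time t
.riskset_A <- function(cohort, t) {
  rs <- .riskset(cohort, t)
  if (!length(rs$case) || !length(rs$ctrl)) return(NA_real_)
  Xc <- cohort$marker[rs$case]; Xq <- cohort$marker[rs$ctrl]
  mean(outer(Xc, Xq, ">"))
}

#' Weighted mean rank incident/dynamic AUC
#'
#' Local average of risk-set concordance U-statistics: at each event
#' time `t_j`, `A(t_j)` is the proportion of case-control pairs in the
#' risk set with the case marker larger; the estimate at `t` averages
#' `A(t_j)` over the event times in the window `|t - t_j| < h` with
#' uniform weights (the plain neighbourhood mean) or standardised
#' Gaussian kernel weights summing to one.
#'
#' @param cohort A [baseline_cohort()].
#' @param t Target time.
#' @param bandwidth Window half-width `h`; `NULL` spans the nearest 10%
#'   of event times.
#' @param kernel `"uniform"` or `"gaussian"`.
#' @return A `td_auc` object with the per-event-time table in attribute
#'   `"detail"`.
#' @export
id2_wmr <- function(cohort, t, bandwidth = NULL,
                    kernel = c("uniform", "gaussian")) {
  cohort <- .as_cohort(cohort)
  kernel <- match.arg(kernel)
  tev <- sort(unique(cohort$time[cohort$event == 1]))
  if (is.null(bandwidth)) {
    k <- max(1L, ceiling(0.1 * length(tev)))
    bandwidth <- sort(abs(tev - t))[k] * (1 + 1e-8)
  }
  nb <- tev[abs(tev - t) < bandwidth]
  nb <- nb[vapply(nb, function(tt) length(.riskset(cohort, tt)$ctrl) > 0, TRUE)]
  if (!length(nb))
    stop("no event time inside the bandwidth window; increase bandwidth")
  A <- vapply(nb, function(tt) .riskset_A(cohort, tt), 0)
  w <- if (kernel == "uniform") rep(1 / length(nb), length(nb)) else {
    k <- stats::dnorm((t - nb) / bandwidth)
    k / sum(k)
  }
  out <- new_td_auc(t, sum(w * A), "id2")
  attr(out, "detail") <- data.frame(t = nb, A = A, weight = w)
  out
}

# fractional polynomial basis; power 0 means log(t)
.fp_basis <- function(t, powers) {
  if (!length(powers)) return(matrix(nrow = length(t), ncol = 0))
  vapply(powers, function(p) if (p == 0) log(t) else t^p, numeric(length(t)))
}

#' Fractional-polynomial incident/dynamic AUC model
#'
#' Models the incident/dynamic AUC directly as a smooth parametric
#' function of time, `link(AUC(t)) = beta_0 + sum_g beta_g t^(p_g)`
#' (power 0 meaning `log t`), with powers searched exhaustively over
#' the candidate set \{-2, -1, -1/2, 0, 1/2, 1, 2\} (distinct powers,
#' degree `G`). Parameters maximise the pseudo partial-likelihood
#' `prod_k AUC(t_k)^{n1_k} (1 - AUC(t_k))^{n2_k}` where `n1_k`/`n2_k`
#' count concordant/discordant case-control pairs in the risk set at
#' each event time — a binomial likelihood, maximised with
#' [stats::glm()].
#'
#' @param cohort A [baseline_cohort()].
#' @param G Degree (0, 1 or 2).
#' @param link `"logit"` (default) or `"probit"`.
#' @return An object of class `fracpoly_auc` with `powers`, `coef`,
#'   `logLik`, `link` and the risk-set count table `counts`.
#' @export
id3_fit <- function(cohort, G = 1, link = c("logit", "probit")) {
  cohort <- .as_cohort(cohort)
  link <- match.arg(link)
  if (!G %in% 0:2) stop("G must be 0, 1 or 2")
  tev <- sort(unique(cohort$time[cohort$event == 1]))
  cnt <- do.call(rbind, lapply(tev, function(tt) {
    rs <- .riskset(cohort, tt)
    if (!length(rs$ctrl)) return(NULL)
    Xc <- cohort$marker[rs$case]; Xq <- cohort$marker[rs$ctrl]
    n1 <- sum(outer(Xc, Xq, ">"))
    data.frame(t = tt, n1 = n1, n2 = length(Xc) * length(Xq) - n1)
  }))
  if (is.null(cnt) || nrow(cnt) < G + 2)
    stop("need at least G + 2 distinct event times with controls")
  cand <- c(-2, -1, -0.5, 0, 0.5, 1, 2)
  pw_sets <- if (G == 0) list(numeric(0)) else
    utils::combn(cand, G, simplify = FALSE)
  fam <- stats::binomial(link = link)
  best <- NULL
  for (pw in pw_sets) {
    B <- .fp_basis(cnt$t, pw)
    dat <- data.frame(n1 = cnt$n1, n2 = cnt$n2)
    fit <- try(suppressWarnings(
      if (ncol(B)) stats::glm(cbind(n1, n2) ~ B, family = fam, data = dat)
      else stats::glm(cbind(n1, n2) ~ 1, family = fam, data = dat)),
      silent = TRUE)
    if (inherits(fit, "try-error") || any(!is.finite(stats::coef(fit)))) next
    ll <- as.numeric(stats::logLik(fit))
    if (is.null(best) || ll > best$logLik)
      best <- list(powers = sort(pw), coef = unname(stats::coef(fit)),
                   logLik = ll, link = link)
  }
  if (is.null(best)) stop("no fractional-polynomial fit converged")
  best$counts <- cnt
  best$separated <- all(cnt$n2 == 0) || all(cnt$n1 == 0)
  if (best$separated)
    warning("all risk sets fully concordant or discordant; ",
            "AUC pinned to the boundary")
  class(best) <- "fracpoly_auc"
  best
}

#' @export
print.fracpoly_auc <- function(x, ...) {
  cat(sprintf(
    "Fractional-polynomial AUC model (G = %d, %s link)\n  powers: %s\n  coef: %s\n  logLik: %.3f\n",
    length(x$powers), x$link,
    if (length(x$powers)) paste(x$powers, collapse = ", ") else "(intercept only)",
    paste(signif(x$coef, 5), collapse = ", "), x$logLik))
  invisible(x)
}

#' Evaluate a fractional-polynomial AUC curve
#'
#' @param model An [id3_fit()] result.
#' @param t Evaluation times (> 0).
#' @return A `td_auc` object when `t` is scalar, otherwise a numeric
#'   vector of AUC values.
#' @export
id3_auc <- function(model, t) {
  stopifnot(inherits(model, "fracpoly_auc"))
  if (any(t <= 0)) stop("t must be positive")
  eta <- model$coef[1] +
    as.numeric(.fp_basis(t, model$powers) %*% model$coef[-1])
  val <- stats::binomial(link = model$link)$linkinv(eta)
  if (length(t) == 1L)
    return(new_td_auc(t, val, "id3",
                      flags = if (model$separated) "boundary" else character(0)))
  val
}

#' Integrated AUC of a fractional-polynomial model
#'
#' Uniform-weight time average of the fitted analytic AUC curve over
#' `(0, tau]`, by numerical integration.
#'
#' @param model An [id3_fit()] result.
#' @param tau Upper limit.
#' @return Scalar integrated AUC.
#' @export
id3_integrated_auc <- function(model, tau) {
  lo <- min(model$counts$t) * 1e-3
  stats::integrate(function(u) id3_auc(model, u), lo, tau,
                   rel.tol = 1e-8)$value / (tau - lo)
}
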