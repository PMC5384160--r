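#' Right-continuous step survival function
#'
#' Minimal container for product-limit style survival curves: ascending
#' jump times and the survival value attained at each jump. `S(0) = 1`
#' and the curve is right-continuous and non-increasing.
#'
#' @param time Ascending jump times.
#' @param surv Survival values at the jumps (right-continuous).
#' @return An object of class `step_surv`.
#' @export
step_surv <- function(time, surv) {
  stopifnot(length(time) == length(surv))
  if (is.unsorted(time)) {
    o <- order(time)
    time <- time[o]; surv <- surv[o]
  }
  if (any(diff(c(1, surv)) > 1e-12)) stop("survival values must be non-increasing")
  if (any(surv < -1e-12 | surv > 1 + 1e-12)) stop("survival values must lie in [0,1]")
  structure(list(time = unname(time), surv = unname(pmin(pmax(surv, 0), 1))),
            class = "step_surv")
}

#' Evaluate a step survival function
#'
#' @param s A [step_surv()].
#' @param t Evaluation times.
#' @param left If `TRUE`, return the left limit `S(t-)` instead of the
#'   right-continuous value `S(t)`.
#' @return Numeric vector of survival probabilities.
#' @export
surv_at <- function(s, t, left = FALSE) {
  if (!length(s$time)) return(rep(1, length(t)))
  idx <- findInterval(t, s$time, left.open = left)
  c(1, s$surv)[idx + 1L]
}

#' @export
print.step_surv <- function(x, ...) {
  cat(sprintf("Step survival function: %d jumps, final S = %.4f\n",
              length(x$time), if (length(x$surv)) min(x$surv) else 1))
  invisible(x)
}

# Weighted product-limit estimator. Ties follow the standard convention:
# subjects censored at an event time stay in that risk set. Weights may
# be any non-negative reals (0/1 weights give a subset Kaplan-Meier).
.wkm <- function(Z, delta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(Z))
  keep <- w > 0
  Z <- Z[keep]; delta <- delta[keep]; w <- w[keep]
  o <- order(Z)
  Z <- Z[o]; delta <- delta[o]; w <- w[o]
  ev <- delta == 1
  if (!any(ev)) return(step_surv(numeric(0), numeric(0)))
  # risk mass just before each position, scanning from the right
  atrisk <- rev(cumsum(rev(w)))
  tev <- unique(Z[ev])
  d <- vapply(split(w[ev], Z[ev]), sum, 0)          # event mass per time
  r <- atrisk[match(tev, Z)]                        # at-risk mass at each event time
  s <- cumprod(1 - d / r)
  step_surv(tev, pmax(s, 0))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the marginal survival function of the event
#' time, with jumps at observed event times. Censored-only data return
#' the constant curve S = 1.
#'
#' @param cohort A [baseline_cohort()].
#' @return A [step_surv()].
#' @export
km_curve <- function(cohort) {
  cohort <- .as_cohort(cohort)
  .wkm(cohort$time, cohort$event)
}

# Product-limit estimator of the censoring survival P(C > t) under the
# events-before-censorings tie convention: subjects with an event at a
# time leave the risk set before the censoring jump at that same time.
# On tie-free data this coincides with the reverse Kaplan-Meier.
.wkm_censor <- function(Z, delta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(Z))
  keep <- w > 0
  Z <- Z[keep]; delta <- delta[keep]; w <- w[keep]
  o <- order(Z)
  Z <- Z[o]; delta <- delta[o]; w <- w[o]
  cen <- delta == 0
  if (!any(cen)) return(step_surv(numeric(0), numeric(0)))
  atrisk <- rev(cumsum(rev(w)))
  tc <- unique(Z[cen])
  cmass <- vapply(split(w[cen], Z[cen]), sum, 0)
  dmass <- vapply(tc, function(a) sum(w[Z == a & delta == 1]), 0)
  r <- atrisk[match(tc, Z)] - dmass
  s <- cumprod(1 - cmass / pmax(r, .Machine$double.xmin))
  step_surv(tc, pmin(pmax(s, 0), 1))
}

#' Kaplan-Meier curve of the censoring distribution
#'
#' Product-limit estimate of `P(C > t)`, treating censorings as the
#' events of interest. Tied event/censoring times follow the
#' events-before-censorings convention: a subject observed to fail at
#' `t` is no longer at risk for the censoring jump at `t` (on tie-free
#' data this is exactly the reverse Kaplan-Meier with the indicator
#' flipped). Left limits `S_c(t-)` needed by
#' inverse-probability-of-censoring weights are available through
#' [surv_at()] with `left = TRUE`.
#'
#' @param cohort A [baseline_cohort()].
#' @return A [step_surv()].
#' @export
censoring_km <- function(cohort) {
  cohort <- .as_cohort(cohort)
  .wkm_censor(cohort$time, cohort$event)
}

#' Nearest-neighbour smoothing window
#'
#' Configuration of the 0/1 nearest-neighbour kernel acting on the
#' marker's empirical-CDF scale: subject j is a neighbour of anchor x0
#' when `|F_X(X_j) - F_X(x0)| < lambda`. `2 * lambda` is the fraction of
#' the sample inside each window, so `lambda` must lie in (0, 0.5). The
#' default, used when `lambda = NULL` in consuming functions, is
#' `0.25 * n^(-1/3)`.
#'
#' @param lambda Half-width on the CDF scale, in (0, 0.5).
#' @return An object of class `nne_config`.
#' @export
nne_config <- function(lambda) {
  if (!is.numeric(lambda) || lambda <= 0 || lambda >= 0.5)
    stop("lambda must lie strictly between 0 and 0.5")
  structure(list(lambda = lambda), class = "nne_config")
}

.nne_lambda <- function(cfg, n, default = 0.25 * n^(-1/3)) {
  if (is.null(cfg)) return(min(default, 0.499))
  if (inherits(cfg, "nne_config")) return(cfg$lambda)
  lam <- as.numeric(cfg)
  if (!is.finite(lam) || lam <= 0 || lam >= 1)
    stop("lambda must lie in (0, 1)")
  # plain-numeric lambda >= 0.5 saturates the kernel (window covers the
  # whole sample); useful for degenerate-limit checks
  lam
}

# neighbour indicator matrix row i = kernel window of subject/anchor i
.nne_neighbours <- function(Fx, f0, lambda) {
  abs(outer(f0, Fx, "-")) < lambda
}

#' Nearest-neighbour weighted Kaplan-Meier (conditional survival)
#'
#' Akritas's weighted product-limit estimator of `S(t | X = x0)`: a
#' Kaplan-Meier computation restricted to the subjects whose marker
#' empirical-CDF value lies within `lambda` of the anchor's. The window
#' acts on the CDF scale, so the estimator is invariant to strictly
#' increasing transformations of the marker. The anchor's own record is
#' always inside its window.
#'
#' @param cohort A [baseline_cohort()].
#' @param x0 Marker anchor value.
#' @param lambda Window half-width, a number or [nne_config()];
#'   `NULL` uses the default `0.25 n^(-1/3)`.
#' @return A [step_surv()].
#' @export
nne_km <- function(cohort, x0, lambda = NULL) {
  cohort <- .as_cohort(cohort)
  n <- nrow(cohort)
  lam <- .nne_lambda(lambda, n)
  Fx <- stats::ecdf(cohort$marker)(cohort$marker)
  f0 <- stats::ecdf(cohort$marker)(x0)
  w <- as.numeric(abs(Fx - f0) < lam)
  i0 <- which(cohort$marker == x0)
  if (length(i0)) w[i0] <- 1
  .wkm(cohort$time, cohort$event, w)
}

#' Nearest-neighbour bivariate survival surface
#'
#' Estimates the bivariate survival function of (marker, event time),
#' `S(c, t) = P(X > c, T > t)`, by averaging conditional weighted
#' Kaplan-Meier curves over subjects with marker above the threshold:
#' `S_lambda(c, t) = n^-1 sum_i I(X_i > c) S_lambda(t | X_i)`. The
#' marginal is `S_lambda(-Inf, t)`.
#'
#' @inheritParams nne_km
#' @return A function `f(c, t)` evaluating the surface, with attribute
#'   `cond_surv(t)` returning the vector of per-subject conditional
#'   survival probabilities at `t` (in cohort row order).
#' @export
nne_bivariate <- function(cohort, lambda = NULL) {
  cohort <- .as_cohort(cohort)
  n <- nrow(cohort)
  lam <- .nne_lambda(lambda, n)
  X <- cohort$marker
  Fx <- stats::ecdf(X)(X)
  curves <- lapply(seq_len(n), function(i)
    .wkm(cohort$time, cohort$event, as.numeric(abs(Fx - Fx[i]) < lam)))
  cond_surv <- function(t) vapply(curves, surv_at, 0, t = t)
  f <- function(c, t) {
    s <- cond_surv(t)
    vapply(c, function(cc) mean((X > cc) * s), 0)
  }
  attr(f, "cond_surv") <- cond_surv
  attr(f, "marker") <- X
  f
}

#' Proportional-hazards marker fit
#'
#' Cox partial-likelihood fit of the event time on the scalar marker
#' (Breslow tie handling), exposing the log-hazard coefficient, the
#' Breslow baseline cumulative hazard and the per-event scaled
#' Schoenfeld residuals (per-event estimates of the time-varying
#' coefficient) used for [smooth_tv_coef()].
#'
#' @param cohort A [baseline_cohort()].
#' @return An object of class `ph_fit` with elements `gamma`,
#'   `baseline_cumhaz` (data frame `time`, `hazard`), `schoenfeld`
#'   (data frame `time`, `resid` of scaled residuals), and the
#'   underlying `survival::coxph` fit in `$coxph`.
#' @export
ph_fit <- function(cohort) {
  cohort <- .as_cohort(cohort)
  if (sum(cohort$event) < 1) stop("at least one event is required")
  if (stats::var(cohort$marker) == 0) stop("marker is constant")
  d <- as.data.frame(cohort)
  fit <- survival::coxph(survival::Surv(time, event) ~ marker, data = d,
                         ties = "breslow")
  if (!is.finite(stats::coef(fit)))
    stop("Cox fit failed to converge; coefficient is not finite")
  bh <- survival::basehaz(fit, centered = FALSE)
  sch <- residuals(fit, type = "scaledsch")
  stime <- as.numeric(names(sch) %||% rownames(as.matrix(sch)))
  if (all(is.na(stime))) stime <- sort(d$time[d$event == 1])
  structure(list(gamma = unname(stats::coef(fit)),
                 baseline_cumhaz = data.frame(time = bh$time, hazard = bh$hazard),
                 schoenfeld = data.frame(time = stime, resid = as.numeric(sch)),
                 coxph = fit),
            class = "ph_fit")
}

#' @export
print.ph_fit <- function(x, ...) {
  cat(sprintf("Proportional-hazards marker fit: gamma = %.4f (se %.4f)\n",
              x$gamma, sqrt(x$coxph$var[1, 1])))
  invisible(x)
}

# baseline cumulative hazard at t (right-continuous step)
.cumhaz_at <- function(fit, t) {
  bh <- fit$baseline_cumhaz
  idx <- findInterval(t, bh$time)
  c(0, bh$hazard)[idx + 1L]
}

#' Conditional absolute risk under the Cox model
#'
#' `F(t; x) = 1 - exp(-Lambda_0(t) exp(gamma x))` with the Breslow
#' baseline cumulative hazard.
#'
#' @param fit A [ph_fit()].
#' @param t Horizon.
#' @param x Marker values.
#' @return Vector of conditional risks.
#' @export
cox_risk <- function(fit, t, x) {
  1 - exp(-.cumhaz_at(fit, t) * exp(fit$gamma * x))
}

#' Aalen additive hazards fit
#'
#' Least-squares estimation of the cumulative regression functions of
#' the additive hazards model `lambda(t | x) = beta_0(t) + beta_1(t) x`:
#' at each event time the hazard increments are regressed on (1, marker)
#' over the risk set, and increments are accumulated into `B_0(t)` and
#' `B_1(t)` (both 0 at time 0). Rank-deficient risk-set designs (for
#' example a constant marker) are resolved by the minimum-norm
#' least-squares solution, so a constant-zero marker yields `B_1 == 0`.
#'
#' @param cohort A [baseline_cohort()].
#' @return An object of class `additive_fit` with data frame `cumcoef`
#'   (`time`, `b0`, `b1`).
#' @export
additive_fit <- function(cohort) {
  cohort <- .as_cohort(cohort)
  if (sum(cohort$event) < 2) stop("at least two events are required")
  Z <- cohort$time; delta <- cohort$event; X <- cohort$marker
  tev <- sort(unique(Z[delta == 1]))
  b0 <- b1 <- numeric(length(tev))
  dropped <- 0L
  for (k in seq_along(tev)) {
    at <- Z >= tev[k]
    Xr <- cbind(1, X[at])
    dN <- as.numeric(Z[at] == tev[k] & delta[at] == 1)
    XtX <- crossprod(Xr)
    inc <- if (abs(det(XtX)) > 1e-10 * nrow(Xr)^2) {
      solve(XtX, crossprod(Xr, dN))
    } else {
      dropped <- dropped + 1L
      MASS::ginv(Xr) %*% dN
    }
    b0[k] <- inc[1]; b1[k] <- inc[2]
  }
  if (dropped)
    warning(dropped, " risk-set design(s) were rank deficient; ",
            "minimum-norm increments used")
  structure(list(cumcoef = data.frame(time = tev,
                                      b0 = cumsum(b0), b1 = cumsum(b1))),
            class = "additive_fit")
}

#' Cumulative additive-hazards coefficients at a time point
#'
#' @param fit An [additive_fit()].
#' @param t Horizon.
#' @return Named vector `c(b0, b1)` of `B_0(t)`, `B_1(t)`.
#' @export
additive_coef_at <- function(fit, t) {
  cc <- fit$cumcoef
  idx <- findInterval(t, cc$time)
  c(b0 = c(0, cc$b0)[idx + 1L], b1 = c(0, cc$b1)[idx + 1L])
}

#' Smoothed time-varying Cox coefficient
#'
#' Estimates `gamma(t)` by local-linear smoothing of the scaled
#' Schoenfeld residuals on the event-time grid. The scaled residuals
#' (as returned by `survival`) are per-event estimates of the
#' time-varying coefficient, so their smooth is the `gamma(t)` curve;
#' under proportional hazards it is flat at the partial-likelihood
#' estimate. Smoothing is done on the event-rank scale (as in
#' `survival::cox.zph`) to avoid instability where event times are
#' sparse; the smoother is `stats::loess` with `degree = 1` and `span`
#' the fraction of events in each local window.
#'
#' @param fit A [ph_fit()].
#' @param span Local window fraction in (0, 1].
#' @return An object of class `tv_coef` with `grid`, `gamma_t` and an
#'   evaluator usable through [tv_coef_at()].
#' @export
smooth_tv_coef <- function(fit, span = 0.75) {
  stopifnot(inherits(fit, "ph_fit"))
  sch <- fit$schoenfeld
  if (nrow(sch) < 5) stop("at least 5 events are required for smoothing")
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  minspan <- 4 / nrow(sch)
  if (span < minspan) {
    warning("span below the resolvable minimum; widened to ", signif(minspan, 3))
    span <- minspan
  }
  xs <- rank(sch$time, ties.method = "first") / nrow(sch)
  sm <- suppressWarnings(
    stats::loess(sch$resid ~ xs, span = span, degree = 1,
                 family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  gamma_t <- as.numeric(stats::predict(sm))
  if (any(!is.finite(gamma_t))) stop("smoothing produced non-finite values")
  structure(list(grid = sch$time, gamma_t = gamma_t, span = span,
                 gamma = fit$gamma),
            class = "tv_coef")
}

#' Evaluate a smoothed time-varying coefficient
#'
#' Linear interpolation on the event-time grid, constant beyond it.
#'
#' @param tv A [smooth_tv_coef()] result, or `NULL` / a single number
#'   for a constant coefficient.
#' @param t Evaluation times.
#' @return Numeric vector `gamma(t)`.
#' @export
tv_coef_at <- function(tv, t) {
  if (is.null(tv)) return(rep(0, length(t)))
  if (is.numeric(tv)) return(rep(tv[1], length(t)))
  stats::approx(tv$grid, tv$gamma_t, xout = t, rule = 2)$y
}
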