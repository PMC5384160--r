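# Synthetic-cohort generators. The generators carry closed-form
# conditional risk functions, so the true cumulative/dynamic and
# incident/dynamic AUC are available by quadrature for any scenario.

#' Baseline simulation scenario
#'
#' Describes a synthetic baseline cohort: marker law, event-time model
#' and censoring mechanism. Defaults are the package's reference study
#' conditions (times in days): a standard-normal marker with a
#' log-linear proportional-hazards effect (baseline hazard 2e-4 per
#' day, log hazard ratio 1) and independent exponential censoring at
#' rate 1e-4 per day. Marker-dependent censoring uses the hazard
#' `rate * exp(eta * X)`, the mechanism that breaks estimators relying
#' on marker-independent censoring.
#'
#' @param n Cohort size (>= 2).
#' @param marker `"gaussian"` (standard normal) or `"uniform"` (0, 1).
#' @param event_model List: `type` in `"exp_ph"`, `"weibull_ph"`,
#'   `"additive"`; `lambda0` baseline rate; `gamma` log hazard ratio
#'   (PH models); `shape` Weibull shape; `b0`, `b1` additive intercept/
#'   slope hazards.
#' @param censor_model List: `type` in `"none"`, `"exp"`, `"marker"`;
#'   `rate`; `eta` (marker dependence, `"marker"` only).
#' @return An object of class `baseline_scenario`.
#' @export
baseline_scenario <- function(n = 200,
                              marker = c("gaussian", "uniform"),
                              event_model = list(type = "exp_ph",
                                                 lambda0 = 2e-4, gamma = 1),
                              censor_model = list(type = "exp", rate = 1e-4)) {
  marker <- match.arg(marker)
  if (n < 2) stop("n must be at least 2")
  em <- utils::modifyList(list(type = "exp_ph", lambda0 = 2e-4, gamma = 1,
                               shape = 1.5, b0 = 2e-4, b1 = 2e-4),
                          event_model)
  cm <- utils::modifyList(list(type = "exp", rate = 1e-4, eta = 0.8),
                          censor_model)
  if (!em$type %in% c("exp_ph", "weibull_ph", "additive"))
    stop("unknown event model type")
  if (!cm$type %in% c("none", "exp", "marker"))
    stop("unknown censoring model type")
  if (em$type == "additive" && marker == "gaussian")
    marker <- "uniform"   # keeps the additive hazard non-negative
  structure(list(n = n, marker = marker, event_model = em,
                 censor_model = cm),
            class = "baseline_scenario")
}

# conditional risk F(t | x) and hazard of a scenario, vectorised in x
.scn_risk <- function(sc, t, x) {
  em <- sc$event_model
  switch(em$type,
         exp_ph = 1 - exp(-em$lambda0 * exp(em$gamma * x) * t),
         weibull_ph = 1 - exp(-em$lambda0 * exp(em$gamma * x) * t^em$shape),
         additive = 1 - exp(-pmax(em$b0 + em$b1 * x, 0) * t))
}

.scn_hazard <- function(sc, t, x) {
  em <- sc$event_model
  switch(em$type,
         exp_ph = em$lambda0 * exp(em$gamma * x) + 0 * t,
         weibull_ph = em$lambda0 * em$shape * t^(em$shape - 1) *
           exp(em$gamma * x),
         additive = pmax(em$b0 + em$b1 * x, 0) + 0 * t)
}

.scn_marker_grid <- function(sc, m = 4001) {
  if (sc$marker == "gaussian") {
    x <- seq(-8, 8, length.out = m)
    list(x = x, f = stats::dnorm(x))
  } else {
    x <- seq(0, 1, length.out = m)
    list(x = x, f = rep(1, m))
  }
}

#' Simulate a baseline cohort
#'
#' Draws markers, event times and censoring times from a
#' [baseline_scenario()]. The returned object carries the scenario as
#' an oracle handle: [true_cd_auc()] and [true_id_auc()] evaluate the
#' true AUC of the scenario by quadrature, and
#' `oracle$risk(t, x)` exposes the true conditional risk.
#'
#' @param sc A [baseline_scenario()].
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return A list of class `baseline_sim` with elements `cohort` (a
#'   [baseline_cohort()]) and `oracle`.
#' @export
simulate_baseline <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "baseline_scenario"))
  rng <- .local_rng(seed)
  x <- if (sc$marker == "gaussian") rng$norm(sc$n) else rng$unif(sc$n)
  u <- rng$unif(sc$n)
  em <- sc$event_model
  T <- switch(em$type,
    exp_ph = -log(u) / (em$lambda0 * exp(em$gamma * x)),
    weibull_ph = (-log(u) / (em$lambda0 * exp(em$gamma * x)))^(1 / em$shape),
    additive = -log(u) / pmax(em$b0 + em$b1 * x, 1e-12))
  cm <- sc$censor_model
  C <- switch(cm$type,
              none = rep(Inf, sc$n),
              exp = -log(rng$unif(sc$n)) / cm$rate,
              marker = -log(rng$unif(sc$n)) / (cm$rate * exp(cm$eta * x)))
  Z <- pmin(T, C)
  delta <- as.numeric(T <= C)
  oracle <- list(scenario = sc,
                 risk = function(t, xx) .scn_risk(sc, t, xx),
                 hazard = function(t, xx) .scn_hazard(sc, t, xx))
  class(oracle) <- "td_oracle"
  structure(list(cohort = baseline_cohort(seq_len(sc$n), Z, delta, x),
                 oracle = oracle, seed = seed),
            class = "baseline_sim")
}

# seed-scoped RNG that does not disturb the global stream
.local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    s
  })
  draw <- function(f) function(n, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- f(n, ...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
  list(norm = draw(stats::rnorm), unif = draw(stats::runif),
       sample = draw(function(n, ...) sample.int(n, ...)))
}

#' True cumulative/dynamic AUC of a scenario
#'
#' `P(X_i > X_j | T_i <= t, T_j > t)` for independent subjects of the
#' scenario, by double quadrature over the marker law (the inner
#' integral is a cumulative trapezoid, giving quadrature error well
#' below 1e-6 on the default grid).
#'
#' @param oracle The `oracle` element of a [simulate_baseline()] result.
#' @param t Horizon.
#' @return Scalar true AUC.
#' @export
true_cd_auc <- function(oracle, t) {
  sc <- oracle$scenario
  g <- .scn_marker_grid(sc, 8001)
  F <- .scn_risk(sc, t, g$x)
  .auc_quad(g, wc = F, wq = 1 - F)
}

#' True incident/dynamic AUC of a scenario
#'
#' `P(X_i > X_j | T_i = t, T_j > t)`: the case marker is weighted by
#' the event-time density `f(t | x) = lambda(t | x) S(t | x)` and the
#' control marker by `S(t | x)`.
#'
#' @inheritParams true_cd_auc
#' @return Scalar true AUC.
#' @export
true_id_auc <- function(oracle, t) {
  sc <- oracle$scenario
  g <- .scn_marker_grid(sc, 8001)
  S <- 1 - .scn_risk(sc, t, g$x)
  .auc_quad(g, wc = .scn_hazard(sc, t, g$x) * S, wq = S)
}

# P(Xc > Xq) where Xc ~ f*wc and Xq ~ f*wq (independently), by
# trapezoid quadrature with a cumulative inner integral
.auc_quad <- function(g, wc, wq) {
  fc <- g$f * wc; fq <- g$f * wq
  h <- diff(g$x)
  cumq <- c(0, cumsum(h * (fq[-1] + fq[-length(fq)]) / 2))  # int_{-inf}^x fq
  num <- sum(h * ((fc * cumq)[-1] + (fc * cumq)[-length(fc)]) / 2)
  mc <- sum(h * (fc[-1] + fc[-length(fc)]) / 2)
  mq <- cumq[length(cumq)]
  num / (mc * mq)
}

#' Longitudinal simulation scenario
#'
#' Case/control trajectory generator matching the paired linear
#' mixed-effects models of the induced-binormal method: case marker
#' values depend on visit time, time before event and their
#' interaction; control values on visit time only; both with correlated
#' random intercept and visit-time slope and Gaussian residuals.
#' Defaults are the published PBC-scale estimates with annual visits
#' (times in days).
#'
#' @param n_case,n_control Numbers of case and control subjects.
#' @param n_visits Visits per subject.
#' @param visit_spacing Days between scheduled visits.
#' @param visit_jitter SD of the visit-time jitter in days.
#' @param case_fixef,control_fixef Fixed effects (see
#'   [mixed_model_fit()]).
#' @param case_ranef_sd,case_ranef_cor,case_resid_sd Case random-effect
#'   SDs, correlation and residual SD.
#' @param control_ranef_sd,control_ranef_cor,control_resid_sd Control
#'   counterparts.
#' @param event_gap_mean Mean of the exponential gap between a case's
#'   last visit and its event, so the time before event is defined at
#'   every visit.
#' @param control_followup Extra event-free follow-up of controls after
#'   their last visit.
#' @return An object of class `longitudinal_scenario`.
#' @export
longitudinal_scenario <- function(n_case = 200, n_control = 200,
                                  n_visits = 5, visit_spacing = 365,
                                  visit_jitter = 30,
                                  case_fixef = c(1.139, -4.813e-4,
                                                 2.283e-4, -1.083e-7),
                                  case_ranef_sd = c(0.593, 3.448e-4),
                                  case_ranef_cor = -0.378,
                                  case_resid_sd = 0.293,
                                  control_fixef = c(-0.569, 2.906e-4),
                                  control_ranef_sd = c(0.550, 2.615e-4),
                                  control_ranef_cor = 0.209,
                                  control_resid_sd = 0.220,
                                  event_gap_mean = 730,
                                  control_followup = 1825) {
  if (n_visits < 1) stop("at least one visit per subject")
  structure(as.list(environment()), class = "longitudinal_scenario")
}

#' Simulate a longitudinal cohort
#'
#' @param sc A [longitudinal_scenario()].
#' @param seed Integer seed.
#' @return A [longitudinal_cohort()]; cases have `event = 1` with the
#'   event strictly after their last visit, controls `event = 0`.
#' @export
simulate_longitudinal <- function(sc, seed = 1L) {
  stopifnot(inherits(sc, "longitudinal_scenario"))
  rng <- .local_rng(seed)
  draw_group <- function(nsub, prefix, case) {
    sd2 <- if (case) sc$case_ranef_sd else sc$control_ranef_sd
    rho <- if (case) sc$case_ranef_cor else sc$control_ranef_cor
    sres <- if (case) sc$case_resid_sd else sc$control_resid_sd
    beta <- if (case) sc$case_fixef else sc$control_fixef
    z <- matrix(rng$norm(2 * nsub), ncol = 2)
    # exact 2x2 factor of the random-effect covariance
    b <- cbind(sd2[1] * z[, 1],
               sd2[2] * (rho * z[, 1] + sqrt(max(1 - rho^2, 0)) * z[, 2]))
    rows <- vector("list", nsub)
    for (i in seq_len(nsub)) {
      s <- (seq_len(sc$n_visits) - 1) * sc$visit_spacing +
        c(0, rng$norm(sc$n_visits - 1)) * sc$visit_jitter
      s <- sort(pmax(s, 0))
      s <- s + seq(0, 1e-6, length.out = sc$n_visits)  # break exact ties
      if (case) {
        Z <- max(s) + (-log(rng$unif(1))) * sc$event_gap_mean
        tbe <- Z - s
        mu <- beta[1] + beta[2] * s + beta[3] * tbe + beta[4] * s * tbe
      } else {
        Z <- max(s) + sc$control_followup
        mu <- beta[1] + beta[2] * s
      }
      y <- b[i, 1] + b[i, 2] * s + mu + rng$norm(sc$n_visits) * sres
      rows[[i]] <- data.frame(id = paste0(prefix, i), visit_time = s,
                              marker = y, time = Z,
                              event = as.numeric(case))
    }
    do.call(rbind, rows)
  }
  d <- rbind(draw_group(sc$n_case, "case", TRUE),
             draw_group(sc$n_control, "ctrl", FALSE))
  longitudinal_cohort(d$id, d$visit_time, d$marker, d$time, d$event)
}

#' Constant-discrimination cohort
#'
#' Builds an uncensored cohort whose incident/dynamic AUC equals `auc`
#' at every event time exactly: markers are drawn i.i.d. uniform, and
#' the event order is constructed sequentially so that at each event
#' time the case's marker exceeds a randomly chosen control's with
#' probability `auc` (exponentially tilted selection over the current
#' risk-set ranks, tilt solved per risk set). Intended for calibrating
#' incident/dynamic estimators against a known flat AUC profile.
#'
#' @param n Cohort size (>= 3).
#' @param auc Target incident AUC in (0, 1).
#' @param seed Integer seed.
#' @return A [baseline_cohort()] with `event = 1` throughout and event
#'   times `1, 2, ..., n`.
#' @export
simulate_constant_id_auc <- function(n, auc, seed = 1L) {
  if (auc <= 0 || auc >= 1) stop("auc must lie in (0, 1)")
  .sim_tilted_id(n, rep(auc, n - 1L), seed)
}

#' Cohort with a prescribed incident-AUC profile
#'
#' Generalises [simulate_constant_id_auc()]: the target incident AUC is
#' a function of the event time (event times are `1, ..., n`), so
#' decaying or otherwise structured discrimination profiles can be
#' generated exactly at the risk-set level.
#'
#' @param n Cohort size (>= 3).
#' @param auc_fun Function mapping an event time in `1:(n-1)` to a
#'   target AUC in (0, 1).
#' @param seed Integer seed.
#' @return A [baseline_cohort()] with `event = 1` throughout.
#' @export
simulate_profile_id_auc <- function(n, auc_fun, seed = 1L) {
  targets <- vapply(seq_len(n - 1L), auc_fun, 0)
  if (any(targets <= 0 | targets >= 1)) stop("targets must lie in (0, 1)")
  .sim_tilted_id(n, targets, seed)
}

.sim_tilted_id <- function(n, targets, seed) {
  if (n < 3) stop("n must be at least 3")
  rng <- .local_rng(seed)
  X <- rng$unif(n)
  remaining <- order(X)          # ids ordered by marker rank
  order_out <- integer(n)
  for (k in seq_len(n - 1L)) {
    m <- length(remaining)
    u <- (seq_len(m) - 1) / (m - 1)
    target <- targets[k]
    # tilt theta with sum p(u) u = target, p(u) propto exp(theta u)
    f <- function(th) {
      w <- exp(th * u); sum(w * u) / sum(w) - target
    }
    th <- if (abs(f(0)) < 1e-12) 0 else
      stats::uniroot(f, c(-200, 200), tol = 1e-12)$root
    w <- exp(th * u); w <- w / sum(w)
    pick <- findInterval(rng$unif(1), cumsum(w)) + 1L
    order_out[k] <- remaining[pick]
    remaining <- remaining[-pick]
  }
  order_out[n] <- remaining
  Z <- integer(n)
  Z[order_out] <- seq_len(n)
  baseline_cohort(seq_len(n), Z, rep(1, n), X)
}
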