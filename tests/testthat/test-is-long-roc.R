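# helper: longitudinal cohort whose marker rises as the event approaches
drift_scenario <- function(n = 60) {
  longitudinal_scenario(
    n_case = n, n_control = n, n_visits = 4, visit_spacing = 365,
    visit_jitter = 20,
    case_fixef = c(1.2, 0, -8e-4, 0), case_ranef_sd = c(0.4, 1e-5),
    case_ranef_cor = 0, case_resid_sd = 0.3,
    control_fixef = c(0, 0), control_ranef_sd = c(0.4, 1e-5),
    control_ranef_cor = 0, control_resid_sd = 0.3,
    event_gap_mean = 500, control_followup = 3000)
}

first_visit_cohort <- function(lc) {
  d <- as.data.frame(lc)
  first <- d[!duplicated(d$id), ]
  baseline_cohort(first$id, first$time, first$event, first$marker)
}

test_that("static-control estimator honours its contracts and the uniform-weight oracle", {
  set.seed(301)
  n <- 200
  ch <- baseline_cohort(1:n, sort(stats::rexp(n, 1e-3)), rep(1, n),
                        stats::rnorm(n))
  t0 <- ch$time[5]
  t_star <- unname(stats::quantile(ch$time, 0.6))
  # no survivor beyond t_star: error
  expect_error(is2_auc(ch, t0, t_star = max(ch$time) + 1), "static control")
  # gamma(t) = 0: sensitivity is the survivor function over the
  # redefined risk set (case + static controls); AUC by enumeration
  r <- is2_auc(ch, t0, t_star, tv = 0)
  idx <- c(which(ch$time == t0), which(ch$time > t_star))
  expect_equal(r$sens,
               vapply(r$thresholds, function(cc) mean(ch$marker[idx] > cc), 0),
               tolerance = 1e-12)
  ctrl <- ch$marker[ch$time > t_star]
  bf <- mean(vapply(ch$marker[idx], function(x)
    mean((x > ctrl) + 0.5 * (x == ctrl)), 0))
  expect_equal(r$auc, bf, tolerance = 1e-12)
  expect_error(is2_auc(ch, t_star + 1, t_star), "smaller than t_star")
})

test_that("last-value markers beat baseline markers when trajectories drift before events", {
  sc <- drift_scenario()
  diffs_is2 <- diffs_ecd2 <- c()
  for (r in 1:25) {
    lc <- simulate_longitudinal(sc, seed = 400 + r)
    bc <- first_visit_cohort(lc)
    s0 <- 1095; t1 <- 1460
    lv <- try(last_value_cohort(lc, s0), silent = TRUE)
    if (inherits(lv, "try-error")) next
    tev <- lv$time[lv$event == 1 & lv$time > s0]
    if (!length(tev)) next
    t0 <- sort(tev)[ceiling(length(tev) / 4)]
    ts <- unname(stats::quantile(lv$time, 0.8))
    if (!(t0 < ts)) next
    a_lv <- try(auc_value(is2_auc(lv, t0, ts, tv = 0)), silent = TRUE)
    tev_b <- bc$time[bc$event == 1]
    a_bl <- try(auc_value(is2_auc(bc, t0, ts, tv = 0)), silent = TRUE)
    if (!inherits(a_lv, "try-error") && !inherits(a_bl, "try-error"))
      diffs_is2 <- c(diffs_is2, a_lv - a_bl)
    e_lv <- try(auc_value(ecd2_roc(lc, s0, t1)), silent = TRUE)
    e_bl <- try(auc_value(cd2_roc(bc, t1)), silent = TRUE)
    if (!inherits(e_lv, "try-error") && !inherits(e_bl, "try-error"))
      diffs_ecd2 <- c(diffs_ecd2, e_lv - e_bl)
  }
  expect_gt(length(diffs_is2), 10)
  expect_gt(mean(diffs_is2), 0)
  expect_gt(length(diffs_ecd2), 10)
  expect_gt(mean(diffs_ecd2), 0)
})

test_that("landmark nearest-neighbour estimation reduces to the baseline estimator and stays bounded", {
  # single baseline visit per subject: identical to the baseline curve
  set.seed(311)
  n <- 60
  Z <- stats::rexp(n, 1e-3) + 10
  lc <- longitudinal_cohort(1:n, rep(0, n), stats::rnorm(n), Z,
                            stats::rbinom(n, 1, 0.7))
  bc <- baseline_cohort(1:n, Z, lc$event[match(1:n, lc$id)],
                        lc$marker[match(1:n, lc$id)])
  s0 <- min(Z) / 2
  t0 <- unname(stats::quantile(Z[bc$event == 1], 0.5))
  a <- ecd2_roc(lc, s0, t0)
  b <- cd2_roc(bc, t0)
  expect_equal(a$sens, b$sens, tolerance = 1e-12)
  expect_equal(a$fpr, b$fpr, tolerance = 1e-12)
  # monotone and bounded across seeded longitudinal cohorts
  sc <- drift_scenario(40)
  for (r in 1:10) {
    lc <- simulate_longitudinal(sc, seed = 500 + r)
    a <- try(ecd2_roc(lc, 1095, 1825), silent = TRUE)
    if (inherits(a, "try-error")) next
    expect_true(is_monotone_curve(a))
    expect_true(in_unit(a$sens) && in_unit(a$fpr))
  }
})

test_that("trajectory mixed models recover their generating parameters", {
  lc <- simulate_longitudinal(longitudinal_scenario(), seed = 4)
  f <- ad1_fit(lc)
  k <- attr(f, "fits")$time_scale
  se_case <- stats::coef(summary(attr(f, "fits")$case))[
    c("(Intercept)", "vs", "ts", "vs:ts"), 2] / c(1, k, k, k^2)
  se_ctrl <- stats::coef(summary(attr(f, "fits")$control))[, 2] / c(1, k)
  truth_case <- c(1.139, -4.813e-4, 2.283e-4, -1.083e-7)
  truth_ctrl <- c(-0.569, 2.906e-4)
  expect_true(all(abs(f$case$beta - truth_case) < 2 * se_case))
  expect_true(all(abs(f$control$beta - truth_ctrl) < 2 * se_ctrl))
  # covariance entry is rho * sd_int * sd_slope by construction
  vc <- as.matrix(lme4::VarCorr(attr(f, "fits")$case)$id)[1:2, 1:2]
  rho_hat <- vc[1, 2] / sqrt(vc[1, 1] * vc[2, 2])
  expect_equal(f$case$V[1, 2],
               rho_hat * sqrt(f$case$V[1, 1]) * sqrt(f$case$V[2, 2]),
               tolerance = 1e-12)
  # control data generated with zero slope: slope estimate near zero
  sc0 <- longitudinal_scenario(n_case = 30, n_control = 80,
                               control_fixef = c(0.5, 0),
                               control_ranef_sd = c(0.3, 1e-6),
                               control_ranef_cor = 0,
                               control_resid_sd = 0.2)
  f0 <- ad1_fit(simulate_longitudinal(sc0, seed = 5))
  se0 <- stats::coef(summary(attr(f0, "fits")$control))[2, 2] /
    attr(f0, "fits")$time_scale
  expect_lt(abs(f0$control$beta[2]), 3 * se0)
})

test_that("model-implied moments match the published worked example and collapse at the origin", {
  fit <- pbc_published_mixed_fit()
  m <- ad1_moments(fit, s = 3650, t = 1825)
  expect_equal(round(unname(m["mu_control"]), 3), 0.492)
  expect_equal(round(unname(m["sd_case"]), 3), 1.207)
  expect_equal(round(unname(m["sd_control"]), 3), 1.217)
  m0 <- ad1_moments(fit, 0, 0)
  expect_equal(unname(m0["mu_case"]), fit$case$beta[1])
  expect_equal(unname(m0["sd_case"]),
               sqrt(fit$case$sigma^2 + fit$case$V[1, 1]))
})

test_that("induced binormal ROC is diagonal under equality and integrates to its closed form", {
  eq <- mixed_model_fit(case_fixef = c(0.5, 0, 0, 0),
                        control_fixef = c(0.5, 0),
                        case_ranef_sd = c(0.4, 1e-6), case_ranef_cor = 0,
                        case_resid_sd = 0.3,
                        control_ranef_sd = c(0.4, 1e-6),
                        control_ranef_cor = 0, control_resid_sd = 0.3)
  r <- ad1_roc(eq, 100, 50)
  expect_equal(r$auc, 0.5, tolerance = 1e-12)
  expect_lt(max(abs(r$sens - r$fpr)), 1e-10)
  # closed form vs numeric integration on a fine grid
  fit <- pbc_published_mixed_fit()
  r <- ad1_roc(fit, 3650, 1825, p = seq(1e-5, 1 - 1e-5, length.out = 1e4))
  expect_lt(abs(r$auc - trapezoid_auc(r$fpr, r$sens)), 1e-6)
  # case mean one case-SD above the control mean, equal SDs:
  # AUC = pnorm(1 / sqrt(2))
  up <- mixed_model_fit(case_fixef = c(1.3, 0, 0, 0),
                        control_fixef = c(0.8, 0),
                        case_ranef_sd = c(0.3, 1e-6), case_ranef_cor = 0,
                        case_resid_sd = 0.4,
                        control_ranef_sd = c(0.3, 1e-6),
                        control_ranef_cor = 0, control_resid_sd = 0.4)
  # sd = sqrt(0.4^2 + 0.3^2) = 0.5; mean gap = 0.5 = one SD
  r <- ad1_roc(up, 0, 0)
  expect_equal(r$auc, stats::pnorm(1 / sqrt(2)), tolerance = 1e-10)
})

test_that("ROC-GLM recovers the null and a known binormal model", {
  set.seed(321)
  mk <- function(n, case) data.frame(
    id = paste0(ifelse(case, "c", "q"), seq_len(n)), visit = 0,
    y = stats::rnorm(n), time = 1000 + stats::runif(n, 0, 500),
    ev = as.numeric(case))
  d <- rbind(mk(150, TRUE), mk(150, FALSE))
  lc0 <- longitudinal_cohort(d$id, d$visit, d$y, d$time, d$ev)
  f0 <- ad2_fit(lc0, time_effect = FALSE)
  expect_lt(abs(f0$gamma0), 0.15)
  expect_lt(abs(f0$gamma1 - 1), 0.2)
  r0 <- ad2_roc(f0, 0)
  expect_lt(max(abs(r0$sens - r0$fpr)), 0.1)
  # binormal generation: controls N(0,1), cases N(0.8 - 0.3 tbe, 1)
  # implies gamma0 = 0.8, gamma1 = 1, alpha = -0.3
  set.seed(322)
  n <- 400
  tbe <- stats::runif(n, 0, 5)
  dd <- rbind(
    data.frame(id = paste0("c", 1:n), visit = 2000 - tbe,
               y = stats::rnorm(n, 0.8 - 0.3 * tbe, 1), time = 2000, ev = 1),
    data.frame(id = paste0("q", 1:n), visit = 0, y = stats::rnorm(n),
               time = 3000, ev = 0))
  f1 <- ad2_fit(longitudinal_cohort(dd$id, dd$visit, dd$y, dd$time, dd$ev))
  expect_lt(abs(f1$gamma0 - 0.8), 0.2)
  expect_lt(abs(f1$gamma1 - 1), 0.2)
  expect_lt(abs(f1$alpha + 0.3), 0.06)
  # probit monotonicity for any fit with positive slope
  r <- ad2_roc(f1, 2)
  expect_true(all(diff(r$sens[order(r$fpr)]) >= -1e-12))
})
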