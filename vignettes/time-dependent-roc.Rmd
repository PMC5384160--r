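---
title: "Time-dependent ROC methods in tdauc: models, conventions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dependent ROC methods in tdauc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdauc)
```

## The problem

A scalar marker $X$ (a lab value, or a risk score from a survival
model) is measured on $n$ subjects followed for a right-censored event
time. We observe $Z_i = \min(T_i, C_i)$ and $\delta_i = I(T_i \le
C_i)$. Classical ROC analysis treats "diseased" as a fixed label;
with event times the label depends on the horizon, and sensitivity and
specificity become functions of time. Three case/control definitions
are standard:

* **cumulative/dynamic (C/D)** — cases have $T \le t$, controls have
  $T > t$; the clinically usual "who fails by $t$" question;
* **incident/dynamic (I/D)** — cases have $T = t$ exactly, controls
  $T > t$; the natural companion of hazard models, and the basis of
  concordance summaries;
* **incident/static (I/S)** — cases incident at $t$, controls
  event-free past a fixed horizon $t^*$ ("long-term survivors").

For each definition the AUC at $t$ is the probability that a random
case outranks a random control, $P(X_i > X_j \mid \cdot)$. The whole
difficulty is censoring: subjects censored before $t$ have an unknown
status at $t$, and naive removal biases the estimates, increasingly so
when censoring depends on the marker.

## Estimators implemented

**Cumulative/dynamic.** `naive_roc()` discards censored subjects
before $t$. `cd1_roc()` applies Bayes' theorem with conditional
Kaplan–Meier curves on marker subsets; its implied quadrant
probabilities need not form a valid joint distribution, so sensitivity
and specificity can be non-monotone and exit $[0,1]$ — the raw values
are flagged, never clipped. `cd2_roc()` replaces the conditional KM
with the nearest-neighbour weighted KM on the marker's empirical-CDF
scale (window half-width $\lambda$, i.e. a $2\lambda$ fraction of the
sample per window), which makes the curve monotone, bounded, invariant
to increasing marker transforms, and robust to marker-dependent
censoring. `cd3_roc()` is the closed-form Kaplan–Meier-like recursion:
each observed event carries the KM increment of its event time.
`cd4_roc()` weights every subject by its conditional absolute risk
under a Cox fit of the marker (monotone, but not transform-invariant —
a documented asymmetry we test rather than hide). `cd5_roc()` and
`cd6_roc()` are the marginal and marker-conditional
inverse-probability-of-censoring-weighted (IPCW) estimators;
`cd7_weighted_auc()` averages any C/D AUC over an interval with
KM-increment weights; `cd8_auc()` is the plug-in family built on
conditional absolute risk estimates under Cox, Aalen-additive, or
nearest-neighbour KM working models.

**Incident/dynamic.** `id1_roc()` uses exponentially tilted risk-set
weights $\pi_i(t) \propto \exp\{X_i \hat\gamma(t)\}$ with
$\hat\gamma(t)$ from `smooth_tv_coef()`; `concordance_tau()` averages
the incident AUC with weights $2f(t)S(t)/(1-S(\tau)^2)$;
`id2_wmr()` locally averages the risk-set concordance U-statistic
$A(t)$; `id3_fit()`/`id3_auc()` model $\mathrm{link}(AUC(t))$ as a
fractional polynomial fitted by a pseudo partial-likelihood that is a
binomial likelihood in the per-risk-set concordant/discordant pair
counts, so it is maximised exactly by `stats::glm`, with an exhaustive
search over the candidate powers $\{-2,-1,-\tfrac12,0,\tfrac12,1,2\}$
(distinct powers, degrees 0–2).

**Incident/static and longitudinal markers.** `is2_auc()` re-uses the
riskset-Cox machinery with the control set replaced by the static
survivors beyond $t^*$, optionally with each subject's most recent
marker value before a landmark (`last_value_cohort()`); `ecd2_roc()`
is the nearest-neighbour estimator on the landmark last-value cohort;
`ad1_fit()`/`ad1_moments()`/`ad1_roc()` fit the paired case/control
linear mixed-effects models of serial measurements and induce a
Gaussian binormal ROC from the implied moments; `ad2_fit()`/`ad2_roc()`
regress case–control pair indicators on the normal quantile of the
control placement value with a probit link, giving a binormal ROC with
a linear effect of time before event.

## Conventions that matter (and why)

* **Tie handling.** Events precede censorings at tied times. For the
  censoring curve this means a subject failing at $t$ has left the
  risk set before the censoring jump at $t$ (`censoring_km()` differs
  here from a literal reverse KM exactly on mixed ties). This is what
  makes the IPCW sensitivity *identical* to the KM-like recursion's —
  an identity the suite asserts to $10^{-12}$ on tied and untied data.
  Cox fits use Breslow ties.
* **IPCW left limits.** Weights evaluate the censoring curve at
  $Z_i^-$, so an event never discounts itself through censoring mass
  at its own time; a flag (`left = FALSE`) restores the
  right-continuous reading.
* **Nearest-neighbour window.** Default $\lambda = 0.25\,n^{-1/3}$ (so
  the window shrinks at the rate usually recommended); the `vl_km`
  risk plug-in uses $0.25\,n^{-1/5}$, matching the plug-in guidance for
  that family. The window acts on the empirical CDF, hence transform
  invariance. Plain numeric $\lambda \ge 0.5$ saturates the window —
  outside the sensible range, but useful for degenerate-limit checks.
* **Threshold grid.** The unique marker values plus $\pm\infty$
  sentinels: exact empirical curves, no binning; every curve contains
  $(0,0)$ and $(1,1)$. AUCs of curve-producing estimators are
  trapezoids over these step points and coincide with the estimator's
  pairwise form (half-weight on marker ties) to $10^{-8}$ on tie-free
  data — a per-estimator test.
* **Risk plug-in normalisation.** The rank form of `cd8_auc()` is the
  U-statistic $\sum_{i \ne j} I(X_i > X_j) F_i (1-F_j) / \sum_{i \ne
  j} F_i (1-F_j)$: self-pairs are excluded from numerator and
  denominator alike, so an exchangeable (constant-risk) profile gives
  exactly $1/2$ at any $n$, and the $O(n\log n)$ rank form equals the
  brute-force double sum to $10^{-10}$.
* **Concordance discretisation.** $C^\tau$ uses the telescoping
  weights $w_k = (S_{k-1}-S_k)(S_{k-1}+S_k) / (1 - S_m^2)$, the exact
  discrete counterpart of $2 f(t) S(t)$: they sum to one identically
  (the plain Riemann form misses by $\sum (\Delta S)^2$, which is far
  from negligible at small $n$).
* **Time-varying coefficient.** The scaled Schoenfeld residuals
  returned by `survival` are per-event estimates of $\gamma(t)$
  (the coefficient is already folded in); `smooth_tv_coef()`
  local-linearly smooths them on the event-rank scale, as `cox.zph`
  does, which keeps the sparse right tail from whipping the smoother.
  Under proportional hazards at $n = 1000$ the smoothed curve stays
  within 0.25 of the partial-likelihood estimate (observed: about
  0.05–0.1).
* **Induced binormal sign convention.** With survival-style
  location-scale families, $ROC(p) = S_D[a_0 + a_1
  S_{\bar D}^{-1}(p)]$ with $a_0 = (\mu_{\bar D} - \mu_D)/s_D$ and
  $a_1 = s_{\bar D}/s_D$ evaluates to $\Phi(-a_0 + a_1 \Phi^{-1}(p))$,
  and its exact integral is $AUC = \Phi(-a_0/\sqrt{1 + a_1^2})$ — the
  closed form is cross-checked against quadrature of the curve to
  $10^{-6}$. The variance design uses only the random-effect columns
  $[1, s]$ (the covariance is $2 \times 2$), while the mean design for
  cases is $[1, s, t, st]$; visit time and time before event are in
  days. The shipped published estimates reproduce the reference
  moments (control mean 0.492; case and control SDs 1.207 and 1.217 at
  a ten-year visit) under exactly this construction.
* **Cases and controls for the trajectory models.** Subjects with an
  observed event are cases; censored subjects are retained as the
  event-free group. These models do not weight for censoring — a known
  limitation of the family, flagged in the documentation rather than
  silently absorbed.
* **Landmark semantics.** `last_value_cohort()` keeps subjects with
  $Z > s_0$ strictly (matching the strict inequalities of the control
  definitions), carries the most recent marker value at $s \le s_0$,
  and leaves the time axis on the original scale.

## The synthetic cohorts

`simulate_baseline()` draws a standard-normal (or uniform) marker and
event times from an exponential or Weibull proportional-hazards model
or an additive-hazards model, with censoring independent exponential
or marker-dependent (hazard $r\,e^{\eta X}$). Defaults — times in
days, baseline hazard $2 \times 10^{-4}$/day, log hazard ratio 1,
independent censoring at $10^{-4}$/day (roughly a third censored) —
are one fixed choice of realistic cohort, not tuning knobs. The
returned oracle evaluates the true conditional risk in closed form,
and `true_cd_auc()`/`true_id_auc()` integrate it by trapezoid
quadrature with a cumulative inner integral (error well below
$10^{-6}$; cross-checked against a $10^6$-draw Monte Carlo).

`simulate_longitudinal()` draws case/control trajectories from the
same paired mixed models the estimators assume, defaulting to the
published PBC-scale parameters with five annual visits (30-day
jitter); case event times fall strictly after the last visit so the
time before event is defined everywhere.

`simulate_constant_id_auc()` / `simulate_profile_id_auc()` build
uncensored cohorts whose risk-set concordance has a *prescribed*
incident-AUC profile: markers are i.i.d. uniform and the event order
is drawn sequentially with an exponentially tilted distribution over
the current risk-set ranks, the tilt solved per risk set so that the
case outranks a random control with exactly the target probability.
This gives the fractional-polynomial model a generating truth to
recover without appealing to any particular hazard family.

What the generators deliberately do *not* emulate: covariates beyond
the scalar marker, competing risks, informative visit schedules, and
measurement error in the marker. Passing tests therefore demonstrate
correctness of the estimators under their stated assumptions, not
robustness to violations the methods themselves do not claim to
handle.

## Problem sizes and numerical tolerances in the checks

Exact identities (IPCW = KM-like sensitivity; rank form = double sum;
weight normalisations; transform invariance; zero-censoring
reductions) are asserted at $10^{-8}$–$10^{-12}$ on cohorts of 40–80
subjects. Statistical checks use one fixed seed each at sizes chosen
for stable behaviour at modest cost: coefficient recovery and
cross-estimator agreement at $n = 2000$; mixed-model recovery at
200 + 200 subjects with five visits (per-coefficient median z over
three cohorts, so a single 5%-probability excursion is not mistaken
for bias); bootstrap coverage with 200 resamples over 100 cohorts of
$n = 120$; the marker-dependent-censoring robustness comparison over
200 replicates of $n = 300$ at censoring hazard
$2\times10^{-4} e^{2X}$ (about half censored — the strong-dependence
regime in which conditional reweighting is claimed, and observed, to
beat the conditional KM).

## Known limitations

* The riskset-Cox sensitivity uses the marker as its only covariate;
  adjustment for additional time-invariant covariates is out of scope.
* The trajectory models (`ad1`, `ad2`) ignore censoring within the
  control group by construction; with heavy informative censoring
  their case/control contrast is attenuated.
* `id2_wmr()` exposes a fixed-span default bandwidth (nearest 10% of
  event times); a mean-integrated-squared-error-optimal choice is a
  sensible refinement the interface leaves room for but does not
  implement.
* Competing risks are not supported anywhere; event indicators are
  strictly binary.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_baseline(baseline_scenario(n = 500), seed = 1)
t0 <- 1500  # days
td_auc_table(sim$cohort, t0, "cd2")
td_auc_table(sim$cohort, t0, "cd5", boot = 200, seed = 1)
true_cd_auc(sim$oracle, t0)

fit <- pbc_published_mixed_fit()
ad1_moments(fit, s = 3650, t = 1825)
plot(ad1_roc(fit, 3650, 365))
```
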