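# Fixture builders and brute-force oracles shared across the suite.

# random censored cohort with continuous (a.s. tie-free) times
rand_cohort <- function(n, seed, cens_rate = 6e-4, event_rate = 1e-3,
                        tie_times = FALSE) {
  set.seed(seed)
  T <- stats::rexp(n, event_rate)
  C <- if (cens_rate > 0) stats::rexp(n, cens_rate) else rep(Inf, n)
  Z <- pmin(T, C)
  if (tie_times) Z <- ceiling(Z / 200) * 200
  baseline_cohort(seq_len(n), Z, as.numeric(T <= C), stats::rnorm(n))
}

# the 4-subject uncensored toy: marker 2,4,1,3 with event times 1,2,3,4
toy4 <- function() baseline_cohort(1:4, c(1, 2, 3, 4), rep(1, 4), c(2, 4, 1, 3))

# brute-force product-limit over risk sets (independent of .wkm)
bf_km <- function(Z, delta, times) {
  vapply(times, function(t0) {
    tev <- sort(unique(Z[delta == 1 & Z <= t0]))
    prod(vapply(tev, function(a)
      1 - sum(Z == a & delta == 1) / sum(Z >= a), 0))
  }, 0)
}

# brute-force naive AUC by pair enumeration
bf_naive_auc <- function(ch, t0) {
  case <- which(ch$event == 1 & ch$time <= t0)
  ctrl <- which(ch$time > t0)
  num <- 0
  for (i in case) for (j in ctrl)
    num <- num + (ch$marker[i] > ch$marker[j]) +
      0.5 * (ch$marker[i] == ch$marker[j])
  num / (length(case) * length(ctrl))
}

# monotone non-decreasing fpr/sens along the stored (descending
# threshold) order, within tolerance
is_monotone_curve <- function(r, tol = 1e-10) {
  all(diff(r$sens) >= -tol) && all(diff(r$fpr) >= -tol)
}

in_unit <- function(x, tol = 1e-10) all(x >= -tol & x <= 1 + tol)

transform_marker <- function(ch, f = exp) {
  baseline_cohort(ch$id, ch$time, ch$event, f(ch$marker))
}

# mid-range event time with both cases and controls present
pick_t <- function(ch, q = 0.5) {
  unname(stats::quantile(ch$time[ch$event == 1], q, type = 1))
}
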