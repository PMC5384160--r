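#' Time-dependent AUC at one or several time points
#'
#' Uniform front-end over the estimator families, returning a
#' long-format table (the layout the command-line interface writes).
#' Cumulative/dynamic methods accept any positive time; incident
#' methods require observed event times except `id2`/`id3`, which
#' smooth or model over time.
#'
#' @param cohort A [baseline_cohort()] (or [longitudinal_cohort()] for
#'   `"is2"`).
#' @param times Evaluation times (positive, sorted internally).
#' @param method One of `"naive"`, `"cd1"`...`"cd6"`, `"vl_cox"`,
#'   `"vl_aalen"`, `"vl_km"`, `"id1"`, `"id2"`, `"id3"`, `"is2"`.
#' @param boot Number of bootstrap resamples for percentile confidence
#'   intervals; 0 disables.
#' @param level Confidence level for the bootstrap interval.
#' @param seed Integer seed (bootstrap only).
#' @param ... Method-specific options (`lambda`, `bandwidth`, `G`,
#'   `link`, `t_star`, `landmark`, ...).
#' @return A data frame with columns `method`, `t`, `auc`, `ci_low`,
#'   `ci_high`, `n_boot`, `seed`.
#' @export
td_auc_table <- function(cohort, times, method, boot = 0, level = 0.95,
                         seed = 1L, ...) {
  times <- sort(unique(as.numeric(times)))
  if (any(times <= 0)) stop("time points must be positive")
  est <- td_estimator(method, ...)
  rows <- lapply(times, function(tt) {
    if (boot > 0) {
      r <- bootstrap_ci(function(ch) auc_value(est(ch, tt)), cohort,
                        B = boot, level = level, seed = seed,
                        method = method, t = tt)
      data.frame(method = method, t = tt, auc = r$auc, ci_low = r$ci_low,
                 ci_high = r$ci_high, n_boot = boot, seed = seed)
    } else {
      data.frame(method = method, t = tt,
                 auc = auc_value(est(cohort, tt)),
                 ci_low = NA_real_, ci_high = NA_real_,
                 n_boot = 0L, seed = NA_integer_)
    }
  })
  do.call(rbind, rows)
}

#' Resolve a method name to an estimator function
#'
#' @param method Method tag (see [td_auc_table()]).
#' @param ... Fixed method options bound into the returned closure.
#' @return A function `f(cohort, t)` returning an object understood by
#'   [auc_value()].
#' @export
td_estimator <- function(method, ...) {
  opts <- list(...)
  pick <- function(f, allowed) {
    o <- opts[intersect(names(opts), allowed)]
    function(cohort, t) do.call(f, c(list(cohort, t), o))
  }
  switch(method,
    naive = pick(naive_roc, character(0)),
    cd1 = pick(cd1_roc, character(0)),
    cd2 = pick(cd2_roc, "lambda"),
    cd3 = pick(cd3_roc, character(0)),
    cd4 = pick(cd4_roc, "fit"),
    cd5 = pick(cd5_roc, "left"),
    cd6 = pick(cd6_roc, c("censoring_model", "lambda", "left")),
    vl_cox = function(cohort, t) cd8_auc(cohort, t, "vl_cox"),
    vl_aalen = function(cohort, t) cd8_auc(cohort, t, "vl_aalen"),
    vl_km = function(cohort, t)
      do.call(cd8_auc, c(list(cohort, t, "vl_km"),
                         opts[intersect(names(opts), "lambda")])),
    id1 = pick(id1_roc, "tv"),
    id2 = pick(id2_wmr, c("bandwidth", "kernel")),
    id3 = function(cohort, t) {
      G <- opts$G %||% 1
      link <- opts$link %||% "logit"
      id3_auc(id3_fit(cohort, G = G, link = link), t)
    },
    is2 = function(cohort, t)
      do.call(is2_auc, c(list(cohort, t),
                         opts[intersect(names(opts),
                                        c("t_star", "landmark", "tv"))])),
    stop("unknown method: ", method)
  )
}
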