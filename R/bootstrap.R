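#' Subject-level bootstrap confidence interval
#'
#' Percentile bootstrap for any scalar statistic of a cohort. Subjects
#' are resampled with replacement; for a longitudinal cohort whole
#' subjects (all visits) are resampled and relabelled so ids stay
#' unique. A resample on which the statistic fails is redrawn (with a
#' logged count); more than 10% failed resamples is an error. The
#' interval is deterministic given the seed.
#'
#' @param statistic Function `f(cohort) -> number`, e.g.
#'   `function(ch) auc_value(cd5_roc(ch, t = 365))`.
#' @param cohort A [baseline_cohort()] or [longitudinal_cohort()].
#' @param B Number of bootstrap resamples (>= 50).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @param method Label stored on the result.
#' @param t Evaluation-time label stored on the result.
#' @return A `td_auc` object whose `auc` is the point estimate on the
#'   original cohort, with percentile `ci_low`/`ci_high`, `n_boot`,
#'   `seed`; the resample statistics are in attribute `"boot"` and the
#'   redraw count in attribute `"failures"`.
#' @export
bootstrap_ci <- function(statistic, cohort, B = 200, level = 0.95,
                         seed = 1L, method = "bootstrap", t = NA_real_) {
  if (B < 50) stop("B must be at least 50")
  point <- statistic(cohort)
  longi <- inherits(cohort, "longitudinal_cohort")
  ids <- if (longi) unique(cohort$id) else cohort$id
  n <- length(ids)
  rows_by_id <- if (longi) split(seq_len(nrow(cohort)), cohort$id)
  rng <- .local_rng(seed)
  resample <- function() {
    take <- ids[ceiling(rng$unif(n) * n)]
    if (!longi) {
      ix <- match(take, cohort$id)
      baseline_cohort(seq_len(n), cohort$time[ix], cohort$event[ix],
                      cohort$marker[ix])
    } else {
      ix <- unlist(rows_by_id[take], use.names = FALSE)
      reps <- lengths(rows_by_id[take])
      longitudinal_cohort(rep(seq_len(n), reps), cohort$visit_time[ix],
                          cohort$marker[ix], cohort$time[ix],
                          cohort$event[ix])
    }
  }
  vals <- numeric(B)
  failures <- 0L
  for (b in seq_len(B)) {
    repeat {
      v <- tryCatch(statistic(resample()), error = function(e) NA_real_)
      if (is.finite(v)) break
      failures <- failures + 1L
      if (failures > ceiling(0.1 * B))
        stop("more than 10% of bootstrap resamples failed (", failures,
             " failures)")
    }
    vals[b] <- v
  }
  if (failures) message(failures, " bootstrap resample(s) redrawn")
  alpha <- (1 - level) / 2
  qs <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- new_td_auc(t, point, method, ci_low = qs[1], ci_high = qs[2],
                    n_boot = as.integer(B), seed = as.integer(seed))
  attr(out, "boot") <- vals
  attr(out, "failures") <- failures
  out
}
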