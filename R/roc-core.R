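# ROC curve / AUC containers shared by every estimator family.

# Build a td_roc object from per-threshold sensitivity and false positive
# rate. Thresholds are stored in descending order so that (fpr, sens)
# runs from (0,0) to (1,1); +-Inf sentinels guarantee the end points.
new_td_roc <- function(t, thresholds, sens, fpr, method, auc = NULL,
                       flags = character(0)) {
  o <- order(thresholds, decreasing = TRUE)
  thresholds <- thresholds[o]; sens <- sens[o]; fpr <- fpr[o]
  if (is.null(auc)) auc <- trapezoid_auc(fpr, sens)
  structure(list(t = t, thresholds = thresholds, sens = sens, fpr = fpr,
                 method = method, auc = auc, flags = flags),
            class = "td_roc")
}

#' Trapezoidal area under an ROC curve
#'
#' @param fpr False-positive rates (any order; sorted internally).
#' @param sens Matching sensitivities.
#' @return Scalar area.
#' @export
trapezoid_auc <- function(fpr, sens) {
  o <- order(fpr, sens)
  fpr <- fpr[o]; sens <- sens[o]
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

#' @export
print.td_roc <- function(x, ...) {
  cat(sprintf("Time-dependent ROC [%s] at t = %g: AUC = %.4f (%d thresholds)\n",
              x$method, x$t, x$auc, length(x$thresholds)))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
plot.td_roc <- function(x, add = FALSE, ...) {
  if (!add) {
    graphics::plot(x$fpr, x$sens, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                   xlab = "1 - specificity", ylab = "sensitivity",
                   main = sprintf("%s, t = %g (AUC = %.3f)", x$method, x$t,
                                  x$auc), ...)
    graphics::abline(0, 1, lty = 3, col = "grey60")
  } else {
    graphics::lines(x$fpr, x$sens, type = "s", ...)
  }
  invisible(x)
}

# scalar AUC container
new_td_auc <- function(t, auc, method, ci_low = NA_real_, ci_high = NA_real_,
                       n_boot = NA_integer_, seed = NA_integer_,
                       flags = character(0)) {
  structure(list(t = t, auc = auc, method = method, ci_low = ci_low,
                 ci_high = ci_high, n_boot = n_boot, seed = seed,
                 flags = flags),
            class = "td_auc")
}

#' @export
print.td_auc <- function(x, ...) {
  ci <- if (is.finite(x$ci_low))
    sprintf(" [%.4f, %.4f] (%d bootstrap resamples)", x$ci_low, x$ci_high,
            x$n_boot) else ""
  cat(sprintf("AUC [%s] at t = %g: %.4f%s\n", x$method, x$t, x$auc, ci))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Extract the scalar AUC
#'
#' @param x A `td_roc` or `td_auc` object.
#' @return The AUC as a plain number.
#' @export
auc_value <- function(x) {
  if (inherits(x, c("td_roc", "td_auc"))) return(x$auc)
  as.numeric(x)
}

# threshold grid: unique marker values plus +-Inf sentinels
.threshold_grid <- function(X) c(-Inf, sort(unique(X)), Inf)

# weighted "proportion above c" curve over a threshold grid:
# returns sum(w * (X > c)) for each c, normalised by sum(w)
.surv_curve <- function(X, w, grid) {
  sw <- sum(w)
  vapply(grid, function(cc) sum(w * (X > cc)), 0) / sw
}

# pairwise probability that a case marker exceeds a control marker,
# with case weights wc on Xc and control weights wq on Xq; ties get
# half weight.
.pairwise_auc <- function(Xc, wc, Xq, wq) {
  num <- 0
  for (i in seq_along(Xc)) {
    num <- num + wc[i] * sum(wq * ((Xc[i] > Xq) + 0.5 * (Xc[i] == Xq)))
  }
  num / (sum(wc) * sum(wq))
}
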