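#' Published mixed-model estimates for the Mayo PBC serial marker
#'
#' Loads the published case/control linear mixed-effects estimates for
#' the Cox model score in the Mayo Clinic primary biliary cirrhosis
#' (DPCA trial) sequential data — the worked illustration of the
#' induced-binormal method, with visit time and time before event in
#' days — as a [mixed_model_fit()], ready for [ad1_moments()] and
#' [ad1_roc()].
#'
#' @return A [mixed_model_fit()].
#' @export
#' @examples
#' fit <- pbc_published_mixed_fit()
#' ad1_moments(fit, s = 3650, t = 1825)
pbc_published_mixed_fit <- function() {
  path <- system.file("extdata", "pbc_ad1_published_estimates.csv",
                      package = "tdauc", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  g <- function(p, col) {
    v <- d[[col]][d$parameter == p]
    if (!length(v) || is.na(v)) NA_real_ else as.numeric(v)
  }
  mixed_model_fit(
    case_fixef = c(g("fixef_intercept", "case"),
                   g("fixef_visit_time", "case"),
                   g("fixef_time_before_event", "case"),
                   g("fixef_visit_time_x_tbe", "case")),
    control_fixef = c(g("fixef_intercept", "control"),
                      g("fixef_visit_time", "control")),
    case_ranef_sd = c(g("ranef_sd_intercept", "case"),
                      g("ranef_sd_visit_time", "case")),
    case_ranef_cor = g("ranef_cor", "case"),
    case_resid_sd = g("resid_sd", "case"),
    control_ranef_sd = c(g("ranef_sd_intercept", "control"),
                         g("ranef_sd_visit_time", "control")),
    control_ranef_cor = g("ranef_cor", "control"),
    control_resid_sd = g("resid_sd", "control"))
}
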