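#' Baseline survival cohort
#'
#' Bundles the observed follow-up time `Z = min(T, C)`, the event
#' indicator `delta` (1 = event observed, 0 = censored) and a scalar
#' marker (or risk score) `X` for `n` subjects. Higher marker values are
#' taken as more indicative of disease throughout the package. Times are
#' carried in a single user-declared unit (default days); the package
#' never converts units internally.
#'
#' @param id Subject identifiers (unique; coerced to character).
#' @param time Observed event/censoring times, finite and positive.
#' @param event Event indicators, each 0 or 1.
#' @param marker Scalar marker or risk-score values, finite.
#' @param time_unit Label for the time unit (metadata only).
#'
#' @return An object of class `baseline_cohort`: a data frame with
#'   columns `id`, `time`, `event`, `marker` and attribute `time_unit`.
#' @export
#' @examples
#' baseline_cohort(1:4, c(1, 2, 3, 4), c(1, 1, 1, 1), c(2, 4, 1, 3))
baseline_cohort <- function(id, time, event, marker, time_unit = "days") {
  id <- as.character(id)
  time <- as.numeric(time)
  event <- as.numeric(event)
  marker <- as.numeric(marker)
  n <- length(id)
  if (n < 2L) stop("a baseline cohort needs at least 2 subjects")
  if (length(time) != n || length(event) != n || length(marker) != n)
    stop("id, time, event and marker must have equal length")
  if (anyDuplicated(id)) stop("subject ids must be unique")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("all observed times must be finite and > 0")
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop("event indicator must be 0 or 1; offending row(s): ",
         paste(bad, collapse = ", "))
  if (any(!is.finite(marker))) stop("all marker values must be finite")
  out <- data.frame(id = id, time = time, event = event, marker = marker,
                    stringsAsFactors = FALSE)
  attr(out, "time_unit") <- time_unit
  class(out) <- c("baseline_cohort", "data.frame")
  out
}

#' @export
print.baseline_cohort <- function(x, ...) {
  cat(sprintf("Baseline cohort: %d subjects, %d events (%.1f%%), time unit %s\n",
              nrow(x), sum(x$event), 100 * mean(x$event),
              attr(x, "time_unit") %||% "days"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Longitudinal survival cohort
#'
#' Long-format container for repeated biomarker measurements: one row
#' per visit, each subject carrying an observed event time `Z`, event
#' indicator `delta` and an ascending sequence of (visit time, marker)
#' pairs. Retained visits always satisfy `s <= Z`.
#'
#' @param id Subject identifier per visit row.
#' @param visit_time Visit time of each measurement.
#' @param marker Marker value at the visit.
#' @param time Observed event/censoring time of the subject (constant
#'   within subject).
#' @param event Event indicator of the subject (constant within subject).
#' @param visit_policy What to do with visits recorded after the
#'   subject's observed time: `"drop-after-Z"` removes them with a
#'   warning reporting the count, `"error"` fails.
#' @param time_unit Label for the time unit (metadata only).
#'
#' @return An object of class `longitudinal_cohort`: a long-format data
#'   frame with columns `id`, `visit_time`, `marker`, `time`, `event`,
#'   sorted by subject and visit time.
#' @export
longitudinal_cohort <- function(id, visit_time, marker, time, event,
                                visit_policy = c("drop-after-Z", "error"),
                                time_unit = "days") {
  visit_policy <- match.arg(visit_policy)
  id <- as.character(id)
  d <- data.frame(id = id, visit_time = as.numeric(visit_time),
                  marker = as.numeric(marker), time = as.numeric(time),
                  event = as.numeric(event), stringsAsFactors = FALSE)
  if (any(!is.finite(d$visit_time)) || any(!is.finite(d$marker)))
    stop("visit times and marker values must be finite")
  if (any(!is.finite(d$time)) || any(d$time <= 0))
    stop("all observed times must be finite and > 0")
  if (!all(d$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1")
  per <- tapply(seq_len(nrow(d)), d$id, function(ix) {
    if (length(unique(d$time[ix])) > 1L || length(unique(d$event[ix])) > 1L)
      stop("time and event must be constant within subject ", d$id[ix[1]])
  })
  if (anyDuplicated(d[c("id", "visit_time")]))
    stop("duplicate (subject, visit time) rows")
  late <- d$visit_time > d$time
  if (any(late)) {
    if (visit_policy == "error")
      stop(sum(late), " visit(s) recorded after the observed time")
    warning("dropped ", sum(late), " visit(s) after the observed time")
    d <- d[!late, , drop = FALSE]
  }
  if (!nrow(d)) stop("no visits remain")
  nvis <- table(d$id)
  if (any(nvis < 1L)) stop("every subject needs at least one visit")
  d <- d[order(d$id, d$visit_time), , drop = FALSE]
  rownames(d) <- NULL
  attr(d, "time_unit") <- time_unit
  class(d) <- c("longitudinal_cohort", "data.frame")
  d
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat(sprintf(
    "Longitudinal cohort: %d subjects, %d visits, %d events, time unit %s\n",
    length(unique(x$id)), nrow(x),
    sum(x$event[!duplicated(x$id)]),
    attr(x, "time_unit") %||% "days"))
  invisible(x)
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

.map_cols <- function(d, column_map, needed, path) {
  for (nm in names(column_map)) {
    src <- column_map[[nm]]
    if (!src %in% names(d))
      stop("column '", src, "' (mapped to ", nm, ") missing in ", path)
    names(d)[names(d) == src] <- nm
  }
  miss <- setdiff(needed, names(d))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  d
}

#' Read a baseline cohort from delimited text
#'
#' CSV or TSV (auto-detected by extension), one row per subject with a
#' header. Rows with missing time or marker are rejected and counted in
#' a warning; non-0/1 event values are a validation error naming the row.
#'
#' @param path File path.
#' @param column_map Named list/character vector mapping the canonical
#'   names `id`, `time`, `event`, `marker` to the file's column names;
#'   columns already canonically named need no entry.
#' @param time_unit Label for the time unit.
#' @return A [baseline_cohort()].
#' @export
read_baseline <- function(path, column_map = NULL, time_unit = "days") {
  d <- .read_delim_auto(path)
  d <- .map_cols(d, column_map, c("id", "time", "event", "marker"), path)
  bad <- which(!(d$event %in% c(0, 1)))
  if (length(bad))
    stop("event values outside {0,1} at row(s): ", paste(bad, collapse = ", "))
  drop <- !is.finite(suppressWarnings(as.numeric(d$time))) |
    !is.finite(suppressWarnings(as.numeric(d$marker)))
  if (any(drop)) {
    warning("rejected ", sum(drop), " row(s) with missing time or marker")
    d <- d[!drop, , drop = FALSE]
  }
  baseline_cohort(d$id, d$time, d$event, d$marker, time_unit = time_unit)
}

#' Write a baseline cohort as CSV
#'
#' Numeric columns are written with full precision so that
#' `read_baseline(write_baseline(x))` round-trips exactly.
#'
#' @param cohort A [baseline_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baseline <- function(cohort, path) {
  d <- as.data.frame(cohort)
  d$time <- format(d$time, digits = 17, trim = TRUE, scientific = FALSE)
  d$marker <- format(d$marker, digits = 17, trim = TRUE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a longitudinal cohort from delimited text
#'
#' Long format, one visit per row, with columns `id`, `visit_time`,
#' `marker`, `time`, `event` (or mapped via `column_map`).
#'
#' @inheritParams read_baseline
#' @param visit_policy Passed to [longitudinal_cohort()]: how to treat
#'   visits recorded after the subject's observed time.
#' @return A [longitudinal_cohort()].
#' @export
read_longitudinal <- function(path, column_map = NULL,
                              visit_policy = c("drop-after-Z", "error"),
                              time_unit = "days") {
  d <- .read_delim_auto(path)
  d <- .map_cols(d, column_map,
                 c("id", "visit_time", "marker", "time", "event"), path)
  longitudinal_cohort(d$id, d$visit_time, d$marker, d$time, d$event,
                      visit_policy = match.arg(visit_policy),
                      time_unit = time_unit)
}

#' Landmark last-value cohort
#'
#' Restricts a longitudinal cohort to subjects still at risk strictly
#' beyond the landmark `s0` that have at least one visit at or before
#' `s0`, and carries each subject's most recent marker value before the
#' landmark as a scalar baseline marker. The time axis is unchanged
#' (original scale). This is the marker construction behind landmark
#' ("last value prior to ...") analyses.
#'
#' @param lc A [longitudinal_cohort()].
#' @param landmark Landmark time `s0 > 0`.
#' @return A [baseline_cohort()] with attribute `landmark`.
#' @export
last_value_cohort <- function(lc, landmark) {
  stopifnot(inherits(lc, "longitudinal_cohort"))
  if (!is.numeric(landmark) || landmark <= 0) stop("landmark must be > 0")
  d <- lc[lc$time > landmark & lc$visit_time <= landmark, , drop = FALSE]
  if (!nrow(d))
    stop("no subject is at risk beyond the landmark with a prior visit")
  keep <- unlist(tapply(seq_len(nrow(d)), d$id, function(ix)
    ix[which.max(d$visit_time[ix])]), use.names = FALSE)
  d <- d[keep, , drop = FALSE]
  out <- baseline_cohort(d$id, d$time, d$event, d$marker,
                         time_unit = attr(lc, "time_unit") %||% "days")
  attr(out, "landmark") <- landmark
  out
}

# coerce a baseline cohort or a plain data.frame with the right columns
.as_cohort <- function(x) {
  if (inherits(x, "baseline_cohort")) return(x)
  baseline_cohort(x$id %||% seq_len(nrow(x)), x$time, x$event, x$marker)
}
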