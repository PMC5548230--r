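## Kaplan-Meier product-limit estimation and the unweighted log-rank test,
## used to compare age at risk stratification with age at diagnosis.
## Implemented directly (the closed forms are short and the tie/error
## contracts explicit); the survival package serves as an independent
## cross-check in the test suite.

#' Construct an event series
#'
#' @param times Non-negative, finite event/censoring ages (years).
#' @param events Parallel logical vector; `TRUE` = endpoint reached,
#'   `FALSE` = censored.
#' @param label Series label for reports.
#' @return Object of class `event_series`.
#' @export
event_series <- function(times, events, label = "") {
  stopifnot(length(times) == length(events), length(times) > 0)
  if (anyNA(times) || anyNA(events) || any(!is.finite(times)) ||
      any(times < 0)) {
    stop("times must be finite, non-negative and non-missing", call. = FALSE)
  }
  structure(list(times = as.numeric(times), events = as.logical(events),
                 label = as.character(label)[1]),
            class = "event_series")
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time \eqn{t_i} with \eqn{d_i} events among
#' \eqn{n_i} at risk, the survival drops by the factor
#' \eqn{(1 - d_i / n_i)}.  Ties between events and censorings at the same
#' time are resolved events-first (the censored subject is still at risk at
#' that time); censored times reduce the risk set without a step.
#'
#' @param series An [event_series()] containing at least one event.
#' @return Object of class `km_curve`: data.frame with `time` (strictly
#'   increasing distinct event times), `n_risk`, `n_event`, `survival`.
#' @export
km_estimate <- function(series) {
  stopifnot(inherits(series, "event_series"))
  if (!any(series$events)) {
    stop("no events in series", if (nzchar(series$label))
         paste0(" '", series$label, "'") else "",
         "; the product-limit estimate is undefined", call. = FALSE)
  }
  tt <- sort(unique(series$times[series$events]))
  n_risk <- vapply(tt, function(t) sum(series$times >= t), integer(1))
  n_event <- vapply(tt, function(t) sum(series$times == t & series$events),
                    integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    data.frame(time = tt, n_risk = n_risk, n_event = n_event,
               survival = surv),
    label = series$label,
    class = c("km_curve", "data.frame")
  )
}

#' Export a KM curve as a plain table
#'
#' @param curve A `km_curve`.
#' @param path Output path (CSV: time, at-risk, survival), or `NULL` to
#'   return the table.
#' @return The plain data.frame (columns `time`, `at_risk`, `survival`).
#' @export
km_table <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  out <- data.frame(time = curve$time, at_risk = curve$n_risk,
                    survival = curve$survival)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Unweighted log-rank test
#'
#' Standard two-sample log-rank chi-square on 1 degree of freedom: at each
#' pooled event time the observed events in the first series are compared
#' with their hypergeometric expectation given the pooled risk set, and the
#' standardized sum \eqn{(O - E)^2 / V} is referred to \eqn{\chi^2_1}.
#' Symmetric in its arguments and invariant to common rescaling of the
#' time axis.
#'
#' @param a,b [event_series()] objects, each containing events.
#' @return Object of class `logrank_test`: list with `statistic`,
#'   `p_value`, `observed`, `expected` (length-2 vectors, one per series).
#' @export
logrank_test <- function(a, b) {
  stopifnot(inherits(a, "event_series"), inherits(b, "event_series"))
  if (!any(a$events) || !any(b$events)) {
    stop("both series must contain events", call. = FALSE)
  }
  times <- c(a$times, b$times)
  events <- c(a$events, b$events)
  group1 <- rep(c(TRUE, FALSE), c(length(a$times), length(b$times)))
  tt <- sort(unique(times[events]))
  o1 <- e1 <- v <- 0
  for (t in tt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group1)
    d <- sum(times == t & events)
    d1 <- sum(times == t & events & group1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  d_total <- sum(events)
  structure(
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         observed = c(o1, d_total - o1),
         expected = c(e1, d_total - e1),
         labels = c(a$label, b$label)),
    class = "logrank_test"
  )
}

#' @export
print.logrank_test <- function(x, ...) {
  cat("Log-rank test (1 df)\n")
  lab <- ifelse(nzchar(x$labels), x$labels, c("series 1", "series 2"))
  for (i in 1:2) {
    cat(sprintf("  %s: observed %g, expected %.2f\n",
                lab[i], x$observed[i], x$expected[i]))
  }
  cat(sprintf("  chi-square = %.3f, p = %.3g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Age-at-stratification vs age-at-diagnosis event series
#'
#' From a cohort containing both a baseline and a follow-up visit per
#' patient, builds the two surveillance endpoints: age at Kid-SMS risk
#' stratification (the baseline age of every patient stratified at
#' moderate risk or higher) and age at Ghent-2 diagnosis (the age at the
#' earliest visit where the diagnosis holds).  Patients never reaching an
#' endpoint are censored at their age at last visit.
#'
#' @param cohort Cohort data.frame with `visit` values `"baseline"` and
#'   `"follow_up"` for the same patient ids.
#' @param sv_nomogram,pa_nomogram,threshold Dilatation resolution settings,
#'   as in [kidsms_cohort()].
#' @return List with elements `kidsms` and `ghent2`, each an
#'   [event_series()].
#' @export
endpoint_series <- function(cohort, sv_nomogram = NULL, pa_nomogram = NULL,
                            threshold = 2) {
  base <- cohort[cohort$visit == "baseline", , drop = FALSE]
  fup <- cohort[cohort$visit == "follow_up", , drop = FALSE]
  if (nrow(base) == 0 || nrow(fup) == 0) {
    stop("cohort must contain both baseline and follow_up visits",
         call. = FALSE)
  }
  fup <- fup[match(base$patient_id, fup$patient_id), , drop = FALSE]
  stopifnot(!anyNA(fup$patient_id))
  kid <- kidsms_cohort(base, sv_nomogram = sv_nomogram,
                       pa_nomogram = pa_nomogram,
                       threshold = threshold)$category >= "moderate"
  g_base <- ghent2_cohort(base, nomogram = sv_nomogram,
                          threshold = threshold)$diagnosis
  g_fup <- ghent2_cohort(fup, nomogram = sv_nomogram,
                         threshold = threshold)$diagnosis
  last_age <- fup$age_years
  kid_series <- event_series(
    ifelse(kid, base$age_years, last_age), kid,
    label = "Kid-SMS risk stratification")
  g_times <- ifelse(g_base, base$age_years,
                    ifelse(g_fup, fup$age_years, last_age))
  ghent_series <- event_series(g_times, g_base | g_fup,
                               label = "Ghent-2 diagnosis")
  list(kidsms = kid_series, ghent2 = ghent_series)
}
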