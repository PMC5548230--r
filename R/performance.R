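## Fourfold tables and diagnostic test performance with exact intervals.

#' Fourfold (2x2) table of index test vs reference standard
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true/false
#'   positives/negatives).
#' @return Object of class `fourfold`.
#' @export
fourfold <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (sum(counts) == 0) stop("fourfold table must have a positive total",
                             call. = FALSE)
  structure(as.list(as.integer(counts)), names = names(counts),
            class = "fourfold")
}

#' @export
print.fourfold <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(index = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Build a fourfold table from a cohort
#'
#' Cross-tabulates an index-test predicate against a reference-standard
#' predicate over all records.  Each predicate is either a logical vector
#' (one value per record) or a function of the cohort returning one.
#'
#' @param cohort Cohort data.frame (non-empty).
#' @param index_positive,reference_positive Predicates as above.
#' @return A [fourfold()] table.
#' @export
build_fourfold <- function(cohort, index_positive, reference_positive) {
  if (nrow(cohort) == 0) stop("empty cohort", call. = FALSE)
  as_pred <- function(p, what) {
    v <- if (is.function(p)) p(cohort) else p
    if (!is.logical(v) || length(v) != nrow(cohort) || anyNA(v)) {
      stop(what, " predicate must yield one non-missing logical per record",
           call. = FALSE)
    }
    v
  }
  idx <- as_pred(index_positive, "index")
  ref <- as_pred(reference_positive, "reference")
  fourfold(tp = sum(idx & ref), fp = sum(idx & !ref),
           fn = sum(!idx & ref), tn = sum(!idx & !ref))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta-distribution quantiles; the lower
#' bound is 0 when the numerator is 0 and the upper bound 1 when the
#' numerator equals the denominator.
#'
#' @param numerator,denominator Integers with
#'   `0 <= numerator <= denominator`, `denominator > 0`.
#' @param level Confidence level in (0, 1), default 0.95.
#' @return Object of class `prop_ci`: list with `numerator`, `denominator`,
#'   `estimate`, `ci_low`, `ci_high`, `level`.
#' @export
clopper_pearson_ci <- function(numerator, denominator, level = 0.95) {
  stopifnot(level > 0, level < 1)
  if (denominator <= 0) stop("denominator must be positive", call. = FALSE)
  stopifnot(numerator >= 0, numerator <= denominator)
  alpha <- 1 - level
  lo <- if (numerator == 0) 0
        else stats::qbeta(alpha / 2, numerator, denominator - numerator + 1)
  hi <- if (numerator == denominator) 1
        else stats::qbeta(1 - alpha / 2, numerator + 1,
                          denominator - numerator)
  structure(
    list(numerator = as.integer(numerator),
         denominator = as.integer(denominator),
         estimate = numerator / denominator,
         ci_low = lo, ci_high = hi, level = level),
    class = "prop_ci"
  )
}

#' @export
print.prop_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f (%g%% CI %.2f to %.2f)\n",
              x$numerator, x$denominator, x$estimate, 100 * x$level,
              x$ci_low, x$ci_high))
  invisible(x)
}

#' Fisher's exact test for a fourfold table
#'
#' Two-sided exact p-value by hypergeometric enumeration under the
#' probability-ordering convention: with margins fixed, the probabilities
#' of all tables no more likely than the observed one (within a relative
#' tolerance of 1e-7 for ties) are summed.  A table with an all-zero row or
#' column has a single-point support and p = 1.
#'
#' @param table A [fourfold()] table.
#' @param alternative Only `"two_sided"` (the convention used for
#'   qualitative comparisons here).
#' @return The p-value in (0, 1].
#' @export
fisher_exact <- function(table, alternative = "two_sided") {
  stopifnot(inherits(table, "fourfold"))
  alternative <- match.arg(alternative, "two_sided")
  a <- table$tp; b <- table$fp; c <- table$fn; d <- table$tn
  m <- a + c   # reference-positive margin
  n <- b + d
  k <- a + b   # index-positive margin
  support <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Diagnostic performance of an index test
#'
#' Sensitivity, specificity, PPV and NPV with exact Clopper-Pearson
#' intervals, the positive likelihood ratio
#' \eqn{LR+ = sens / (1 - spec)} (\code{Inf} when specificity is 1), and
#' the two-sided Fisher exact p-value.  A statistic whose margin is empty
#' is flagged undefined (`NULL`) rather than propagated as NaN.
#'
#' @param table A [fourfold()] table.
#' @param level Confidence level for all intervals.
#' @return Object of class `diagnostic_performance`: list with
#'   `sensitivity`, `specificity`, `ppv`, `npv` (each a [prop_ci] or
#'   `NULL` if undefined), `undefined` (character vector of flagged
#'   statistics), `positive_lr`, `fisher_p`, `table`, `level`.
#' @export
performance <- function(table, level = 0.95) {
  stopifnot(inherits(table, "fourfold"))
  prop_or_null <- function(num, den) {
    if (den == 0) NULL else clopper_pearson_ci(num, den, level)
  }
  sens <- prop_or_null(table$tp, table$tp + table$fn)
  spec <- prop_or_null(table$tn, table$fp + table$tn)
  ppv <- prop_or_null(table$tp, table$tp + table$fp)
  npv <- prop_or_null(table$tn, table$fn + table$tn)
  undefined <- c("sensitivity", "specificity", "ppv", "npv")[
    vapply(list(sens, spec, ppv, npv), is.null, logical(1))]
  lr <- if (is.null(sens) || is.null(spec)) {
    NA_real_
  } else if (spec$estimate == 1) {
    Inf
  } else {
    sens$estimate / (1 - spec$estimate)
  }
  structure(
    list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
         undefined = undefined, positive_lr = lr,
         fisher_p = fisher_exact(table), table = table, level = level),
    class = "diagnostic_performance"
  )
}

fmt_prop <- function(p) {
  if (is.null(p)) return("undefined (empty margin)")
  sprintf("%.0f%% (CI %g%% %.2f to %.2f)",
          100 * p$estimate, 100 * p$level, p$ci_low, p$ci_high)
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat("Diagnostic performance (index vs reference)\n")
  print(x$table)
  cat("  Sensitivity:", fmt_prop(x$sensitivity), "\n")
  cat("  Specificity:", fmt_prop(x$specificity), "\n")
  cat("  PPV:        ", fmt_prop(x$ppv), "\n")
  cat("  NPV:        ", fmt_prop(x$npv), "\n")
  cat("  Positive likelihood ratio:",
      if (is.na(x$positive_lr)) "undefined"
      else if (is.infinite(x$positive_lr)) "inf"
      else sprintf("%.1f", x$positive_lr), "\n")
  cat("  Fisher exact p:",
      if (x$fisher_p < 0.001) format(x$fisher_p, digits = 3)
      else sprintf("%.3f", x$fisher_p), "\n")
  invisible(x)
}

#' Flat key-value export of a performance report
#'
#' One `key=value` line per quantity (counts, estimates, CI bounds, LR,
#' Fisher p); undefined statistics are written as `NA`.  Values are
#' unrounded.
#'
#' @param perf A `diagnostic_performance`.
#' @param path Output path, or `NULL` to return the lines.
#' @return The lines, invisibly when written.
#' @export
performance_report <- function(perf, path = NULL) {
  stopifnot(inherits(perf, "diagnostic_performance"))
  kv <- c(tp = perf$table$tp, fp = perf$table$fp,
          fn = perf$table$fn, tn = perf$table$tn)
  for (nm in c("sensitivity", "specificity", "ppv", "npv")) {
    p <- perf[[nm]]
    kv[[nm]] <- if (is.null(p)) NA else p$estimate
    kv[[paste0(nm, "_ci_low")]] <- if (is.null(p)) NA else p$ci_low
    kv[[paste0(nm, "_ci_high")]] <- if (is.null(p)) NA else p$ci_high
  }
  kv[["positive_lr"]] <- perf$positive_lr
  kv[["fisher_p"]] <- perf$fisher_p
  kv[["ci_level"]] <- perf$level
  lines <- paste0(names(kv), "=",
                  vapply(kv, function(v) {
                    if (is.na(v)) "NA"
                    else format(v, digits = 15, scientific = FALSE)
                  }, character(1)))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Unpaired t test on a quantitative cohort summary
#'
#' Thin convenience wrapper around [stats::t.test()] (classical unpaired
#' Student test, equal variances) for comparing quantitative measures
#' between two groups of records, provided for parity with routine cohort
#' reporting.  Not part of the scoring engines.
#'
#' @param x,y Numeric vectors.
#' @return An `htest` object.
#' @export
cohort_t_test <- function(x, y) {
  stats::t.test(x, y, var.equal = TRUE)
}
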