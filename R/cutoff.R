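# Dichotomization of continuous densities: median split (the unbiased
# first-pass rule), ROC/Youden exploration of alternative cut-offs, and
# distribution-shape diagnostics.

.new_cutoff_result <- function(variable, cutoff_value, rule, labels,
                               skewness = NA_real_,
                               excess_kurtosis = NA_real_,
                               roc_auc = NA_real_, extra = list()) {
  structure(
    c(list(variable = variable, cutoff_value = cutoff_value, rule = rule,
           labels = labels,
           n_high = sum(labels == "high", na.rm = TRUE),
           n_low = sum(labels == "low", na.rm = TRUE),
           skewness = skewness, excess_kurtosis = excess_kurtosis,
           roc_auc = roc_auc),
      extra),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cutoff for %s (rule: %s)\n", x$variable, x$rule))
  cat(sprintf("  cutoff = %.6g; high %d / low %d\n",
              x$cutoff_value, x$n_high, x$n_low))
  if (is.finite(x$skewness)) {
    cat(sprintf("  skewness = %.3f, excess kurtosis = %.3f\n",
                x$skewness, x$excess_kurtosis))
  }
  if (is.finite(x$roc_auc)) cat(sprintf("  ROC AUC = %.3f\n", x$roc_auc))
  invisible(x)
}

#' Sample-size-adjusted skewness and excess kurtosis
#'
#' The small-sample-corrected moment estimators (type 2 in the
#' classification of Joanes & Gill), i.e. the values SPSS and SAS report by
#' default.
#'
#' @param values Numeric vector with at least 4 non-missing values (the
#'   adjusted kurtosis is undefined below that).
#' @return Named numeric vector `c(skewness = , excess_kurtosis = )`.
#' @examples
#' shape_stats(c(0, 0, 0, 1)) # skewness 2 under the adjusted formula
#' @export
shape_stats <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 4) {
    stop("need at least 4 non-missing values for adjusted shape statistics")
  }
  c(skewness = e1071::skewness(v, type = 2),
    excess_kurtosis = e1071::kurtosis(v, type = 2))
}

#' Median dichotomization of a continuous variable
#'
#' Labels each value `high` iff it is strictly greater than the sample
#' median; ties at the median are labeled `low`. With all-distinct values
#' and even n this yields an exact 50/50 split.
#'
#' @param values Numeric vector (NA allowed; NA values get NA labels and
#'   are excluded from the counts).
#' @param variable Name used in reports.
#' @return A `cutoff_result` with `cutoff_value` (the median), per-value
#'   `labels` (factor `low`/`high`), counts, and shape diagnostics.
#' @export
median_dichotomize <- function(values, variable = "value") {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("need at least 2 non-missing values")
  if (max(v) == min(v)) {
    stop("all values identical: no median split possible")
  }
  m <- stats::median(v)
  labels <- factor(ifelse(values > m, "high", "low"),
                   levels = c("low", "high"))
  sh <- if (length(v) >= 4) shape_stats(v) else
    c(skewness = NA_real_, excess_kurtosis = NA_real_)
  .new_cutoff_result(variable, m, "median", labels,
                     skewness = unname(sh[1]),
                     excess_kurtosis = unname(sh[2]))
}

# J = sensitivity + specificity - 1 for the rule "positive iff value > cut".
.youden_at <- function(values, outcome, cut) {
  sens <- mean(values[outcome] > cut)
  spec <- mean(values[!outcome] <= cut)
  sens + spec - 1
}

#' ROC-based optimal cut-off (Youden's J)
#'
#' Computes the empirical ROC curve of a continuous variable against a
#' binary outcome, reports the AUC, and proposes the cut-off maximizing
#' Youden's J (sensitivity + specificity - 1). The result also states
#' whether the candidate improves J over the median split by more than
#' `margin`, mirroring the check that a median cut-off is already adequate.
#'
#' @param values Numeric vector.
#' @param outcome Logical (or coercible) vector, `TRUE` = case; both
#'   classes must be present.
#' @param variable Name used in reports.
#' @param margin Minimum J improvement over the median split to declare the
#'   ROC cut-off better (default 0.05).
#' @return A `cutoff_result` (rule `"roc_youden"`) with `roc_auc`,
#'   `j_best`, `j_median`, `improves_over_median`, and labels from the
#'   candidate cut-off.
#' @export
roc_optimal_cutoff <- function(values, outcome, variable = "value",
                               margin = 0.05) {
  outcome <- as.logical(outcome)
  keep <- !is.na(values) & !is.na(outcome)
  v <- values[keep]
  y <- outcome[keep]
  if (length(unique(y)) < 2) {
    stop("outcome must contain both classes")
  }
  r <- pROC::roc(response = y, predictor = v, direction = "<",
                 levels = c(FALSE, TRUE), quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  co <- pROC::coords(r, x = "all", ret = c("threshold", "sensitivity",
                                           "specificity"),
                     transpose = FALSE)
  j <- co$sensitivity + co$specificity - 1
  finite <- is.finite(co$threshold)
  best_i <- which(finite)[which.max(j[finite])]
  cut <- co$threshold[best_i]
  j_best <- j[best_i]
  j_med <- .youden_at(v, y, stats::median(v))
  labels <- factor(ifelse(values > cut, "high", "low"),
                   levels = c("low", "high"))
  sh <- if (length(v) >= 4) shape_stats(v) else
    c(skewness = NA_real_, excess_kurtosis = NA_real_)
  .new_cutoff_result(
    variable, cut, "roc_youden", labels,
    skewness = unname(sh[1]), excess_kurtosis = unname(sh[2]),
    roc_auc = auc,
    extra = list(j_best = j_best, j_median = j_med,
                 improves_over_median = (j_best - j_med) > margin,
                 margin = margin)
  )
}
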