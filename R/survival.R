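# Overall-survival analysis: Kaplan-Meier curves and the two-group
# log-rank test (survival package behind the module surface).

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimate of overall survival, one curve per group.
#' Censored times reduce the risk set without a step; at tied times events
#' are handled before censorings, as in the standard estimator.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Logical; `TRUE` = death observed, `FALSE` = censored.
#' @param group Optional grouping vector (default: one pooled group).
#' @return A tibble with `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (one row per distinct observed time, survival evaluated just
#'   after that time).
#' @export
km_estimate <- function(times, events, group = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0))
  if (is.null(group)) group <- rep("all", length(times))
  if (length(group) != length(times)) stop("group length mismatch")
  if (any(table(group) == 0) || length(times) == 0) {
    stop("each group must contain at least one subject")
  }
  events <- as.logical(events)
  g <- factor(group)
  out <- lapply(levels(g), function(lev) {
    sel <- g == lev
    sf <- survival::survfit(
      survival::Surv(times[sel], events[sel]) ~ 1, conf.type = "none")
    tibble::tibble(group = lev, time = sf$time, n_risk = sf$n.risk,
                   n_event = sf$n.event, n_censor = sf$n.censor,
                   surv = sf$surv)
  })
  dplyr::bind_rows(out)
}

#' Two-group (or k-group) log-rank test
#'
#' Observed-minus-expected events summed over event times with the
#' hypergeometric variance; p from the upper tail of chi-squared with
#' (k - 1) df.
#'
#' @inheritParams km_estimate
#' @param group Grouping vector with at least 2 non-empty groups.
#' @return List with `statistic`, `df`, `p`, and `p_formatted` (values
#'   below 1e-4 rendered as `"<0.0001"`, the customary reporting style).
#' @export
logrank_test <- function(times, events, group) {
  stopifnot(length(times) == length(events),
            length(group) == length(times))
  g <- factor(group)
  if (nlevels(g) < 2) stop("log-rank test needs at least 2 groups")
  sd <- survival::survdiff(
    survival::Surv(times, as.logical(events)) ~ g, rho = 0)
  df <- nlevels(g) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  list(statistic = unname(sd$chisq), df = df, p = p,
       p_formatted = if (p < 1e-4) "<0.0001" else sprintf("%.4f", p))
}
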