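# Relapse-risk association statistics: 2x2 odds ratio with Woolf CI,
# Pearson chi-square (uncorrected), Fisher's exact test, and logistic
# regression with separation detection.

#' Cross-tabulate a dichotomized exposure against a binary outcome
#'
#' Builds the 2x2 table with rows = exposure (`low`, `high`) and columns =
#' outcome (`FALSE`, `TRUE`), the layout used throughout the association
#' functions.
#'
#' @param exposure Factor with levels `low`, `high` (e.g. the labels of a
#'   [median_dichotomize()] result), or any 2-level factor.
#' @param outcome Logical vector.
#' @return A 2x2 integer matrix.
#' @export
cross_tab <- function(exposure, outcome) {
  keep <- !is.na(exposure) & !is.na(outcome)
  tab <- table(exposure = exposure[keep],
               outcome = factor(as.logical(outcome[keep]),
                                levels = c(FALSE, TRUE)))
  if (!all(dim(tab) == c(2, 2))) stop("exposure must have exactly 2 levels")
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  m
}

.check_2x2 <- function(tab) {
  if (!is.matrix(tab) || !all(dim(tab) == c(2, 2))) {
    stop("expected a 2x2 matrix")
  }
  if (any(tab < 0) || any(tab != round(tab)) || sum(tab) == 0) {
    stop("counts must be non-negative integers with a positive total")
  }
  invisible(tab)
}

#' Odds ratio with Woolf confidence interval
#'
#' Cross-product odds ratio of a 2x2 table (rows = exposure low/high,
#' columns = outcome no/yes):
#' `OR = (high & yes) * (low & no) / ((high & no) * (low & yes))`, with the
#' Woolf 95% CI `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If
#' any cell is zero the Haldane-Anscombe correction (+0.5 to every cell) is
#' applied and `method` is set to `"haldane_corrected"`.
#'
#' @param tab 2x2 matrix of counts (see [cross_tab()]).
#' @return A list of class `or_result`: `or`, `ci_low`, `ci_high`,
#'   `log_or_se`, `method`.
#' @examples
#' odds_ratio(matrix(c(124, 118, 2, 14), 2, 2)) # OR 7.36 (1.64-33.06)
#' @export
odds_ratio <- function(tab) {
  .check_2x2(tab)
  if ((tab[1, 1] == 0 && tab[1, 2] == 0) ||
      (tab[2, 1] == 0 && tab[2, 2] == 0) ||
      (tab[1, 1] == 0 && tab[2, 1] == 0) ||
      (tab[1, 2] == 0 && tab[2, 2] == 0)) {
    stop("odds ratio undefined: a full row or column of the table is zero")
  }
  method <- "woolf"
  if (any(tab == 0)) {
    tab <- tab + 0.5
    method <- "haldane_corrected"
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(
    list(or = or,
         ci_low = exp(log(or) - 1.96 * se),
         ci_high = exp(log(or) + 1.96 * se),
         log_or_se = se,
         method = method),
    class = "or_result"
  )
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), log-OR SE %.4f [%s]\n",
              x$or, x$ci_low, x$ci_high, x$log_or_se, x$method))
  invisible(x)
}

#' Pearson chi-square test of a 2x2 table (no continuity correction)
#'
#' @param tab 2x2 matrix of counts; all four marginals must be positive.
#' @return List with `statistic` (1 df) and `p`.
#' @export
pearson_chi2 <- function(tab) {
  .check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("chi-square undefined: zero marginal")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value))
}

#' Fisher's exact test (two-sided, minimum-likelihood rule)
#'
#' Conditional on both margins, sums the hypergeometric probabilities of
#' every admissible table whose probability does not exceed that of the
#' observed table (with the customary `1 + 1e-7` relative tolerance for
#' floating-point ties) -- the same two-sided convention as
#' `stats::fisher.test`.
#'
#' @param tab 2x2 matrix of counts.
#' @return Two-sided p-value. A table with a zero margin has p = 1.
#' @export
fisher_exact <- function(tab) {
  .check_2x2(tab)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  d <- stats::dhyper(support, r1, r2, c1)
  d_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  min(sum(d[d <= d_obs * (1 + 1e-7)]), 1)
}

#' Logistic regression with Wald intervals and separation detection
#'
#' Binomial GLM fitted by iteratively reweighted least squares
#' (`stats::glm`). Categorical covariates are expanded to indicators
#' against their first factor level. Coefficients with `|estimate| > 10`
#' and `SE > 50` are flagged as (quasi-)separated and their odds ratio and
#' CI reported as undefined (`NA`) while the Wald p is retained --
#' mirroring how saturated stage levels print as "-" in clinical reports.
#' All-constant covariate columns are dropped with a note.
#'
#' @param outcome Logical (or 0/1) response.
#' @param design Data frame of covariates (numeric or factor); may be
#'   `NULL`/empty for an intercept-only model.
#' @param max_iter,tol IRLS control (`glm` maxit / epsilon).
#' @return A list of class `logistic_fit`: `coefficients` tibble (`term`,
#'   `estimate`, `se`, `or`, `ci_low`, `ci_high`, `p`, `separation`),
#'   `loglik`, `converged`, `n`, and the underlying `glm` object as `fit`.
#' @export
logistic_fit <- function(outcome, design = NULL, max_iter = 100L,
                         tol = 1e-10) {
  y <- as.logical(outcome)
  if (is.null(design) || ncol(as.data.frame(design)) == 0) {
    df <- data.frame(.y = y)
  } else {
    design <- as.data.frame(design)
    constant <- vapply(design, function(col) {
      length(unique(col[!is.na(col)])) < 2
    }, logical(1))
    if (any(constant)) {
      message("dropping constant covariate(s): ",
              paste(names(design)[constant], collapse = ", "))
      design <- design[, !constant, drop = FALSE]
    }
    df <- data.frame(.y = y, design)
  }
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (length(unique(df$.y)) < 2) stop("outcome must contain both classes")
  fit <- suppressWarnings(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol,
                                            maxit = max_iter))
  )
  sm <- summary(fit)$coefficients
  est <- sm[, 1]
  se <- sm[, 2]
  sep <- abs(est) > 10 & se > 50
  or <- exp(est)
  ci_low <- exp(est - 1.96 * se)
  ci_high <- exp(est + 1.96 * se)
  p <- 2 * stats::pnorm(-abs(est / se))
  or[sep] <- NA_real_
  ci_low[sep] <- NA_real_
  ci_high[sep] <- NA_real_
  structure(
    list(coefficients = tibble::tibble(
           term = rownames(sm), estimate = unname(est), se = unname(se),
           or = unname(or), ci_low = unname(ci_low),
           ci_high = unname(ci_high), p = unname(p),
           separation = unname(sep)),
         loglik = as.numeric(stats::logLik(fit)),
         converged = fit$converged,
         n = nrow(df),
         fit = fit),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, loglik = %.3f%s\n", x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(x$coefficients)
  invisible(x)
}

# One univariate (or multivariate) fit summarized as report rows.
.fit_rows <- function(outcome, design, model, outcome_name) {
  f <- logistic_fit(outcome, design)
  co <- f$coefficients[f$coefficients$term != "(Intercept)", ]
  tibble::tibble(outcome = outcome_name, model = model, term = co$term,
                 or = co$or, ci_low = co$ci_low, ci_high = co$ci_high,
                 p = co$p, separation = co$separation, n = f$n)
}

#' Univariate and multivariate relapse-risk screens
#'
#' Runs the univariate logistic battery -- each dichotomized density
#' variable plus age (continuous), sex, histology (adenocarcinoma vs
#' rest), stage (reference IA) and, when a `ps` column is present,
#' performance status -- against three outcomes (any relapse, CNS relapse
#' vs all others, non-CNS relapse vs all others), then a multivariate
#' model for CNS relapse combining the primary density variable with age,
#' histology and stage.
#'
#' Density medians are computed over all patients with density data;
#' associations use the patients with a known relapse site.
#'
#' @param densities Output of [compute_densities()].
#' @param clinical Clinical table with `patient_id`, `age`, `sex`,
#'   `histology`, `stage`, `relapse_site` (`NA` = unknown).
#' @param density_vars Density columns to screen (default: the NRF2 and
#'   TrxR1 double-positive densities in all three compartments).
#' @param primary Density variable entering the multivariate model.
#' @return A list of class `relapse_report` with tibbles `univariate` and
#'   `multivariate` (per-term OR, 95% CI, Wald p, separation flag) and the
#'   per-variable `cutoffs` used.
#' @export
relapse_screens <- function(densities, clinical,
                            density_vars = c("nrf2_ck_density_whole",
                                             "nrf2_ck_density_tumor",
                                             "nrf2_ck_density_stroma",
                                             "trxr1_ck_density_whole",
                                             "trxr1_ck_density_tumor",
                                             "trxr1_ck_density_stroma"),
                            primary = "nrf2_ck_density_whole") {
  density_vars <- intersect(density_vars, names(densities))
  if (!primary %in% density_vars) {
    stop("primary density variable not present: ", primary)
  }
  cutoffs <- lapply(density_vars, function(v) {
    median_dichotomize(densities[[v]], variable = v)
  })
  names(cutoffs) <- density_vars
  lab <- densities["patient_id"]
  for (v in density_vars) lab[[paste0(v, "_group")]] <- cutoffs[[v]]$labels

  cl <- dplyr::inner_join(clinical, lab, by = "patient_id")
  cl <- cl[!is.na(cl$relapse_site), ]
  cl$stage <- factor(cl$stage, levels = c("IA", "IB", "IIA", "IIB",
                                          "IIIA", "IIIB"))
  cl$sex <- factor(cl$sex, levels = c("male", "female"))
  cl$adeno <- factor(ifelse(cl$histology == "adenocarcinoma",
                            "adenocarcinoma", "rest"),
                     levels = c("rest", "adenocarcinoma"))
  outcomes <- list(
    any_relapse = cl$relapse_site != "none",
    cns_relapse = cl$relapse_site == "CNS",
    other_relapse = !cl$relapse_site %in% c("none", "CNS")
  )
  uni_vars <- c(stats::setNames(paste0(density_vars, "_group"), density_vars),
                age = "age", sex = "sex", histology = "adeno",
                stage = "stage")
  if ("ps" %in% names(cl)) uni_vars <- c(uni_vars, ps = "ps")

  uni <- dplyr::bind_rows(lapply(names(outcomes), function(on) {
    dplyr::bind_rows(lapply(names(uni_vars), function(vn) {
      d <- cl[, uni_vars[[vn]], drop = FALSE]
      names(d) <- vn
      .fit_rows(outcomes[[on]], d, "univariate", on)
    }))
  }))

  mv_design <- cl[, c(paste0(primary, "_group"), "age", "adeno", "stage")]
  names(mv_design)[1] <- primary
  names(mv_design)[3] <- "histology"
  mv <- .fit_rows(outcomes$cns_relapse, mv_design, "multivariate",
                  "cns_relapse")

  structure(list(univariate = uni, multivariate = mv, cutoffs = cutoffs),
            class = "relapse_report")
}

#' @export
print.relapse_report <- function(x, ...) {
  cat("Univariate screens:\n")
  print(x$univariate, n = Inf)
  cat("\nMultivariate model (CNS relapse):\n")
  print(x$multivariate, n = Inf)
  invisible(x)
}
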