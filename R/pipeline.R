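# End-to-end orchestration: simulate or ingest -> mixture thresholds ->
# classification -> densities -> cutoffs -> associations -> survival ->
# summary bundle.

#' Build a pipeline configuration
#'
#' @param simulate Either `NULL` (read CSV inputs from `input_dir`) or a
#'   list describing the synthetic cohort: `preset = "paperlike"` with
#'   optional `scale`, or `config = sim_config(...)`.
#' @param input_dir Directory with `cells.csv`, `areas.csv`,
#'   `clinical.csv` (used when `simulate` is `NULL`).
#' @param markers Signal markers to analyze (besides the CK gate).
#' @param cutoff_rule `"median"` or `"roc_youden"` for the dichotomization
#'   feeding the association stage.
#' @param fit_subsample Maximum number of cells used to fit each pooled
#'   marker mixture (`Inf` = all cells); classification always uses all
#'   cells. Subsampling is seeded and only matters at very large scale.
#' @param out_dir Output directory for the report bundle (`NULL` = don't
#'   write, return results only).
#' @param seed Integer seed for every stochastic stage.
#' @param log Print per-stage progress lines?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = list(preset = "paperlike", scale = 1),
                            input_dir = NULL,
                            markers = c("NRF2", "TrxR1"),
                            cutoff_rule = c("median", "roc_youden"),
                            fit_subsample = Inf,
                            out_dir = NULL,
                            seed = 1L,
                            log = TRUE) {
  cutoff_rule <- match.arg(cutoff_rule)
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either `simulate` or `input_dir` must be given")
  }
  structure(list(schema_version = 1L, simulate = simulate,
                 input_dir = input_dir, markers = markers,
                 cutoff_rule = cutoff_rule, fit_subsample = fit_subsample,
                 out_dir = out_dir, seed = as.integer(seed), log = log),
            class = "pipeline_config")
}

.stage_log <- function(enabled, stage, fmt, ...) {
  if (enabled) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
}

.validate_inputs <- function(cohort, markers) {
  problems <- character(0)
  need <- c("patient_id", "core_id", "compartment",
            paste0("intensity_", c("CK", markers)))
  miss <- setdiff(need, names(cohort$cells))
  if (length(miss)) {
    problems <- c(problems, paste("cells table missing columns:",
                                  paste(miss, collapse = ", ")))
  }
  miss <- setdiff(c("patient_id", "core_id", "compartment", "area_mm2"),
                  names(cohort$areas))
  if (length(miss)) {
    problems <- c(problems, paste("area table missing columns:",
                                  paste(miss, collapse = ", ")))
  }
  miss <- setdiff(c("patient_id", "age", "sex", "histology", "stage",
                    "relapse_site", "os_months", "os_event"),
                  names(cohort$clinical))
  if (length(miss)) {
    problems <- c(problems, paste("clinical table missing columns:",
                                  paste(miss, collapse = ", ")))
  }
  if (length(problems)) {
    stop("invalid pipeline inputs:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
}

#' Run the full quantification-and-association pipeline
#'
#' Sequences all stages: cohort simulation (or CSV ingestion), pooled
#' mixture fitting and thresholding per marker, cell classification,
#' per-patient compartment densities, median/ROC cutoffs with shape
#' diagnostics, the 2x2 association statistics (odds ratio with Woolf CI,
#' chi-square, Fisher exact) for the primary density variable vs CNS
#' relapse, the univariate/multivariate logistic screens, and the overall
#' survival comparison of CNS-relapse patients against everyone else.
#' Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with elements `fits`,
#'   `densities`, `cutoffs`, `contingency`, `association`, `screens`,
#'   `survival`, `summary` (the content of the summary JSON). When
#'   `config$out_dir` is set, every intermediate artifact is also written
#'   there (CSV for tables, JSON for fits/tests) plus `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- isTRUE(config$log)
  set.seed(config$seed)

  t0 <- Sys.time()
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cohort <- if (!is.null(sim$preset)) {
      if (!identical(sim$preset, "paperlike")) {
        stop("unknown simulate preset: ", sim$preset)
      }
      paperlike_cohort(seed = config$seed,
                       scale = if (is.null(sim$scale)) 1L else sim$scale)
    } else {
      generate_cohort(sim$config)
    }
    .stage_log(log, "simulate", "%d cells / %d patients",
               nrow(cohort$cells), nrow(cohort$clinical))
  } else {
    cohort <- read_cohort(config$input_dir)
    .stage_log(log, "ingest", "%d cells / %d patients from %s",
               nrow(cohort$cells), nrow(cohort$clinical), config$input_dir)
  }
  .validate_inputs(cohort, config$markers)

  all_markers <- c("CK", config$markers)
  n_cells <- nrow(cohort$cells)
  fit_idx <- if (is.finite(config$fit_subsample) &&
                 config$fit_subsample < n_cells) {
    sample(n_cells, config$fit_subsample)
  } else {
    seq_len(n_cells)
  }
  fits <- lapply(all_markers, function(mk) {
    x <- cohort$cells[[paste0("intensity_", mk)]]
    fit <- fit_mixture(x[fit_idx])
    .stage_log(log, "threshold", "%s: threshold %.4g (pi_noise %.3f, %s)",
               mk, fit$threshold, fit$pi_noise,
               if (fit$converged) "converged" else "not converged")
    fit
  })
  names(fits) <- all_markers

  classified <- cohort$cells[, c("patient_id", "core_id", "cell_id",
                                 "compartment")]
  for (mk in all_markers) {
    classified[[paste0("pos_", mk)]] <-
      classify_cells(cohort$cells[[paste0("intensity_", mk)]],
                     fits[[mk]]$threshold)
  }

  densities <- compute_densities(classified, cohort$areas)
  .stage_log(log, "densities", "%d patients x %d columns",
             nrow(densities), ncol(densities))

  density_vars <- intersect(
    as.vector(outer(paste0(tolower(config$markers), "_ck_density_"),
                    c("whole", "tumor", "stroma"), paste0)),
    names(densities))
  primary <- density_vars[1]

  clin <- cohort$clinical
  merged <- dplyr::inner_join(densities, clin, by = "patient_id")
  cns <- ifelse(is.na(merged$relapse_site), NA,
                merged$relapse_site == "CNS")

  cutoffs <- lapply(density_vars, function(v) {
    if (config$cutoff_rule == "median") {
      median_dichotomize(merged[[v]], variable = v)
    } else {
      roc_optimal_cutoff(merged[[v]], cns, variable = v)
    }
  })
  names(cutoffs) <- density_vars
  # ROC exploration of the primary variable is always reported
  roc_primary <- roc_optimal_cutoff(merged[[primary]], cns,
                                    variable = primary)
  .stage_log(log, "cutoff", "%s: %s cutoff %.4g (high %d / low %d)",
             primary, config$cutoff_rule,
             cutoffs[[primary]]$cutoff_value,
             cutoffs[[primary]]$n_high, cutoffs[[primary]]$n_low)

  tab <- cross_tab(cutoffs[[primary]]$labels, cns)
  contingency <- list(
    table = tab,
    odds_ratio = odds_ratio(tab),
    chi2 = pearson_chi2(tab),
    fisher_p = fisher_exact(tab)
  )
  .stage_log(log, "associate", "%s vs CNS relapse: OR %.2f (%.2f-%.2f)",
             primary, contingency$odds_ratio$or,
             contingency$odds_ratio$ci_low, contingency$odds_ratio$ci_high)

  screens <- relapse_screens(densities, clin, density_vars = density_vars,
                             primary = primary)

  complete <- !is.na(clin$relapse_site)
  surv_group <- ifelse(clin$relapse_site[complete] == "CNS",
                       "CNS relapse", "no CNS relapse")
  km <- km_estimate(clin$os_months[complete], clin$os_event[complete],
                    surv_group)
  lr <- logrank_test(clin$os_months[complete], clin$os_event[complete],
                     surv_group)
  .stage_log(log, "survival", "log-rank p %s", lr$p_formatted)

  summary <- list(
    schema_version = config$schema_version,
    seed = config$seed,
    n_patients = nrow(clin),
    n_patients_outcome_complete = sum(complete),
    n_cells = n_cells,
    thresholds = lapply(fits, function(f) {
      f[c("pi_noise", "chi2_df", "chi2_scale", "mu_pos", "sigma_pos",
          "threshold", "converged")]
    }),
    primary_variable = primary,
    cutoff_rule = config$cutoff_rule,
    primary_cutoff = cutoffs[[primary]]$cutoff_value,
    primary_shape = list(skewness = cutoffs[[primary]]$skewness,
                         excess_kurtosis = cutoffs[[primary]]$excess_kurtosis),
    roc = list(auc = roc_primary$roc_auc,
               improves_over_median = roc_primary$improves_over_median),
    contingency = list(counts = as.vector(contingency$table),
                       or = contingency$odds_ratio$or,
                       ci_low = contingency$odds_ratio$ci_low,
                       ci_high = contingency$odds_ratio$ci_high,
                       chi2_p = contingency$chi2$p,
                       fisher_p = contingency$fisher_p),
    multivariate = as.list(
      screens$multivariate[grepl("density", screens$multivariate$term),
                           c("or", "ci_low", "ci_high", "p")]),
    logrank = lr[c("statistic", "p", "p_formatted")]
  )
  .stage_log(log, "done", "total %.1fs",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- structure(
    list(fits = fits, classified = classified, densities = densities,
         cutoffs = cutoffs, roc_primary = roc_primary,
         contingency = contingency, screens = screens,
         survival = list(km = km, logrank = lr),
         summary = summary, config = config),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline(result, config$out_dir)
  result
}

#' Write a pipeline report bundle
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jw <- function(x, f) {
    jsonlite::write_json(x, file.path(dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  for (mk in names(result$fits)) {
    f <- result$fits[[mk]]
    jw(f[c("pi_noise", "chi2_df", "chi2_scale", "mu_pos", "sigma_pos",
           "threshold", "threshold_fallback", "loglik", "n_iter",
           "converged", "n")],
       sprintf("fit_%s.json", mk))
  }
  readr::write_csv(result$classified, file.path(dir, "classified_cells.csv"))
  readr::write_csv(result$densities, file.path(dir, "densities.csv"))
  jw(lapply(result$cutoffs, function(co) {
    co[c("variable", "cutoff_value", "rule", "n_high", "n_low",
         "skewness", "excess_kurtosis")]
  }), "cutoffs.json")
  readr::write_csv(result$screens$univariate,
                   file.path(dir, "association_univariate.csv"))
  readr::write_csv(result$screens$multivariate,
                   file.path(dir, "association_multivariate.csv"))
  jw(result$summary$contingency, "contingency.json")
  readr::write_csv(result$survival$km, file.path(dir, "survival_km.csv"))
  jw(result$survival$logrank, "survival_test.json")
  jw(result$summary, "summary.json")
  invisible(dir)
}
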