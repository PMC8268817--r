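# Synthetic multiplex-IF cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: TMA
# patients with duplicate 1-mm cores, per-cell marker intensities drawn from
# a scaled chi-squared noise component plus a (0-truncated) normal positive
# component, tumor/stroma compartment labels, and a binary CNS-relapse
# outcome generated by a logistic link to the true double-positive density.

.sim_marker_defaults <- function() {
  list(pi_pos = 0.3, pi_pos_logit_sd = 0, chi2_df = 2, chi2_scale = 1,
       mu_pos = 8, sigma_pos = 1.5)
}

.check_range <- function(value, field, lo = -Inf, hi = Inf,
                         open_lo = FALSE, open_hi = FALSE) {
  ok <- length(value) >= 1 && all(is.finite(value)) &&
    all(if (open_lo) value > lo else value >= lo) &&
    all(if (open_hi) value < hi else value <= hi)
  if (!ok) {
    stop("invalid SimConfig field `", field, "`: must be finite in ",
         if (open_lo) "(" else "[", lo, ", ", hi,
         if (open_hi) ")" else "]", call. = FALSE)
  }
  invisible(value)
}

#' Build a synthetic-cohort configuration
#'
#' @param n_patients Number of patients.
#' @param cores_per_patient Tissue cores per patient (duplicate 1-mm cores
#'   by default).
#' @param cells_per_core_mean Mean of the Poisson per-core cell count.
#' @param tumor_area_fraction Expected fraction of core area classified as
#'   tumor epithelium, in (0, 1).
#' @param area_fraction_conc Beta concentration of the per-core tumor-area
#'   fraction around `tumor_area_fraction`.
#' @param core_area_mm2 Nominal area of one core (a 1-mm-diameter disc by
#'   default, `pi / 4` mm^2).
#' @param evaluable_fraction Length-2 range; each core's evaluable
#'   (tumor + stroma) area is `core_area_mm2` times a uniform draw from
#'   this range, reflecting per-core exclusion of blank or necrotic area.
#' @param markers Named list of per-marker mixture parameters; each entry
#'   may override `pi_pos`, `pi_pos_logit_sd` (between-patient SD of the
#'   positive fraction on the logit scale; 0 means all patients share
#'   `pi_pos`), `chi2_df`, `chi2_scale`, `mu_pos`, `sigma_pos`.
#' @param relapse List with `baseline_logit` and `beta_density`: per
#'   patient, CNS relapse is drawn with probability
#'   `plogis(baseline_logit + beta_density * true double-positive density)`
#'   where the density (cells/mm^2) uses the true generating labels of the
#'   first two markers (gate, then signal marker).
#' @param relapse_marker Marker whose double-positive density drives
#'   relapse (default `"NRF2"`); the gate marker is `"CK"`.
#' @param nonCNS_relapse_probs Named probabilities of the non-CNS relapse
#'   sites, conditional on not relapsing in the CNS.
#' @param os List with `median_months` (named: `cns`, `other`) for the
#'   exponential survival times and `censor_range_months` for the uniform
#'   censoring window.
#' @param n_missing_relapse Number of patients (drawn completely at random)
#'   whose relapse site is set to missing.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 304L,
                       cores_per_patient = 2L,
                       cells_per_core_mean = 200,
                       tumor_area_fraction = 0.55,
                       area_fraction_conc = 60,
                       core_area_mm2 = pi / 4,
                       evaluable_fraction = c(0.8, 1),
                       markers = list(CK = list(pi_pos = 0.6),
                                      NRF2 = list(),
                                      TrxR1 = list()),
                       relapse = list(baseline_logit = -4, beta_density = 0),
                       relapse_marker = "NRF2",
                       nonCNS_relapse_probs = c(none = 146, thoracic = 59,
                                                bone = 12, liver = 5,
                                                adrenal = 1, multiple = 19) / 242,
                       os = list(median_months = c(cns = 12, other = 60),
                                 censor_range_months = c(36, 118)),
                       n_missing_relapse = 0L,
                       seed = 1L) {
  .check_range(n_patients, "n_patients", 1)
  .check_range(cores_per_patient, "cores_per_patient", 1)
  .check_range(cells_per_core_mean, "cells_per_core_mean", 1)
  .check_range(tumor_area_fraction, "tumor_area_fraction", 0, 1,
               open_lo = TRUE, open_hi = TRUE)
  .check_range(area_fraction_conc, "area_fraction_conc", 0, open_lo = TRUE)
  .check_range(core_area_mm2, "core_area_mm2", 0, open_lo = TRUE)
  .check_range(evaluable_fraction, "evaluable_fraction", 0, 1, open_lo = TRUE)
  if (length(evaluable_fraction) != 2 ||
      evaluable_fraction[1] > evaluable_fraction[2]) {
    stop("invalid SimConfig field `evaluable_fraction`: need an increasing length-2 range")
  }
  mk <- lapply(markers, function(m) utils::modifyList(.sim_marker_defaults(), m))
  for (nm in names(mk)) {
    m <- mk[[nm]]
    .check_range(m$pi_pos, paste0("markers$", nm, "$pi_pos"), 0, 1)
    .check_range(m$pi_pos_logit_sd, paste0("markers$", nm, "$pi_pos_logit_sd"), 0)
    .check_range(m$chi2_df, paste0("markers$", nm, "$chi2_df"), 0, open_lo = TRUE)
    .check_range(m$chi2_scale, paste0("markers$", nm, "$chi2_scale"), 0, open_lo = TRUE)
    .check_range(m$sigma_pos, paste0("markers$", nm, "$sigma_pos"), 0, open_lo = TRUE)
    .check_range(m$mu_pos, paste0("markers$", nm, "$mu_pos"), 0)
  }
  if (!"CK" %in% names(mk)) stop("invalid SimConfig field `markers`: a 'CK' gate marker is required")
  if (!relapse_marker %in% names(mk)) {
    stop("invalid SimConfig field `relapse_marker`: not among markers")
  }
  .check_range(relapse$baseline_logit, "relapse$baseline_logit")
  .check_range(relapse$beta_density, "relapse$beta_density")
  .check_range(os$median_months, "os$median_months", 0, open_lo = TRUE)
  .check_range(n_missing_relapse, "n_missing_relapse", 0, n_patients)
  if (abs(sum(nonCNS_relapse_probs) - 1) > 1e-8) {
    stop("invalid SimConfig field `nonCNS_relapse_probs`: must sum to 1")
  }
  .check_range(seed, "seed")
  structure(
    list(n_patients = as.integer(n_patients),
         cores_per_patient = as.integer(cores_per_patient),
         cells_per_core_mean = cells_per_core_mean,
         tumor_area_fraction = tumor_area_fraction,
         area_fraction_conc = area_fraction_conc,
         core_area_mm2 = core_area_mm2,
         evaluable_fraction = evaluable_fraction,
         markers = mk,
         relapse = relapse,
         relapse_marker = relapse_marker,
         nonCNS_relapse_probs = nonCNS_relapse_probs,
         os = os,
         n_missing_relapse = as.integer(n_missing_relapse),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# 0-truncated normal via inverse CDF (exact, vectorized).
.rtnorm0 <- function(n, mu, sigma) {
  p0 <- stats::pnorm(0, mu, sigma)
  stats::qnorm(stats::runif(n, p0, 1), mu, sigma)
}

#' Generate a synthetic cohort
#'
#' Draws cell-level, area and clinical tables with the structure described
#' in [sim_config()]. All randomness is fixed by `config$seed`: two calls
#' with an identical config return identical tables.
#'
#' @param config A [sim_config()].
#' @return A list of class `mif_cohort` with tibbles `cells` (one row per
#'   cell: ids, compartment, per-marker `intensity_*` and true generating
#'   labels `true_label_*`), `areas` (per core x compartment, mm^2),
#'   `clinical` (one row per patient, including the latent
#'   `true_density` driving relapse and the relapse probability
#'   `p_cns`), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  np <- config$n_patients
  cpp <- config$cores_per_patient
  nc <- np * cpp

  core_patient <- rep(seq_len(np), each = cpp)
  core_id <- seq_len(nc)
  tf <- config$tumor_area_fraction
  conc <- config$area_fraction_conc
  frac_tumor <- stats::rbeta(nc, tf * conc, (1 - tf) * conc)
  ev <- config$evaluable_fraction
  core_area <- config$core_area_mm2 * stats::runif(nc, ev[1], ev[2])
  # cell abundance scales with evaluable area: homogeneous cell density
  n_cells_core <- stats::rpois(
    nc, config$cells_per_core_mean * core_area / config$core_area_mm2)

  cell_core <- rep.int(core_id, n_cells_core)
  cell_patient <- rep.int(core_patient, n_cells_core)
  n_cells <- length(cell_core)
  compartment <- ifelse(
    stats::runif(n_cells) < frac_tumor[cell_core], "tumor", "stroma")

  cells <- tibble::tibble(
    patient_id = cell_patient,
    core_id = cell_core,
    cell_id = sequence(n_cells_core),
    compartment = compartment
  )

  for (nm in names(config$markers)) {
    m <- config$markers[[nm]]
    pi_pat <- if (m$pi_pos_logit_sd > 0) {
      stats::plogis(stats::qlogis(min(max(m$pi_pos, 1e-12), 1 - 1e-12)) +
                      stats::rnorm(np, 0, m$pi_pos_logit_sd))
    } else {
      rep(m$pi_pos, np)
    }
    pos <- stats::runif(n_cells) < pi_pat[cell_patient]
    intensity <- numeric(n_cells)
    intensity[!pos] <- rchisq_scaled(sum(!pos), m$chi2_df, m$chi2_scale)
    intensity[pos] <- .rtnorm0(sum(pos), m$mu_pos, m$sigma_pos)
    cells[[paste0("intensity_", nm)]] <- intensity
    cells[[paste0("true_label_", nm)]] <- pos
  }

  areas <- tibble::tibble(
    patient_id = rep(core_patient, times = 2),
    core_id = rep(core_id, times = 2),
    compartment = rep(c("tumor", "stroma"), each = nc),
    area_mm2 = c(frac_tumor, 1 - frac_tumor) * rep(core_area, 2)
  )

  # true double-positive density (gate & relapse marker, whole core)
  dp <- cells$true_label_CK &
    cells[[paste0("true_label_", config$relapse_marker)]]
  dp_count <- tabulate(cell_patient[dp], nbins = np)
  total_area <- as.vector(tapply(core_area, core_patient, sum))
  true_density <- dp_count / total_area

  p_cns <- stats::plogis(config$relapse$baseline_logit +
                           config$relapse$beta_density * true_density)
  cns <- stats::runif(np) < p_cns
  site <- character(np)
  site[cns] <- "CNS"
  site[!cns] <- sample(names(config$nonCNS_relapse_probs), sum(!cns),
                       replace = TRUE, prob = config$nonCNS_relapse_probs)

  med <- ifelse(cns, config$os$median_months[["cns"]],
                config$os$median_months[["other"]])
  t_death <- stats::rexp(np, rate = log(2) / med)
  cr <- config$os$censor_range_months
  t_cens <- stats::runif(np, cr[1], cr[2])

  clinical <- tibble::tibble(
    patient_id = seq_len(np),
    age = round(stats::rnorm(np, 67.5, 7.6), 1),
    sex = sample(c("male", "female"), np, replace = TRUE),
    histology = sample(
      c("adenocarcinoma", "squamous", "large_cell", "adenosquamous", "nos"),
      np, replace = TRUE, prob = c(175, 91, 25, 9, 4) / 304),
    stage = sample(c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB"),
                   np, replace = TRUE, prob = c(118, 69, 32, 31, 44, 10) / 304),
    smoking = sample(c("current", "ex", "never"), np, replace = TRUE,
                     prob = c(157, 111, 36) / 304),
    relapse_site = site,
    os_months = pmin(t_death, t_cens),
    os_event = t_death <= t_cens,
    true_density = true_density,
    p_cns = p_cns
  )
  if (config$n_missing_relapse > 0) {
    miss <- sample(np, config$n_missing_relapse)
    clinical$relapse_site[miss] <- NA_character_
  }

  structure(list(cells = cells, areas = areas, clinical = clinical,
                 config = config),
            class = "mif_cohort")
}

# Relapse-link parameters of the study-sized preset. Tuned once (large-n
# simulation + two-parameter root-find) so that the expected cells of the
# (median-split density x CNS relapse) table among outcome-complete
# patients approximate 2/126 low vs 14/132 high; frozen constants.
.paperlike_relapse <- list(baseline_logit = -4.777, beta_density = 0.03510)

#' Study-sized synthetic cohort preset
#'
#' A convenience preset emulating a 304-patient early-stage NSCLC TMA
#' cohort with duplicate 1-mm cores, a CK epithelial gate, an NRF2 signal
#' marker whose double-positive density drives CNS relapse through a
#' logistic link, a TrxR1 marker with no outcome effect, and 46 patients
#' with relapse information missing completely at random (leaving 258
#' outcome-complete patients at `scale = 1`).
#'
#' @param seed Integer seed.
#' @param scale Integer multiplier on the number of patients (and on the
#'   number of outcome-missing patients); `scale = 100` gives a large-n
#'   analogue with the same generating parameters.
#' @return A `mif_cohort` (see [generate_cohort()]).
#' @export
paperlike_cohort <- function(seed = 1L, scale = 1L) {
  stopifnot(scale >= 1)
  cfg <- sim_config(
    n_patients = 304L * as.integer(scale),
    cores_per_patient = 2L,
    cells_per_core_mean = 200,
    tumor_area_fraction = 0.55,
    markers = list(
      CK = list(pi_pos = 0.60, pi_pos_logit_sd = 0.30, mu_pos = 10),
      NRF2 = list(pi_pos = 0.22, pi_pos_logit_sd = 1.20, mu_pos = 8),
      TrxR1 = list(pi_pos = 0.30, pi_pos_logit_sd = 0.60, mu_pos = 8)
    ),
    relapse = .paperlike_relapse,
    relapse_marker = "NRF2",
    n_missing_relapse = 46L * as.integer(scale),
    seed = seed
  )
  generate_cohort(cfg)
}

#' Odds ratio implied by a cohort's generating model
#'
#' Computes the odds ratio of the expected (density group x CNS relapse)
#' table under the generating logistic model: patients are split at the
#' median of the true double-positive density and the model relapse
#' probabilities `p_cns` are averaged within each group. This is the
#' "configured" odds ratio a correctly calibrated analysis should recover
#' at large n.
#'
#' @param cohort A `mif_cohort`.
#' @return Length-1 numeric odds ratio.
#' @export
configured_or <- function(cohort) {
  cl <- cohort$clinical
  high <- cl$true_density > stats::median(cl$true_density)
  p1 <- mean(cl$p_cns[high])
  p0 <- mean(cl$p_cns[!high])
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' Write cohort tables as CSV
#'
#' @param cohort A `mif_cohort`.
#' @param dir Output directory (created if needed).
#' @param truth_labels Keep the `true_label_*` / latent clinical columns
#'   (testing only)?
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth_labels = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- cohort$cells
  clinical <- cohort$clinical
  if (!truth_labels) {
    cells <- cells[, !grepl("^true_label_", names(cells))]
    clinical <- clinical[, setdiff(names(clinical), c("true_density", "p_cns"))]
  }
  readr::write_csv(cells, file.path(dir, "cells.csv"))
  readr::write_csv(cohort$areas, file.path(dir, "areas.csv"))
  readr::write_csv(clinical, file.path(dir, "clinical.csv"))
  invisible(dir)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Directory containing `cells.csv`, `areas.csv`,
#'   `clinical.csv`.
#' @return A `mif_cohort` (without a config).
#' @export
read_cohort <- function(dir) {
  read1 <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    readr::read_csv(p, show_col_types = FALSE, progress = FALSE)
  }
  structure(list(cells = read1("cells.csv"), areas = read1("areas.csv"),
                 clinical = read1("clinical.csv"), config = NULL),
            class = "mif_cohort")
}
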