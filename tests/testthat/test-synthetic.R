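# Synthetic cohort generator: determinism, mixture structure, outcome
# calibration.

test_that("generation is deterministic under a fixed seed", {
  cfg <- small_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$areas, b$areas)
  expect_identical(a$clinical, b$clinical)

  p1 <- paperlike_cohort(seed = 3)
  p2 <- paperlike_cohort(seed = 3)
  expect_identical(p1$cells, p2$cells)
  expect_identical(p1$clinical, p2$clinical)
})

test_that("cell tables satisfy their structural invariants", {
  coh <- generate_cohort(small_config(seed = 4))
  cells <- coh$cells
  expect_true(all(cells$intensity_CK >= 0))
  expect_true(all(cells$compartment %in% c("tumor", "stroma")))
  expect_false(any(duplicated(
    cells[, c("patient_id", "core_id", "cell_id")])))
  # area table consistent: every core has both compartments, positive area
  expect_true(all(coh$areas$area_mm2 > 0))
  expect_equal(nrow(coh$areas), 2 * 80 * 2)
})

test_that("pi_pos = 0 yields a pure noise marker", {
  cfg <- sim_config(n_patients = 30, cells_per_core_mean = 100,
                    markers = list(CK = list(pi_pos = 0.6),
                                   NRF2 = list(pi_pos = 0)),
                    seed = 9)
  coh <- generate_cohort(cfg)
  expect_false(any(coh$cells$true_label_NRF2))
  # all draws come from the scaled chi-squared: compare the upper tail
  expect_lt(max(coh$cells$intensity_NRF2),
            qchisq(1 - 1e-9, df = 2))
})

test_that("the positive fraction matches pi_pos within Monte-Carlo error", {
  cfg <- sim_config(n_patients = 1000, cells_per_core_mean = 200,
                    markers = list(CK = list(pi_pos = 0.6),
                                   NRF2 = list(pi_pos = 0.3)),
                    seed = 12)
  coh <- generate_cohort(cfg)
  n <- nrow(coh$cells)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(mean(coh$cells$true_label_NRF2) - 0.3), 3 * se)
})

test_that("marker intensities match the analytic mixture moments at large n", {
  pi_pos <- 0.3; df <- 2; sc <- 1; mu <- 8; sig <- 1.5
  cfg <- sim_config(n_patients = 500, cells_per_core_mean = 250,
                    markers = list(CK = list(pi_pos = 0.6),
                                   NRF2 = list(pi_pos = pi_pos, chi2_df = df,
                                               chi2_scale = sc, mu_pos = mu,
                                               sigma_pos = sig)),
                    seed = 21)
  coh <- generate_cohort(cfg)
  x <- coh$cells$intensity_NRF2
  expect_gt(length(x), 1e5)
  m_noise <- df * sc
  v_noise <- 2 * df * sc^2
  m_mix <- (1 - pi_pos) * m_noise + pi_pos * mu
  v_mix <- (1 - pi_pos) * (v_noise + m_noise^2) +
    pi_pos * (sig^2 + mu^2) - m_mix^2
  expect_equal(mean(x), m_mix, tolerance = 0.01)
  expect_equal(var(x), v_mix, tolerance = 0.02)
})

test_that("a null relapse link reproduces the baseline relapse rate", {
  cfg <- sim_config(n_patients = 3000, cells_per_core_mean = 30,
                    relapse = list(baseline_logit = -2.5, beta_density = 0),
                    seed = 31)
  coh <- generate_cohort(cfg)
  rate <- mean(coh$clinical$relapse_site == "CNS")
  p0 <- plogis(-2.5)
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / 3000))
})

test_that("the study-sized preset has exactly 258 outcome-complete patients", {
  for (s in c(1, 17)) {
    coh <- paperlike_cohort(seed = s)
    expect_equal(nrow(coh$clinical), 304)
    expect_equal(sum(!is.na(coh$clinical$relapse_site)), 258)
  }
})

test_that("invalid configuration values are rejected naming the field", {
  expect_error(sim_config(tumor_area_fraction = 1.2),
               "tumor_area_fraction")
  expect_error(sim_config(n_patients = 0), "n_patients")
  expect_error(sim_config(markers = list(CK = list(sigma_pos = -1))),
               "sigma_pos")
  expect_error(sim_config(markers = list(NRF2 = list())), "CK")
  expect_error(sim_config(relapse = list(baseline_logit = NA,
                                         beta_density = 0)),
               "baseline_logit")
})

test_that("cohort CSV round-trip preserves the tables", {
  coh <- generate_cohort(small_config(seed = 5, n_patients = 12))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(as.data.frame(back$cells), as.data.frame(coh$cells),
               tolerance = 1e-12)
  expect_equal(back$clinical$relapse_site, coh$clinical$relapse_site)
})
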