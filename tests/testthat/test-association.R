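# 2x2 association statistics and logistic regression.

tab2x2 <- function(a, b, c, d) matrix(c(a, c, b, d), 2, 2) # rows low/high

rand_tables <- function(n, lo = 1, hi = 40, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tab2x2(sample(lo:hi, 1), sample(lo:hi, 1),
           sample(lo:hi, 1), sample(lo:hi, 1))
  })
}

test_that("odds ratio and Woolf interval match the published contingency table", {
  res <- odds_ratio(tab2x2(124, 2, 118, 14))
  expect_equal(round(res$or, 2), 7.36)
  expect_equal(round(res$ci_low, 2), 1.64)
  expect_equal(round(res$ci_high, 2), 33.06)
  expect_equal(res$method, "woolf")
  expect_equal(res$log_or_se, sqrt(1 / 124 + 1 / 2 + 1 / 118 + 1 / 14))
})

test_that("symmetric tables give OR 1 and zero cells trigger the Haldane correction", {
  expect_equal(odds_ratio(tab2x2(10, 10, 10, 10))$or, 1)
  res <- odds_ratio(tab2x2(5, 0, 5, 5))
  expect_equal(res$method, "haldane_corrected")
  expect_equal(res$or, (5.5 * 5.5) / (0.5 * 5.5))
  expect_error(odds_ratio(tab2x2(5, 0, 5, 0)), "undefined")
})

test_that("Woolf interval width shrinks as all cells scale up", {
  widths <- sapply(c(1, 2, 5, 10), function(k) {
    r <- odds_ratio(tab2x2(8, 3, 6, 9) * k)
    log(r$ci_high) - log(r$ci_low)
  })
  expect_true(all(diff(widths) < 0))
})

test_that("uncorrected Pearson chi-square reproduces the published p and its definition", {
  res <- pearson_chi2(tab2x2(124, 2, 118, 14))
  expect_equal(round(res$p, 3), 0.003)
  expect_equal(pearson_chi2(tab2x2(7, 3, 7, 3))$statistic, 0)
  expect_equal(pearson_chi2(tab2x2(7, 3, 7, 3))$p, 1)
  for (tab in rand_tables(20, seed = 5)) {
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(pearson_chi2(tab)$statistic,
                 sum((tab - exp_tab)^2 / exp_tab), tolerance = 1e-12)
    # invariance under transposition and row/column swaps
    expect_equal(pearson_chi2(t(tab))$statistic,
                 pearson_chi2(tab)$statistic)
    expect_equal(pearson_chi2(tab[2:1, ])$statistic,
                 pearson_chi2(tab)$statistic)
    expect_equal(pearson_chi2(tab[, 2:1])$statistic,
                 pearson_chi2(tab)$statistic)
  }
  expect_error(pearson_chi2(tab2x2(0, 0, 3, 4)), "marginal")
})

test_that("Fisher exact p matches enumeration, the reference implementation, and degenerate margins", {
  # exhaustive 4-table toy case
  expect_equal(fisher_exact(tab2x2(2, 1, 1, 2)), fisher_enum(tab2x2(2, 1, 1, 2)))
  # zero margin
  expect_equal(fisher_exact(tab2x2(3, 0, 4, 0)), 1)
  # published counts against the combinatorial oracle
  expect_equal(fisher_exact(tab2x2(124, 2, 118, 14)),
               fisher_enum(tab2x2(124, 2, 118, 14)), tolerance = 1e-10)
  # independent reference implementation on random tables
  for (tab in rand_tables(25, lo = 0, hi = 25, seed = 6)) {
    expect_equal(fisher_exact(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("the 2x2 logistic slope equals the cross-product odds ratio", {
  for (tab in rand_tables(10, seed = 8)) {
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    y <- rep(c(FALSE, TRUE, FALSE, TRUE),
             c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    x <- rep(c(0, 0, 1, 1), c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]))
    fit <- logistic_fit(y, data.frame(exposure = x))
    slope <- fit$coefficients[fit$coefficients$term == "exposure", ]
    expect_equal(exp(slope$estimate), or, tolerance = 1e-6)
    woolf <- odds_ratio(tab)
    expect_equal(slope$ci_low, woolf$ci_low, tolerance = 1e-4)
    expect_equal(slope$ci_high, woolf$ci_high, tolerance = 1e-4)
  }
})

test_that("separated covariates are flagged and constant covariates dropped", {
  set.seed(3)
  n <- 60
  x <- rep(c("A", "B", "C"), each = n / 3)
  y <- ifelse(x == "C", TRUE, runif(n) < 0.3) # level C predicts perfectly
  fit <- logistic_fit(y, data.frame(grp = factor(x)))
  co <- fit$coefficients
  expect_true(co$separation[co$term == "grpC"])
  expect_true(is.na(co$or[co$term == "grpC"]))
  expect_false(any(co$separation[co$term != "grpC"]))

  expect_message(
    fit0 <- logistic_fit(y, data.frame(z = rep(1, n))),
    "constant covariate")
  expect_equal(plogis(fit0$coefficients$estimate[1]), mean(y),
               tolerance = 1e-8)
})

test_that("relapse screens recover a null density effect and code age continuously", {
  coh <- generate_cohort(small_config(seed = 14, n_patients = 400))
  cells <- coh$cells
  for (mk in c("CK", "NRF2", "TrxR1")) {
    cells[[paste0("pos_", mk)]] <- cells[[paste0("true_label_", mk)]]
  }
  dens <- compute_densities(cells, coh$areas)
  rep <- relapse_screens(dens, coh$clinical)

  uni <- rep$univariate
  row <- uni[uni$outcome == "cns_relapse" &
               grepl("nrf2_ck_density_whole", uni$term), ]
  expect_equal(nrow(row), 1)
  # generated with beta_density = 0: CI covers 1
  expect_true(row$ci_low < 1 && row$ci_high > 1)

  # age enters as one continuous coefficient, not level indicators
  expect_equal(sum(grepl("^age", uni$term[uni$outcome == "cns_relapse"])), 1)
  # stage expands against the IA reference
  expect_false(any(grepl("stageIA$", uni$term)))
  expect_true(any(grepl("stageIIIA", uni$term)))
  # multivariate model carries the density term
  expect_true(any(grepl("nrf2_ck_density_whole", rep$multivariate$term)))
})
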