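# Chi-squared + normal mixture: EM fitting, threshold location,
# classification.

sim_mixture <- function(n, pi_noise, df, scale, mu, sigma, seed) {
  set.seed(seed)
  noise <- runif(n) < pi_noise
  x <- numeric(n)
  x[noise] <- scale * rchisq(sum(noise), df)
  x[!noise] <- rnorm(sum(!noise), mu, sigma)
  list(x = x, label_pos = !noise)
}

test_that("EM recovers generating parameters, with a valid density and monotone log-likelihood", {
  truth <- list(pi_noise = 0.7, chi2_df = 2, chi2_scale = 1,
                mu_pos = 8, sigma_pos = 1.5)
  d <- sim_mixture(50000, 0.7, 2, 1, 8, 1.5, seed = 101)
  fit <- fit_mixture(d$x)

  expect_true(fit$converged)
  for (p in names(truth)) {
    expect_lt(abs(fit[[p]] - truth[[p]]) / truth[[p]], 0.05)
  }
  # observed-data log-likelihood never decreases across EM iterations
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  # the mixture density integrates to 1
  integ <- integrate(function(x) dmixture(fit, x), 0, Inf,
                     rel.tol = 1e-9)$value
  expect_equal(integ, 1, tolerance = 1e-6)
  # threshold agrees with a brute-force grid scan of the same crossing
  expect_lt(abs(fit$threshold - grid_threshold(fit)) / fit$threshold, 0.02)
  # classification against the generating labels: the crossing threshold is
  # the Bayes rule, so accuracy should match the analytic optimum
  #   1 - [pi0 * P(chi2 > t) + pi1 * P(N < t)]  at the true-parameter crossing
  t_true <- as.numeric(find_threshold(structure(truth, class = "mixture_fit")))
  acc_bayes <- 1 - (0.7 * pchisq(t_true, 2, lower.tail = FALSE) +
                      0.3 * pnorm(t_true, 8, 1.5))
  pos <- classify_cells(d$x, fit$threshold)
  expect_equal(mean(pos == d$label_pos), acc_bayes, tolerance = 0.01)
})

test_that("data drawn entirely from the signal component yields a vanishing noise weight", {
  set.seed(7)
  x <- rnorm(5000, 8, 1.5)
  x <- x[x > 0]
  fit <- suppressWarnings(
    fit_mixture(x, init = list(pi_noise = 0.02, chi2_df = 2,
                               chi2_scale = 1, mu_pos = 8,
                               sigma_pos = 1.5)))
  expect_lte(fit$pi_noise, 0.05)
  expect_equal(fit$mu_pos, 8, tolerance = 0.05)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_mixture(rexp(50)), "insufficient data")
  expect_error(fit_mixture(rep(2, 500)), "degenerate")
  expect_error(fit_mixture(c(rep(NA, 500), rexp(50))), "insufficient data")
})

test_that("two equal-sigma normal components at equal weight cross at the midpoint of the means", {
  roots <- density_crossing(function(x) dnorm(x, 2, 1),
                            function(x) dnorm(x, 6, 1),
                            w0 = 0.5, interval = c(0, 8))
  expect_length(roots, 1)
  expect_equal(as.numeric(roots), 4, tolerance = 1e-7)
})

test_that("threshold is non-decreasing in the signal mean", {
  base <- list(pi_noise = 0.7, chi2_df = 2, chi2_scale = 1,
               sigma_pos = 1.5)
  thr <- vapply(seq(5, 14, by = 0.5), function(mu) {
    as.numeric(find_threshold(structure(c(base, mu_pos = mu),
                                        class = "mixture_fit")))
  }, numeric(1))
  expect_true(all(diff(thr) >= -1e-8))
})

test_that("non-crossing components fall back to the noise tail quantile with a warning", {
  # noise weight so small that the signal density dominates everywhere
  fit <- structure(list(pi_noise = 1e-4, chi2_df = 2, chi2_scale = 1,
                        mu_pos = 3, sigma_pos = 4),
                   class = "mixture_fit")
  expect_warning(thr <- find_threshold(fit), "do not cross")
  expect_true(attr(thr, "fallback"))
  expect_equal(as.numeric(thr), qgamma(1 - 1e-4, shape = 1, scale = 2),
               tolerance = 1e-10)
})

test_that("classification uses a strict boundary, propagates NA, and handles empty input", {
  t <- 5
  eps <- 1e-9
  expect_equal(as.logical(classify_cells(c(t - eps, t, t + eps), t)),
               c(FALSE, FALSE, TRUE))
  expect_length(classify_cells(numeric(0), t), 0)
  expect_message(out <- classify_cells(c(1, NA, Inf, 10), t),
                 "2 non-finite")
  expect_identical(as.logical(out), c(FALSE, NA, NA, TRUE))
  expect_identical(attr(out, "n_excluded"), 2L)
})

test_that("classification is invariant under affine rescaling of the intensities", {
  d <- sim_mixture(20000, 0.6, 2, 1, 8, 1.5, seed = 55)
  a <- 3.7
  fit1 <- fit_mixture(d$x)
  fit2 <- fit_mixture(a * d$x)
  expect_equal(fit2$threshold / fit1$threshold, a, tolerance = 0.02)
  p1 <- classify_cells(d$x, fit1$threshold)
  p2 <- classify_cells(a * d$x, fit2$threshold)
  expect_gt(mean(p1 == p2), 0.999)
})
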