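# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Brute-force threshold: scan g(x) = pi0*f0 - pi1*f1 on an equally spaced
# grid and return the largest noise->signal sign change below mu_pos.
grid_threshold <- function(fit, n_grid = 1e6) {
  xs <- seq(1e-9, fit$mu_pos, length.out = n_grid)
  g <- fit$pi_noise * dgamma(xs, shape = fit$chi2_df / 2,
                             scale = 2 * fit$chi2_scale) -
    (1 - fit$pi_noise) * dnorm(xs, fit$mu_pos, fit$sigma_pos)
  s <- sign(g)
  down <- which(s[-1] < s[-n_grid]) # + to - crossing
  if (length(down) == 0) return(NA_real_)
  i <- max(down)
  mean(xs[c(i, i + 1)])
}

# Two-sided Fisher p by explicit combinatorial enumeration (lchoose), not
# dhyper: sums P(table) over all admissible tables with fixed margins whose
# probability is <= the observed one (same 1 + 1e-7 tie tolerance).
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p <- exp(lp)
  p_obs <- exp(lchoose(r1, tab[1, 1]) + lchoose(r2, c1 - tab[1, 1]) -
                 lchoose(n, c1))
  min(sum(p[p <= p_obs * (1 + 1e-7)]), 1)
}

# AUC as the all-pairs concordance probability (+ half ties).
auc_pairwise <- function(values, outcome) {
  v1 <- values[as.logical(outcome)]
  v0 <- values[!as.logical(outcome)]
  cmp <- outer(v1, v0, `-`)
  (sum(cmp > 0) + 0.5 * sum(cmp == 0)) / (length(v1) * length(v0))
}

# Small fast cohort for pipeline-level tests: elevated relapse rate so both
# outcome classes are always present at n = 80.
small_config <- function(seed, n_patients = 80, beta_density = 0) {
  sim_config(
    n_patients = n_patients,
    cells_per_core_mean = 60,
    markers = list(CK = list(pi_pos = 0.6, mu_pos = 10),
                   NRF2 = list(pi_pos = 0.25, pi_pos_logit_sd = 1),
                   TrxR1 = list(pi_pos = 0.3)),
    relapse = list(baseline_logit = -2, beta_density = beta_density),
    seed = seed
  )
}

# True-parameter mixture (as a mixture_fit-shaped list) for a config marker.
true_fit <- function(config, marker) {
  m <- config$markers[[marker]]
  structure(list(pi_noise = 1 - m$pi_pos, chi2_df = m$chi2_df,
                 chi2_scale = m$chi2_scale, mu_pos = m$mu_pos,
                 sigma_pos = m$sigma_pos),
            class = "mixture_fit")
}
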