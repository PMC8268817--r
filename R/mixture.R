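# Two-component intensity mixture: scaled chi-squared noise + normal signal.
#
# A scaled chi-squared with df degrees of freedom and scale s is the law of
# s * X, X ~ chi2(df), i.e. Gamma(shape = df/2, scale = 2s). df is treated as
# a continuous positive parameter so the weighted M-step is an ordinary
# gamma maximum-likelihood problem.

# Noise (scaled chi-squared) density.
dchisq_scaled <- function(x, df, scale) {
  stats::dgamma(x, shape = df / 2, scale = 2 * scale)
}

rchisq_scaled <- function(n, df, scale) {
  scale * stats::rchisq(n, df = df)
}

#' Mixture density of a fitted noise/signal model
#'
#' Evaluates `pi_noise * f_chi2(x) + (1 - pi_noise) * f_normal(x)` for a
#' [mixture_fit] object (or any list carrying the same parameter fields).
#'
#' @param fit A `mixture_fit` (or compatible list).
#' @param x Numeric vector of intensities.
#' @return Numeric vector of mixture density values.
#' @export
dmixture <- function(fit, x) {
  fit$pi_noise * dchisq_scaled(x, fit$chi2_df, fit$chi2_scale) +
    (1 - fit$pi_noise) * stats::dnorm(x, fit$mu_pos, fit$sigma_pos)
}

# Weighted gamma MLE for the noise component. Solves
#   log(shape) - digamma(shape) = log(weighted mean) - weighted mean log
# which is monotone decreasing in shape, then scale = mean / shape.
.gamma_mstep <- function(x, w) {
  sw <- sum(w)
  mw <- sum(w * x) / sw
  mlw <- sum(w * log(x)) / sw
  s <- log(mw) - mlw
  # Jensen guarantees s >= 0; s -> 0 means vanishing dispersion.
  s <- max(s, 1e-10)
  # Standard closed-form starter, then refine.
  a0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  a0 <- min(max(a0, 1e-3), 1e4)
  f <- function(a) log(a) - digamma(a) - s
  lo <- a0 / 10
  hi <- a0 * 10
  while (f(lo) < 0 && lo > 1e-6) lo <- lo / 10
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
  a <- tryCatch(
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root,
    error = function(e) a0
  )
  list(shape = a, scale = mw / a)
}

.mixture_loglik <- function(x, par) {
  d <- par$pi_noise * dchisq_scaled(x, par$chi2_df, par$chi2_scale) +
    (1 - par$pi_noise) * stats::dnorm(x, par$mu_pos, par$sigma_pos)
  sum(log(pmax(d, .Machine$double.xmin)))
}

# Deterministic data-driven start: the lower half of the sample seeds the
# noise component by moment matching, the upper quartile seeds the signal.
.mixture_init <- function(x, pi_noise = 0.75, split = 0.75) {
  q <- stats::quantile(x, split, names = FALSE)
  lower <- x[x <= stats::median(x)]
  upper <- x[x > q]
  m <- mean(lower)
  v <- stats::var(lower)
  if (!is.finite(v) || v <= 0) v <- m^2 / 2 + 1e-8
  shape <- m^2 / v
  list(
    pi_noise = pi_noise,
    chi2_df = 2 * min(max(shape, 1e-3), 1e4),
    chi2_scale = max(v / m, 1e-8) / 2,
    mu_pos = mean(upper),
    sigma_pos = max(stats::sd(upper), 1e-3)
  )
}

#' Fit the chi-squared + normal intensity mixture by EM
#'
#' Models pooled per-cell intensities of one marker as a two-component
#' mixture: a scaled chi-squared noise component (marker-negative cells) and
#' a normal signal component (marker-positive cells). Parameters are
#' estimated by expectation-maximization; the normal component has
#' closed-form updates and the chi-squared df/scale are updated by weighted
#' gamma maximum likelihood. The positivity threshold is placed at the
#' intersection of the two weighted component densities (see
#' [find_threshold()]).
#'
#' @param intensities Numeric vector of non-negative intensities (arbitrary
#'   fluorescence units); at least 100 finite values.
#' @param init Optional named list of starting values (`pi_noise`,
#'   `chi2_df`, `chi2_scale`, `mu_pos`, `sigma_pos`). By default a
#'   deterministic moment-matching start is used, with one fixed fallback
#'   restart if EM fails to converge.
#' @param tol Convergence tolerance on the absolute change of the
#'   observed-data log-likelihood (default `1e-8`).
#' @param max_iter Maximum EM iterations (default 500).
#' @return An object of class `mixture_fit`: a list with `pi_noise`,
#'   `chi2_df`, `chi2_scale`, `mu_pos`, `sigma_pos`, `threshold`,
#'   `threshold_fallback`, `loglik`, `n_iter`, `converged`, `n` and the
#'   per-iteration `loglik_trace`.
#' @examples
#' set.seed(1)
#' x <- c(rchisq(700, df = 2), rnorm(300, 8, 1.5))
#' fit <- fit_mixture(x)
#' fit$threshold
#' @export
fit_mixture <- function(intensities, init = NULL, tol = 1e-8, max_iter = 500L) {
  x <- intensities[is.finite(intensities)]
  if (length(x) < 100) {
    stop("insufficient data: need at least 100 finite intensities, got ",
         length(x))
  }
  if (any(x < 0)) stop("intensities must be non-negative")
  if (stats::sd(x) == 0) {
    stop("degenerate input: all intensities identical")
  }
  stopifnot(tol > 0, max_iter >= 1)
  x <- pmax(x, 1e-300) # gamma log-density needs log(x)

  run_em <- function(par) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      d0 <- par$pi_noise * dchisq_scaled(x, par$chi2_df, par$chi2_scale)
      d1 <- (1 - par$pi_noise) * stats::dnorm(x, par$mu_pos, par$sigma_pos)
      tot <- pmax(d0 + d1, .Machine$double.xmin)
      r <- d0 / tot # noise responsibilities
      ll <- sum(log(tot))
      trace <- c(trace, ll)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      ll_old <- ll
      # M-step
      sr <- sum(r)
      par$pi_noise <- min(max(sr / length(x), 1e-6), 1 - 1e-6)
      w1 <- 1 - r
      sw1 <- sum(w1)
      par$mu_pos <- sum(w1 * x) / sw1
      par$sigma_pos <- max(sqrt(sum(w1 * (x - par$mu_pos)^2) / sw1), 1e-6)
      g <- .gamma_mstep(x, r)
      par$chi2_df <- 2 * g$shape
      par$chi2_scale <- g$scale / 2
    }
    list(par = par, loglik = ll, trace = trace, n_iter = iter,
         converged = converged)
  }

  par0 <- if (is.null(init)) .mixture_init(x) else init
  res <- run_em(par0)
  if (!res$converged && is.null(init)) {
    # one fixed fallback restart: even split at the median
    res2 <- run_em(.mixture_init(x, pi_noise = 0.5, split = 0.5))
    if (res2$converged || res2$loglik > res$loglik) res <- res2
  }

  fit <- structure(
    c(res$par,
      list(threshold = NA_real_, threshold_fallback = FALSE,
           loglik = res$loglik, n_iter = res$n_iter,
           converged = res$converged, n = length(x),
           loglik_trace = res$trace)),
    class = "mixture_fit"
  )
  thr <- find_threshold(fit)
  fit$threshold <- as.numeric(thr)
  fit$threshold_fallback <- isTRUE(attr(thr, "fallback"))
  fit
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Chi-squared + normal intensity mixture fit\n")
  cat(sprintf("  n = %d cells, loglik = %.3f, %d EM iterations (%s)\n",
              x$n, x$loglik, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  noise : pi = %.3f, chi2(df = %.3f, scale = %.3f)\n",
              x$pi_noise, x$chi2_df, x$chi2_scale))
  cat(sprintf("  signal: pi = %.3f, normal(mu = %.3f, sigma = %.3f)\n",
              1 - x$pi_noise, x$mu_pos, x$sigma_pos))
  cat(sprintf("  threshold = %.6g%s\n", x$threshold,
              if (isTRUE(x$threshold_fallback)) " (tail fallback)" else ""))
  invisible(x)
}

#' Locate crossings of two weighted density functions
#'
#' Finds the roots of `g(x) = w0 * f0(x) - (1 - w0) * f1(x)` on an interval
#' by a sign-change scan over a fine grid followed by bisection
#' (`uniroot`, absolute tolerance `tol`).
#'
#' @param f0,f1 Vectorized density functions.
#' @param w0 Weight of `f0` in `(0, 1)`.
#' @param interval Length-2 numeric search interval.
#' @param n_grid Number of grid points for bracketing (default 4096).
#' @param tol Absolute root tolerance (default `1e-8`).
#' @return Numeric vector of roots (possibly empty), with attribute
#'   `"direction"` giving the sign change at each root (`-1` where the
#'   signal density overtakes the noise density).
#' @export
density_crossing <- function(f0, f1, w0, interval, n_grid = 4096L,
                             tol = 1e-8) {
  stopifnot(length(interval) == 2, interval[1] < interval[2],
            w0 > 0, w0 < 1)
  g <- function(x) w0 * f0(x) - (1 - w0) * f1(x)
  xs <- seq(interval[1], interval[2], length.out = n_grid)
  gs <- g(xs)
  sgn <- sign(gs)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  roots <- vapply(idx, function(i) {
    stats::uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root
  }, numeric(1))
  # also accept exact zeros on the grid
  exact <- xs[gs == 0]
  dir <- c(sgn[idx + 1L], rep(0, length(exact)))
  roots <- c(roots, exact)
  o <- order(roots)
  structure(roots[o], direction = dir[o])
}

#' Positivity threshold at the intersection of the component densities
#'
#' The threshold is the intensity where the weighted signal density
#' overtakes the weighted noise density: a root of
#' `g(x) = pi_noise * f_chi2(x) - (1 - pi_noise) * f_normal(x)` between the
#' noise mode and the signal mean. When several crossings exist, the
#' largest root below `mu_pos` with the noise-to-signal sign change is
#' used. When the components never cross in the interval (fully separated
#' or fully dominated), the threshold falls back to the intensity at which
#' the noise component's upper-tail probability is `1e-4`, and the result
#' carries attribute `fallback = TRUE`.
#'
#' @param fit A `mixture_fit` (or compatible list) with `pi_noise` in (0,1).
#' @param search_interval Optional length-2 interval; defaults to
#'   (just above 0, `mu_pos`).
#' @return The threshold intensity (length-1 numeric); attribute
#'   `"fallback"` is `TRUE` when the tail fallback was used.
#' @export
find_threshold <- function(fit, search_interval = NULL) {
  if (!(fit$pi_noise > 0 && fit$pi_noise < 1)) {
    stop("pi_noise must lie strictly in (0, 1)")
  }
  f0 <- function(x) dchisq_scaled(x, fit$chi2_df, fit$chi2_scale)
  f1 <- function(x) stats::dnorm(x, fit$mu_pos, fit$sigma_pos)
  if (is.null(search_interval)) {
    lo <- stats::qgamma(1e-9, shape = fit$chi2_df / 2,
                        scale = 2 * fit$chi2_scale)
    search_interval <- c(max(lo, 1e-12), fit$mu_pos)
  }
  roots <- density_crossing(f0, f1, fit$pi_noise, search_interval)
  dir <- attr(roots, "direction")
  below <- roots < fit$mu_pos
  take <- below & dir < 0
  cand <- if (any(take)) roots[take] else roots[below]
  if (length(cand) > 0) {
    return(structure(max(cand), fallback = FALSE))
  }
  warning("component densities do not cross in the search interval; ",
          "using the noise 1e-4 upper-tail quantile")
  structure(
    stats::qgamma(1 - 1e-4, shape = fit$chi2_df / 2,
                  scale = 2 * fit$chi2_scale),
    fallback = TRUE
  )
}

#' Classify cells as marker-positive by a fixed threshold
#'
#' A cell is positive iff its intensity is strictly greater than the
#' threshold. Non-finite intensities are flagged `NA` and excluded from the
#' positive/negative calls; their count is reported in attribute
#' `"n_excluded"` and via a message.
#'
#' @param intensities Numeric vector.
#' @param threshold Finite length-1 numeric.
#' @return Logical vector of the same length (`NA` for non-finite input),
#'   with attribute `n_excluded`.
#' @export
classify_cells <- function(intensities, threshold) {
  stopifnot(length(threshold) == 1, is.finite(threshold))
  pos <- intensities > threshold
  bad <- !is.finite(intensities)
  if (any(bad)) {
    pos[bad] <- NA
    message(sum(bad), " non-finite intensities flagged and excluded")
  }
  attr(pos, "n_excluded") <- sum(bad)
  pos
}
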