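# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Continuum median of the density that spreads each bin's count uniformly
# over its bin, by direct inversion of the piecewise-linear CDF. When the
# CDF sits exactly at 1/2 on a flat stretch (an exact tie on a bin edge),
# the upper endpoint of the median set is returned, matching the
# convention of applying the interpolation formula in the bin above.
oracle_continuum_median <- function(counts, scheme) {
  n <- sum(counts)
  stopifnot(n > 0)
  nb <- length(counts)
  Fcum <- c(0, cumsum(counts)) / n
  for (k in seq_len(nb - 1)) {   # closed bins only
    lo <- scheme$edges[k]
    if (Fcum[k] <= 0.5 && Fcum[k + 1] > 0.5) {
      if (Fcum[k + 1] == Fcum[k]) next
      return(lo + (0.5 - Fcum[k]) / (Fcum[k + 1] - Fcum[k]) * scheme$width)
    }
    if (Fcum[k + 1] == 0.5) {
      # flat stretch: walk to the start of the next mass
      for (m in (k + 1):nb) {
        if (counts[m] > 0) {
          if (m == nb) return(NA_real_)  # mass resumes in the open bin
          return(scheme$edges[m])
        }
      }
    }
  }
  NA_real_  # median in the open top bin
}

# Exact posterior of the conditionally conjugate model the sampler
# targets: y = a + b x + e, e ~ N(0, 1/tau), independent normal priors on
# (a, b) and a gamma prior on tau. Marginally over (a, b) the model is a
# scale mixture over tau, so posterior moments of (a, b) follow from 1-D
# quadrature over tau: p(tau | y) is known up to a constant (complete the
# square in the Gaussian integral), and (a, b) | tau, y is bivariate
# normal with closed-form mean and covariance. No Monte Carlo involved.
oracle_conjugate_posterior <- function(x, y, priors = prior_spec(),
                                       n_grid = 4000) {
  X <- cbind(1, x)
  n <- length(y)
  L0 <- diag(c(priors$intercept_precision, priors$slope_precision))
  mu0 <- c(priors$intercept_mean, priors$slope_mean)
  a0 <- priors$noise_precision_shape
  b0 <- priors$noise_precision_rate
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  yty <- sum(y^2)

  log_post_tau <- function(tau) {
    A <- tau * XtX + L0
    m <- solve(A, tau * Xty + L0 %*% mu0)
    as.numeric(
      0.5 * n * log(tau) - 0.5 * determinant(A)$modulus -
        0.5 * (tau * yty + t(mu0) %*% L0 %*% mu0 - t(m) %*% A %*% m) +
        (a0 - 1) * log(tau) - b0 * tau)
  }
  # log-spaced grid generously bracketing the residual precision
  s2 <- max(stats::var(stats::residuals(stats::lm(y ~ x))), 1e-8)
  lt <- seq(log(1 / s2) - 12, log(1 / s2) + 12, length.out = n_grid)
  tau <- exp(lt)
  lp <- vapply(tau, log_post_tau, numeric(1)) + lt   # jacobian of log grid
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  ms <- vapply(tau, function(t)
    as.numeric(solve(t * XtX + L0, t * Xty + L0 %*% mu0)), numeric(2))
  Vs <- vapply(tau, function(t) diag(solve(t * XtX + L0)), numeric(2))
  mean_ab <- as.numeric(ms %*% w)
  var_ab <- as.numeric(Vs %*% w) +
    as.numeric((ms - mean_ab)^2 %*% w)
  list(mean = mean_ab, sd = sqrt(var_ab))
}

# Ordinary least squares, for the vague-prior limit checks.
oracle_ols <- function(x, y) {
  fit <- stats::lm(y ~ x)
  list(coef = unname(stats::coef(fit)),
       r_squared = summary(fit)$r.squared)
}

quick_settings <- function(seed = 1, chains = 2, burn_in = 500,
                           samples = 2500) {
  mcmc_settings(chains = chains, burn_in = burn_in, samples = samples,
                seed = seed)
}

# A curve with analytically chosen draws: alpha, beta constants, noise
# sd sigma (tau = 1/sigma^2), z standard-normal with a fixed seed.
degenerate_curve <- function(alpha, beta, sigma, n_draws = 20000,
                             seed = 99) {
  set.seed(seed)
  standard_curve_from_draws(
    alpha = rep(alpha, n_draws), beta = rep(beta, n_draws),
    tau = rep(1 / sigma^2, n_draws), z = stats::rnorm(n_draws))
}

make_pairs <- function(x, y, sex = "male", n_cases = 100,
                       n_population = 1e5) {
  median_pairs(sprintf("U%03d", seq_along(x)), sex, x, y, n_cases,
               n_population)
}

random_bin_counts <- function(scheme, max_per_bin = 20, open_top_mass = TRUE) {
  nb <- length(scheme$labels)
  counts <- stats::rpois(nb, stats::runif(nb, 0, max_per_bin / 2))
  if (!open_top_mass) counts[nb] <- 0
  counts
}
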