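#' Prior specification for the standard curve
#'
#' Vague independent priors matching common registry practice for this
#' model: Normal(0, precision 1e-6) on the intercept and slope, and
#' Gamma(shape 0.5, rate 0.01) on the residual precision tau.
#'
#' @param intercept_mean,intercept_precision Normal prior on the intercept
#'   (years; precision in 1/years^2).
#' @param slope_mean,slope_precision Normal prior on the slope.
#' @param noise_precision_shape,noise_precision_rate Gamma prior on tau.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_mean = 0, intercept_precision = 1e-6,
                       slope_mean = 0, slope_precision = 1e-6,
                       noise_precision_shape = 0.5,
                       noise_precision_rate = 0.01) {
  stopifnot(intercept_precision > 0, slope_precision > 0,
            noise_precision_shape > 0, noise_precision_rate > 0)
  structure(
    list(intercept_mean = intercept_mean,
         intercept_precision = intercept_precision,
         slope_mean = slope_mean, slope_precision = slope_precision,
         noise_precision_shape = noise_precision_shape,
         noise_precision_rate = noise_precision_rate),
    class = "prior_spec"
  )
}

#' MCMC settings
#'
#' Defaults follow the production configuration for this model: 3 chains,
#' 100,000 burn-in iterations discarded and 100,000 retained per chain.
#' Desk-scale analyses and tests run much shorter chains; the conjugate
#' Gibbs sampler mixes essentially immediately.
#'
#' @param chains Number of chains (>= 1).
#' @param burn_in Iterations discarded per chain.
#' @param samples Iterations retained per chain (after thinning).
#' @param seed Integer RNG seed; the fit is deterministic given it.
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param center_x Centre the predictor internally for numerical
#'   conditioning; draws are always mapped back to the raw scale, so the
#'   reported intercept is at x = 0 regardless.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 3, burn_in = 100000, samples = 100000,
                          seed = 1, thin = 1, center_x = FALSE) {
  stopifnot(chains >= 1, burn_in >= 0, samples >= 1, thin >= 1)
  structure(
    list(chains = as.integer(chains), burn_in = as.integer(burn_in),
         samples = as.integer(samples), seed = as.integer(seed),
         thin = as.integer(thin), center_x = isTRUE(center_x)),
    class = "mcmc_settings"
  )
}

new_standard_curve <- function(alpha, beta, tau, z, chains, sex,
                               reference_ids, priors, settings, x_ref) {
  stopifnot(length(alpha) == length(beta), length(beta) == length(tau),
            length(tau) == length(z), all(tau > 0))
  structure(
    list(alpha = alpha, beta = beta, tau = tau, sigma = 1 / sqrt(tau),
         z = z, chains = chains, sex = sex, reference_ids = reference_ids,
         priors = priors, settings = settings, x_ref = x_ref),
    class = "standard_curve"
  )
}

#' Build a standard curve directly from posterior draws
#'
#' Low-level constructor used for audit (re-importing exported draws) and
#' for testing with analytically chosen draws. `z` holds one standard
#' normal deviate per draw, used to form the posterior predictive
#' replicate `alpha + beta x + z/sqrt(tau)`.
#'
#' @param alpha,beta,tau Equal-length draw vectors; `tau > 0`.
#' @param z Standard-normal deviates, one per draw; generated when `NULL`
#'   (then depends on the RNG state).
#' @param chains Number of chains the draws came from (draws assumed
#'   concatenated chain-by-chain in equal blocks).
#' @param sex,reference_ids Optional labels.
#' @return A `standard_curve` object.
#' @export
standard_curve_from_draws <- function(alpha, beta, tau, z = NULL, chains = 1,
                                      sex = "unspecified",
                                      reference_ids = character(0)) {
  if (is.null(z)) z <- stats::rnorm(length(alpha))
  new_standard_curve(alpha, beta, tau, z, chains, sex, reference_ids,
                     priors = NULL, settings = NULL, x_ref = numeric(0))
}

#' Fit the Bayesian standard curve
#'
#' Fits `y ~ Normal(alpha + beta x, 1/tau)` across reference registries,
#' where `x` is the median age of each registry's population and `y` the
#' median age at cancer onset, by a conjugate Gibbs sampler: `(alpha,
#' beta) | tau` is drawn jointly from its bivariate normal full
#' conditional and `tau | (alpha, beta)` from its gamma full conditional.
#' The model is exactly conjugate under the [prior_spec()] priors, so no
#' tuning is involved and mixing is immediate.
#'
#' @param pairs A [median_pairs()] data frame of a single sex; rows with
#'   undefined `y` are dropped (at least 3 usable rows required).
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @return A `standard_curve` object holding the retained draws of
#'   `alpha` (years), `beta` (years/year) and `tau` (1/years^2), plus one
#'   stored standard-normal deviate per draw for posterior predictive
#'   replicates.
#' @examples
#' pairs <- median_pairs(sprintf("R%02d", 1:10), "male",
#'                       x = 40 + 1:10, y = 56 + 0.4 * (40 + 1:10),
#'                       n_cases = 100, n_population = 1e5)
#' fit <- fit_standard_curve(pairs, settings = mcmc_settings(
#'   chains = 2, burn_in = 200, samples = 500, seed = 1))
#' expected_onset(fit, 45)
#' @export
fit_standard_curve <- function(pairs, priors = prior_spec(),
                               settings = mcmc_settings()) {
  stopifnot(inherits(pairs, "median_pairs"), inherits(priors, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  sexes <- unique(pairs$sex)
  if (length(sexes) != 1) {
    stop("fit_standard_curve expects a single sex; got ",
         paste(sexes, collapse = ", "), " — fit each sex separately",
         call. = FALSE)
  }
  use <- !is.na(pairs$y)
  if (sum(use) < 3) {
    stop("need at least 3 reference pairs with a defined onset median; have ",
         sum(use), call. = FALSE)
  }
  x <- pairs$x[use]; y <- pairs$y[use]
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite medians in reference pairs", call. = FALSE)
  }

  xshift <- if (settings$center_x) mean(x) else 0
  xs <- x - xshift
  n <- length(y)
  Sx <- sum(xs); Sxx <- sum(xs^2); Sy <- sum(y); Sxy <- sum(xs * y)
  Syy <- sum(y^2)

  pa <- priors$intercept_precision; ma <- priors$intercept_mean
  pb <- priors$slope_precision; mb <- priors$slope_mean
  a0 <- priors$noise_precision_shape; b0 <- priors$noise_precision_rate

  # OLS start values (slope guarded for degenerate x)
  vx <- Sxx / n - (Sx / n)^2
  b_ols <- if (vx > 0) (Sxy / n - Sx * Sy / n^2) / vx else 0
  a_ols <- Sy / n - b_ols * Sx / n
  s2_ols <- max(sum((y - a_ols - b_ols * xs)^2) / max(n - 2, 1), 1e-6)

  set.seed(settings$seed)
  keep <- settings$samples
  total <- settings$burn_in + keep * settings$thin
  nch <- settings$chains
  alpha <- beta <- tau <- numeric(keep * nch)

  for (ch in seq_len(nch)) {
    # overdispersed start: jitter the OLS residual precision
    tau_c <- exp(stats::runif(1, -1.5, 1.5)) / s2_ols
    a_c <- a_ols; b_c <- b_ols
    idx <- (ch - 1) * keep
    stored <- 0L
    for (it in seq_len(total)) {
      # (alpha, beta) | tau: bivariate normal, solved with explicit 2x2 algebra
      A11 <- tau_c * n + pa
      A12 <- tau_c * Sx
      A22 <- tau_c * Sxx + pb
      r1 <- tau_c * Sy + pa * ma
      r2 <- tau_c * Sxy + pb * mb
      det <- A11 * A22 - A12 * A12
      m1 <- (A22 * r1 - A12 * r2) / det
      m2 <- (A11 * r2 - A12 * r1) / det
      # Cholesky of the precision matrix: A = L L', sample m + L'^{-1} z
      l11 <- sqrt(A11)
      l21 <- A12 / l11
      l22 <- sqrt(A22 - l21 * l21)
      z2 <- stats::rnorm(2)
      b_c <- m2 + z2[2] / l22
      a_c <- m1 + (z2[1] - l21 * z2[2] / l22) / l11
      # tau | (alpha, beta)
      ssr <- Syy + n * a_c * a_c + b_c * b_c * Sxx -
        2 * a_c * Sy - 2 * b_c * Sxy + 2 * a_c * b_c * Sx
      tau_c <- stats::rgamma(1, shape = a0 + n / 2, rate = b0 + ssr / 2)
      if (it > settings$burn_in &&
          (it - settings$burn_in) %% settings$thin == 0) {
        stored <- stored + 1L
        alpha[idx + stored] <- a_c
        beta[idx + stored] <- b_c
        tau[idx + stored] <- tau_c
      }
    }
  }
  # map back to raw x scale (beta unchanged)
  if (xshift != 0) alpha <- alpha - beta * xshift
  z <- stats::rnorm(length(alpha))

  if (length(alpha) < 1000) {
    warning("only ", length(alpha),
            " retained draws; interval estimates want >= 1000", call. = FALSE)
  }
  new_standard_curve(alpha, beta, tau, z, nch, sexes,
                     pairs$unit_id[use], priors, settings, x)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> sex = %s, %d reference units, %d draws (%d chain%s)\n",
    x$sex, length(x$reference_ids), length(x$alpha), x$chains,
    if (x$chains > 1) "s" else ""))
  cat(sprintf("  intercept %.2f (sd %.2f)  slope %.3f (sd %.3f)  sigma %.2f\n",
              mean(x$alpha), stats::sd(x$alpha), mean(x$beta),
              stats::sd(x$beta), mean(x$sigma)))
  invisible(x)
}

#' Expected age at onset for a given population median
#'
#' Posterior mean of `alpha + beta x`, in years.
#'
#' @param curve A fitted `standard_curve`.
#' @param x Median population age(s) in years.
#' @return Numeric vector of expected onset ages.
#' @export
expected_onset <- function(curve, x) {
  stopifnot(inherits(curve, "standard_curve"))
  mean(curve$alpha) + mean(curve$beta) * x
}

#' Posterior predictive interval of the standard curve
#'
#' Equal-tailed Monte-Carlo quantiles of the posterior predictive
#' replicate `y_rep = alpha + beta x + eps`, `eps ~ Normal(0, 1/tau)`,
#' using the one stored standard-normal deviate per retained draw. This is
#' the band within which a new registry's onset median is expected with
#' the stated probability.
#'
#' @param curve A fitted `standard_curve`.
#' @param x_grid Population median ages (years) at which to evaluate.
#' @param level Coverage probability in (0, 1); default 0.95.
#' @return A data frame of class `predictive_band` with columns `x`,
#'   `lower`, `upper`; attribute `level`.
#' @export
predictive_interval <- function(curve, x_grid, level = 0.95) {
  stopifnot(inherits(curve, "standard_curve"), level > 0, level < 1)
  eps <- curve$z / sqrt(curve$tau)
  p <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qs <- vapply(x_grid, function(xx) {
    stats::quantile(curve$alpha + curve$beta * xx + eps, probs = p, names = FALSE)
  }, numeric(2))
  out <- data.frame(x = x_grid, lower = qs[1, ], upper = qs[2, ])
  class(out) <- c("predictive_band", "data.frame")
  attr(out, "level") <- level
  out
}

#' Squared correlation between observed and fitted onset medians
#'
#' Squared Pearson correlation between the observed onset medians and the
#' posterior-mean fitted values, the conventional r-squared quoted with
#' the curve equation.
#'
#' @param curve A fitted `standard_curve`.
#' @param pairs The [median_pairs()] the curve was fitted on (rows with
#'   undefined `y` are dropped).
#' @return A number in \[0, 1\]; `NA` with a warning when `y` is constant.
#' @export
fit_r_squared <- function(curve, pairs) {
  stopifnot(inherits(curve, "standard_curve"), inherits(pairs, "median_pairs"))
  use <- !is.na(pairs$y)
  y <- pairs$y[use]
  fitted <- expected_onset(curve, pairs$x[use])
  if (stats::sd(y) == 0 || stats::sd(fitted) == 0) {
    warning("constant observed or fitted values; r-squared undefined",
            call. = FALSE)
    return(NA_real_)
  }
  stats::cor(y, fitted)^2
}

split_rhat <- function(draws, chains) {
  m <- length(draws) %/% chains
  half <- m %/% 2
  if (half < 2) return(NA_real_)
  halves <- lapply(seq_len(chains), function(ch) {
    d <- draws[((ch - 1) * m + 1):(ch * m)]
    list(d[seq_len(half)], d[(m - half + 1):m])
  })
  segs <- unlist(halves, recursive = FALSE)
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(if (B == 0) NA_real_ else Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence diagnostics for a fitted standard curve
#'
#' Split-R-hat (each chain split in half; flagged when > 1.01) and
#' effective sample size (via [coda::effectiveSize()]) for alpha, beta and
#' tau. With a single chain R-hat is unavailable and only ESS is
#' reported. Chains whose draws are numerically identical are flagged as
#' degenerate (e.g. two chains run from the same stream).
#'
#' @param curve A fitted `standard_curve`.
#' @return A data frame with one row per parameter: `rhat`, `ess`.
#' @export
convergence_diagnostics <- function(curve) {
  stopifnot(inherits(curve, "standard_curve"))
  pars <- list(alpha = curve$alpha, beta = curve$beta, tau = curve$tau)
  nch <- curve$chains
  m <- length(curve$alpha) %/% nch

  if (nch >= 2) {
    ch_draws <- lapply(seq_len(nch), function(ch)
      curve$alpha[((ch - 1) * m + 1):(ch * m)])
    for (i in 2:nch) {
      if (identical(ch_draws[[1]], ch_draws[[i]])) {
        warning("chains 1 and ", i,
                " have identical draws: degenerate replication, diagnostics uninformative",
                call. = FALSE)
      }
    }
  }

  out <- data.frame(
    parameter = names(pars),
    rhat = vapply(pars, function(d)
      if (nch >= 2) split_rhat(d, nch) else NA_real_, numeric(1)),
    ess = vapply(pars, function(d)
      as.numeric(coda::effectiveSize(coda::mcmc(d))), numeric(1)),
    row.names = NULL
  )
  bad <- out$parameter[!is.na(out$rhat) & out$rhat > 1.01]
  if (length(bad)) {
    warning("split-R-hat > 1.01 for: ", paste(bad, collapse = ", "),
            " — run longer chains", call. = FALSE)
  }
  out
}

#' Export posterior draws for audit
#'
#' @param curve A fitted `standard_curve`.
#' @param path Output CSV path (columns alpha, beta, tau, z at full
#'   precision).
#' @return `path`, invisibly.
#' @export
write_curve_draws <- function(curve, path) {
  stopifnot(inherits(curve, "standard_curve"))
  out <- data.frame(alpha = fmt_full(curve$alpha), beta = fmt_full(curve$beta),
                    tau = fmt_full(curve$tau), z = fmt_full(curve$z))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Re-import exported posterior draws
#'
#' @param path CSV written by [write_curve_draws()].
#' @param chains Number of chains the draws came from.
#' @param sex Optional sex label.
#' @return A `standard_curve` object.
#' @export
read_curve_draws <- function(path, chains = 1, sex = "unspecified") {
  df <- utils::read.csv(path)
  standard_curve_from_draws(df$alpha, df$beta, df$tau, z = df$z,
                            chains = chains, sex = sex)
}
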