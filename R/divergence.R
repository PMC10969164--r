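#' Partition study units into eligible and excluded
#'
#' A unit enters the hypothesis-testing step only when it has more than
#' one incident case and a defined onset median. Excluded units are kept
#' in reports with category `no_data` (the white map areas).
#'
#' @param pairs A [median_pairs()] data frame of study units.
#' @return `pairs` with a logical `eligible` column added.
#' @export
eligible_units <- function(pairs) {
  stopifnot(inherits(pairs, "median_pairs"))
  eligible <- pairs$n_cases > 1 & !is.na(pairs$y)
  odd <- pairs$n_cases > 1 & is.na(pairs$y)
  if (any(odd)) {
    warning("unit(s) with >1 case but undefined onset median excluded: ",
            paste(pairs$unit_id[odd], collapse = ", "), call. = FALSE)
  }
  pairs$eligible <- eligible
  pairs
}

#' Bonferroni-corrected significance threshold
#'
#' The familywise alpha divided by the number of eligible study areas
#' (those with more than one incident case).
#'
#' @param alpha Familywise significance level in (0, 1); conventionally
#'   0.05.
#' @param n_eligible Number of eligible study areas (>= 1).
#' @return `alpha / n_eligible`, at full precision.
#' @examples
#' bonferroni_threshold(0.05, 40)  # 0.00125
#' @export
bonferroni_threshold <- function(alpha, n_eligible) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  if (n_eligible < 1) stop("no eligible units", call. = FALSE)
  alpha / n_eligible
}

#' Testing plan for a family of study areas
#'
#' @param alpha Familywise alpha.
#' @param n_eligible Eligible-area count.
#' @return An object of class `testing_plan` with the Bonferroni
#'   `threshold`.
#' @export
testing_plan <- function(alpha = 0.05, n_eligible) {
  structure(
    list(alpha = alpha, n_eligible = as.integer(n_eligible),
         threshold = bonferroni_threshold(alpha, n_eligible)),
    class = "testing_plan"
  )
}

#' @export
print.testing_plan <- function(x, ...) {
  cat(sprintf("<testing_plan> alpha = %g over %d eligible areas: threshold = %g\n",
              x$alpha, x$n_eligible, x$threshold))
  invisible(x)
}

curve_mu_draws <- function(curve, x) curve$alpha + curve$beta * x

#' Residual of a study unit against the standard curve
#'
#' Per posterior draw, the residual is the observed onset median minus the
#' curve value `alpha + beta x` (parameter mode) or minus a posterior
#' predictive replicate `alpha + beta x + eps`, `eps ~ Normal(0, 1/tau)`
#' (predictive mode, the default; its interval is the one a new
#' registry-like observation is judged against). Returns the draw mean and
#' the equal-tailed 95% interval.
#'
#' @param curve A fitted `standard_curve`.
#' @param pair A one-row [median_pairs()] data frame (or any list with
#'   `x`, `y`).
#' @param mode "predictive" or "parameter".
#' @param level Interval level; default 0.95.
#' @return A list with `residual` (years; negative = early onset) and
#'   `ci` (length-2 numeric).
#' @export
residual_summary <- function(curve, pair, mode = c("predictive", "parameter"),
                             level = 0.95) {
  stopifnot(inherits(curve, "standard_curve"))
  mode <- match.arg(mode)
  if (is.na(pair$y)) {
    stop("unit has no defined onset median; filter with eligible_units()",
         call. = FALSE)
  }
  r <- pair$y - curve_mu_draws(curve, pair$x)
  if (mode == "predictive") r <- r - curve$z / sqrt(curve$tau)
  ci <- stats::quantile(r, probs = c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(residual = mean(r), ci = ci)
}

#' Posterior probability that the curve predicts an onset at or below the
#' observed one
#'
#' The lower-tail posterior probability `PP = P(y_rep <= y_obs | x)`.
#' Small values flag an improbably early onset, values near 1 an
#' improbably late one; a unit on the curve has PP near 0.5. In
#' predictive mode the probability is computed exactly given the draws as
#' the average of `pnorm(y_obs, alpha + beta x, 1/sqrt(tau))`; in
#' parameter mode it is the fraction of draws with `alpha + beta x <=
#' y_obs`.
#'
#' @inheritParams residual_summary
#' @return A probability in \[0, 1\].
#' @export
posterior_probability <- function(curve, pair,
                                  mode = c("predictive", "parameter")) {
  stopifnot(inherits(curve, "standard_curve"))
  mode <- match.arg(mode)
  if (is.na(pair$y)) {
    stop("unit has no defined onset median; filter with eligible_units()",
         call. = FALSE)
  }
  mu <- curve_mu_draws(curve, pair$x)
  if (mode == "predictive") {
    mean(stats::pnorm(pair$y, mean = mu, sd = curve$sigma))
  } else {
    mean(mu <= pair$y)
  }
}

residual_categories <- c("postpone_ge2", "neutral", "early_2_4",
                         "early_4_6", "early_ge6", "no_data")

categorize_residual <- function(r) {
  ifelse(is.na(r), "no_data",
  ifelse(r >= 2, "postpone_ge2",
  ifelse(r > -2, "neutral",
  ifelse(r > -4, "early_2_4",
  ifelse(r > -6, "early_4_6", "early_ge6")))))
}

#' Classify a study unit
#'
#' Applies the two-sided decision rule to the lower-tail posterior
#' probability (early: `pp <= threshold`; late: `pp >= 1 - threshold`;
#' the comparison is inclusive) and maps the residual to the five-level
#' map category: >= +2 years postponement; between -2 and +2 neutral;
#' (-4, -2\] years early; (-6, -4\] years early; <= -6 years early. The
#' bands partition the real line, closed on the early side at the round
#' boundaries.
#'
#' @param residual Residual in years (negative = early onset).
#' @param pp Lower-tail posterior probability.
#' @param plan A [testing_plan()].
#' @return A list with `significant_early`, `significant_late`,
#'   `category`.
#' @examples
#' classify_unit(-4.5, 0.0002, testing_plan(0.05, 40))
#' @export
classify_unit <- function(residual, pp, plan) {
  stopifnot(inherits(plan, "testing_plan"), is.finite(residual),
            is.finite(pp), pp >= 0, pp <= 1)
  list(
    significant_early = pp <= plan$threshold,
    significant_late = pp >= 1 - plan$threshold,
    category = categorize_residual(residual)
  )
}

divergence_row <- function(unit_id, sex, n_cases, n_population, x, y,
                           expected = NA_real_, residual = NA_real_,
                           ci = c(NA_real_, NA_real_), pp = NA_real_,
                           pp_predictive = NA_real_,
                           pp_parameter = NA_real_, eligible = FALSE,
                           significant_early = FALSE,
                           significant_late = FALSE,
                           category = "no_data", status = "ok") {
  data.frame(
    unit_id = unit_id, sex = sex, n_cases = n_cases,
    n_population = n_population, x = x, y_observed = y,
    expected = expected, residual = residual,
    ci_low = ci[1], ci_high = ci[2], pp = pp,
    pp_predictive = pp_predictive,
    pp_parameter = pp_parameter, eligible = eligible,
    significant_early = significant_early,
    significant_late = significant_late,
    category = category, status = status,
    stringsAsFactors = FALSE
  )
}

#' Full divergence analysis of study areas against reference registries
#'
#' Per sex: fits the standard curve on the reference pairs, partitions the
#' study units into eligible and excluded, sets the Bonferroni threshold
#' from the eligible count, and computes for every study unit the expected
#' onset, residual with 95% credibility interval, lower-tail posterior
#' probability (both predictive and parameter mode; flags use `mode`),
#' significance flags and map category. Deterministic given
#' `settings$seed` (per-sex fits use seed offsets).
#'
#' @param reference A [median_pairs()] data frame of reference registries
#'   (one or both sexes).
#' @param study A [median_pairs()] data frame of study areas.
#' @param priors A [prior_spec()].
#' @param settings An [mcmc_settings()].
#' @param alpha Familywise alpha before Bonferroni division; default 0.05.
#' @param mode PP mode driving the significance flags; default
#'   "predictive".
#' @return An object of class `divergence_analysis`: list with `results`
#'   (data frame, one row per study unit), `plans` and `curves` (per-sex
#'   lists), `alpha`, `mode`.
#' @export
run_divergence_analysis <- function(reference, study, priors = prior_spec(),
                                    settings = mcmc_settings(), alpha = 0.05,
                                    mode = c("predictive", "parameter")) {
  stopifnot(inherits(reference, "median_pairs"), inherits(study, "median_pairs"))
  mode <- match.arg(mode)

  sexes <- sort(unique(reference$sex))
  curves <- list(); plans <- list(); rows <- list()
  for (s in sexes) {
    sx_settings <- settings
    sx_settings$seed <- settings$seed + match(s, c("male", "female")) - 1L
    curve <- fit_standard_curve(reference[reference$sex == s, , drop = FALSE],
                                priors, sx_settings)
    curves[[s]] <- curve

    st <- study[study$sex == s, , drop = FALSE]
    if (nrow(st) == 0) next
    st <- eligible_units(st)
    n_elig <- sum(st$eligible)
    plan <- if (n_elig >= 1) testing_plan(alpha, n_elig) else NULL
    plans[[s]] <- plan
    if (n_elig == 0) {
      warning("sex ", s, ": no eligible study units, threshold not computed",
              call. = FALSE)
    }

    for (i in seq_len(nrow(st))) {
      p <- st[i, ]
      if (!p$eligible) {
        rows[[length(rows) + 1L]] <- divergence_row(
          p$unit_id, s, p$n_cases, p$n_population, p$x, p$y,
          status = "insufficient cases")
        next
      }
      rs <- residual_summary(curve, p, mode = mode)
      pp_pred <- posterior_probability(curve, p, mode = "predictive")
      pp_par <- posterior_probability(curve, p, mode = "parameter")
      pp_use <- if (mode == "predictive") pp_pred else pp_par
      cl <- classify_unit(rs$residual, pp_use, plan)
      rows[[length(rows) + 1L]] <- divergence_row(
        p$unit_id, s, p$n_cases, p$n_population, p$x, p$y,
        expected = expected_onset(curve, p$x), residual = rs$residual,
        ci = rs$ci, pp = pp_use,
        pp_predictive = pp_pred,
        pp_parameter = pp_par, eligible = TRUE,
        significant_early = cl$significant_early,
        significant_late = cl$significant_late,
        category = cl$category)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    divergence_row("", "", NA_real_, NA_real_, NA_real_, NA_real_)[0, ]
  structure(
    list(results = results, plans = plans, curves = curves,
         alpha = alpha, mode = mode),
    class = "divergence_analysis"
  )
}

#' @export
print.divergence_analysis <- function(x, ...) {
  cat(sprintf("<divergence_analysis> %d study units, %d sex(es), mode = %s\n",
              nrow(x$results), length(x$curves), x$mode))
  for (s in names(x$plans)) {
    pl <- x$plans[[s]]
    if (is.null(pl)) next
    r <- x$results[x$results$sex == s, ]
    cat(sprintf("  %s: %d eligible, threshold %.5g, %d early / %d late flags\n",
                s, pl$n_eligible, pl$threshold,
                sum(r$significant_early), sum(r$significant_late)))
  }
  invisible(x)
}
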