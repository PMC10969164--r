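test_that("eligibility requires more than one case and a defined median", {
  pairs <- median_pairs(
    c("a", "b", "c", "d"), "male", x = rep(44, 4),
    y = c(65, 65, NA, NA), n_cases = c(1, 2, 50, 0),
    n_population = rep(1000, 4))
  expect_warning(out <- eligible_units(pairs), "undefined onset median")
  expect_equal(out$eligible, c(FALSE, TRUE, FALSE, FALSE))
})

test_that("Bonferroni thresholds reproduce the published family sizes", {
  expect_identical(bonferroni_threshold(0.05, 40), 0.00125)
  expect_equal(bonferroni_threshold(0.05, 35), 0.05 / 35)
  expect_equal(round(bonferroni_threshold(0.05, 35), 5), 0.00143)
  expect_identical(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "no eligible")
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
})

test_that("residuals collapse to the noiseless limit and centre on zero on-line", {
  cv <- degenerate_curve(50, 0.5, 1e-9)
  rs <- residual_summary(cv, list(x = 40, y = 66))
  expect_equal(rs$residual, -4, tolerance = 1e-6)
  expect_equal(rs$ci, c(-4, -4), tolerance = 1e-6)

  cv1 <- degenerate_curve(50, 0.5, 1.5)
  rs1 <- residual_summary(cv1, list(x = 40, y = 70))
  expect_equal(rs1$residual, 0, tolerance = 0.05)
  expect_equal(rs1$ci[1], -rs1$ci[2], tolerance = 0.1)
  # predictive CI half-width ~ 1.96 sigma for a parameter-free curve
  expect_equal(rs1$ci[2], 1.96 * 1.5, tolerance = 0.05)

  expect_error(residual_summary(cv1, list(x = 40, y = NA)), "eligible_units")
})

test_that("posterior probability is a calibrated lower-tail quantity", {
  cv <- degenerate_curve(50, 0.5, 1.5)
  expect_equal(posterior_probability(cv, list(x = 40, y = 70)), 0.5,
               tolerance = 1e-12)  # exactly on the line, constant draws
  expect_lt(posterior_probability(cv, list(x = 40, y = 40)), 1e-8)
  expect_gt(posterior_probability(cv, list(x = 40, y = 100)), 1 - 1e-8)

  # monotone nondecreasing in the observed median, both modes
  cfg <- scenario_config(seed = 15)
  fit <- fit_standard_curve(generate_reference_pairs(cfg),
                            settings = quick_settings(seed = 15))
  for (mode in c("predictive", "parameter")) {
    pps <- vapply(seq(55, 90, by = 0.5), function(yy)
      posterior_probability(fit, list(x = 45, y = yy), mode = mode),
      numeric(1))
    expect_true(all(diff(pps) >= 0))
  }
})

test_that("parameter-mode PP is at least as extreme as predictive-mode PP", {
  cfg <- scenario_config(seed = 25)
  fit <- fit_standard_curve(generate_reference_pairs(cfg),
                            settings = quick_settings(seed = 25))
  set.seed(25)
  for (rep in 1:40) {
    x <- runif(1, 40, 50); y <- 56 + 0.4 * x + runif(1, -8, 8)
    pp_par <- posterior_probability(fit, list(x = x, y = y), "parameter")
    pp_pred <- posterior_probability(fit, list(x = x, y = y), "predictive")
    if (pp_pred < 0.5) expect_lte(pp_par, pp_pred)
    if (pp_pred > 0.5) expect_gte(pp_par, pp_pred)
  }
})

test_that("PP is approximately uniform under the null", {
  # marginal calibration: each null unit comes with its own reference draw,
  # since the predictive distribution is calibrated over the joint draw of
  # (reference registries, new unit), not conditionally on one fit
  pps <- numeric(0)
  for (rep in 1:100) {
    cfg <- scenario_config(n_study = 20, shifts = rep(0, 20),
                           study_case_counts = rep(30L, 20),
                           study_noise = "model", seed = 3300 + rep)
    fit <- fit_standard_curve(generate_reference_pairs(cfg),
                              settings = quick_settings(seed = 330 + rep,
                                                        burn_in = 200,
                                                        samples = 1000))
    st <- generate_study_pairs(cfg)
    pps <- c(pps, vapply(seq_len(20), function(i)
      posterior_probability(fit, list(x = st$x[i], y = st$y[i])),
      numeric(1)))
  }
  ks <- suppressWarnings(stats::ks.test(pps, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(max(abs(sort(pps) - seq_along(pps) / length(pps))), 0.05)
})

test_that("classification reproduces the published worked rows", {
  plan_m <- testing_plan(0.05, 40)
  cl <- classify_unit(-4.5, 0.0002, plan_m)
  expect_true(cl$significant_early)
  expect_false(cl$significant_late)
  expect_equal(cl$category, "early_4_6")

  # threshold comparison is inclusive: PP 0.0013 vs 0.05/35 counts
  plan_w <- testing_plan(0.05, 35)
  cl2 <- classify_unit(-5.3, 0.0013, plan_w)
  expect_true(cl2$significant_early)
  expect_equal(cl2$category, "early_4_6")
  expect_true(classify_unit(-1, plan_w$threshold, plan_w)$significant_early)

  cl3 <- classify_unit(0, 0.5, plan_m)
  expect_false(cl3$significant_early || cl3$significant_late)
  expect_equal(cl3$category, "neutral")

  cl4 <- classify_unit(3.1, 0.9995, plan_m)
  expect_true(cl4$significant_late)
  expect_equal(cl4$category, "postpone_ge2")
})

test_that("residual categories partition the real line", {
  r <- seq(-12, 12, by = 0.01)
  cats <- vapply(r, function(ri)
    classify_unit(ri, 0.5, testing_plan(0.05, 10))$category, character(1))
  expect_true(all(cats %in% c("postpone_ge2", "neutral", "early_2_4",
                              "early_4_6", "early_ge6")))
  # closed on the early side at the round boundaries
  cat_of <- function(ri) classify_unit(ri, 0.5, testing_plan(0.05, 10))$category
  expect_identical(cat_of(-2), "early_2_4")
  expect_identical(cat_of(-4), "early_4_6")
  expect_identical(cat_of(-6), "early_ge6")
  expect_identical(cat_of(2), "postpone_ge2")
  expect_identical(cat_of(-1.99), "neutral")
  expect_identical(cat_of(1.99), "neutral")
})

test_that("Bonferroni correction controls the familywise early-flag rate", {
  n_rep <- 200
  n_areas <- 40
  any_early <- 0L
  for (rep in seq_len(n_rep)) {
    cfg <- scenario_config(n_study = n_areas, shifts = rep(0, n_areas),
                           study_case_counts = rep(30L, n_areas),
                           study_noise = "model", seed = 6000 + rep)
    an <- run_divergence_analysis(
      generate_reference_pairs(cfg), generate_study_pairs(cfg),
      settings = quick_settings(seed = 6500 + rep, burn_in = 200,
                                samples = 800))
    any_early <- any_early + as.integer(any(an$results$significant_early))
  }
  # FWER <= alpha, allowing 3 binomial SEs of Monte-Carlo slack
  expect_lte(any_early / n_rep, 0.05 + 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("early-flag power is nondecreasing in the injected shift magnitude", {
  shifts <- c(-2, -5, -9)
  n_rep <- 40
  power <- numeric(length(shifts))
  for (si in seq_along(shifts)) {
    hits <- 0L
    for (rep in seq_len(n_rep)) {
      cfg <- scenario_config(n_study = 20,
                             shifts = c(shifts[si], rep(0, 19)),
                             study_case_counts = rep(30L, 20),
                             seed = 7000 + rep)
      an <- run_divergence_analysis(
        generate_reference_pairs(cfg), generate_study_pairs(cfg),
        settings = quick_settings(seed = 7500 + rep, burn_in = 200,
                                  samples = 800))
      hits <- hits + as.integer(an$results$significant_early[1])
    }
    power[si] <- hits / n_rep
  }
  # allow binomial jitter between neighbouring grid points
  expect_true(all(diff(power) >= -0.1))
  expect_gt(power[3], power[1] + 0.3)
})

test_that("the full analysis flags an injected early-onset unit end-to-end", {
  shifts <- c(-8, rep(0, 40))
  cfg <- scenario_config(shifts = shifts, seed = 41)
  an <- run_divergence_analysis(
    generate_reference_pairs(cfg), generate_study_pairs(cfg),
    settings = quick_settings(seed = 41))
  res <- an$results
  expect_equal(nrow(res), 41)
  expect_equal(an$plans$male$n_eligible, 41)
  target <- res[res$unit_id == "AREA01", ]
  expect_true(target$significant_early)
  expect_equal(target$category, "early_ge6")
  expect_lt(target$residual, -4)
  # flags only where eligible, and categories consistent with residuals
  expect_true(all(!res$significant_early[!res$eligible]))
  expect_true(all(res$category[!res$eligible] == "no_data"))
})

test_that("an empty study collection still returns the fitted curve", {
  cfg <- scenario_config(seed = 2)
  ref <- generate_reference_pairs(cfg)
  empty <- generate_study_pairs(cfg)[0, ]
  an <- run_divergence_analysis(ref, empty,
                                settings = quick_settings(seed = 2, samples = 1000))
  expect_equal(nrow(an$results), 0)
  expect_s3_class(an$curves$male, "standard_curve")
})

test_that("sexes are analysed separately with their own curves and thresholds", {
  cfg_m <- scenario_config(seed = 51, n_study = 10, shifts = rep(0, 10),
                           study_case_counts = rep(20L, 10))
  cfg_w <- scenario_config(seed = 52, true_alpha = 37.4, true_beta = 0.76,
                           n_study = 8, shifts = rep(0, 8),
                           study_case_counts = c(1L, rep(20L, 7)))
  ref <- rbind(generate_reference_pairs(cfg_m, "male"),
               generate_reference_pairs(cfg_w, "female"))
  class(ref) <- c("median_pairs", "data.frame")
  study <- rbind(generate_study_pairs(cfg_m, "male"),
                 generate_study_pairs(cfg_w, "female"))
  class(study) <- c("median_pairs", "data.frame")
  an <- run_divergence_analysis(ref, study,
                                settings = quick_settings(seed = 53, samples = 1500))
  expect_setequal(names(an$curves), c("male", "female"))
  expect_equal(an$plans$male$n_eligible, 10)
  expect_equal(an$plans$female$n_eligible, 7)
  expect_equal(an$plans$female$threshold, 0.05 / 7)
  expect_equal(mean(an$curves$female$beta), 0.76,
               tolerance = 3 * sd(an$curves$female$beta))
  expect_false(identical(mean(an$curves$male$alpha),
                         mean(an$curves$female$alpha)))
})
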