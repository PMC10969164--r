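#' Synthetic-scenario configuration
#'
#' Describes a complete simulated study: reference registries whose
#' (population median, onset median) points scatter around a known line,
#' and sparse study areas with injected early/late onset shifts. All
#' generators are deterministic given `seed` and return their truth
#' tables, so every pipeline stage can be validated end-to-end without
#' access-restricted registry data.
#'
#' Defaults emulate the structure of the motivating study: 36 reference
#' registries with population medians in the 40-50 year range scattering
#' around `y = 56 + 0.4 x` with 1.5 years of residual spread, and 41
#' study areas of 30 cases each. Individual onset ages within a study
#' area spread with `sd_onset = 9` years around the area's target median,
#' a plausible within-area dispersion for lung-cancer onset.
#'
#' @param n_reference Number of reference registries.
#' @param x_range Range (years) from which population medians are drawn
#'   uniformly.
#' @param true_alpha,true_beta,true_sigma Line intercept (years), slope,
#'   and residual standard deviation (years) of the reference scatter.
#' @param n_study Number of study areas.
#' @param shifts Injected onset shift per study area in years (negative =
#'   early); length `n_study`.
#' @param study_case_counts Incident-case count per study area; length
#'   `n_study`.
#' @param sd_onset Standard deviation (years) of individual onset ages
#'   within a study area.
#' @param study_noise `"sampling"` (default): a study area's onset median
#'   is the sample median of `n_cases` simulated individual onset ages,
#'   so small-area sampling noise is present exactly as in real sparse
#'   areas. `"model"`: the onset median is drawn directly from the
#'   reference model `line + Normal(0, true_sigma)`; this is the exact
#'   null of the method, used for calibration studies.
#' @param seed Integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_reference = 36, x_range = c(40, 50),
                            true_alpha = 56, true_beta = 0.4,
                            true_sigma = 1.5, n_study = 41,
                            shifts = rep(0, n_study),
                            study_case_counts = rep(30L, n_study),
                            sd_onset = 9,
                            study_noise = c("sampling", "model"),
                            seed = 1) {
  study_noise <- match.arg(study_noise)
  stopifnot(n_reference >= 3, length(x_range) == 2, x_range[1] < x_range[2],
            true_sigma >= 0, sd_onset >= 0, n_study >= 1)
  if (length(shifts) != n_study || length(study_case_counts) != n_study) {
    stop("shifts and study_case_counts must have length n_study = ", n_study,
         call. = FALSE)
  }
  if (any(study_case_counts < 0) || any(study_case_counts != round(study_case_counts))) {
    stop("study_case_counts must be nonnegative integers", call. = FALSE)
  }
  structure(
    list(n_reference = as.integer(n_reference), x_range = as.numeric(x_range),
         true_alpha = true_alpha, true_beta = true_beta,
         true_sigma = true_sigma, n_study = as.integer(n_study),
         shifts = as.numeric(shifts),
         study_case_counts = as.integer(study_case_counts),
         sd_onset = sd_onset, study_noise = study_noise,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' Read a scenario configuration from YAML
#'
#' @param path YAML file whose keys mirror the [scenario_config()]
#'   arguments.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(scenario_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown scenario key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(scenario_config, cfg)
}

#' Generate reference registry median pairs
#'
#' `x_i ~ Uniform(x_range)`, `y_i = true_alpha + true_beta x_i +
#' Normal(0, true_sigma^2)`. Registry sizes are drawn in the
#' 60,000-1,300,000 inhabitant range typical of regional registries, with
#' case counts scaled accordingly; they do not influence `x` or `y`.
#'
#' @param config A [scenario_config()].
#' @param sex Sex label for the generated pairs.
#' @return A [median_pairs()] data frame with attribute `truth`: a data
#'   frame holding the noise-free line value and realized deviation per
#'   registry.
#' @export
generate_reference_pairs <- function(config, sex = "male") {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n_reference
  x <- stats::runif(n, config$x_range[1], config$x_range[2])
  line <- config$true_alpha + config$true_beta * x
  y <- line + stats::rnorm(n, 0, config$true_sigma)
  n_population <- round(stats::runif(n, 6e4, 1.3e6))
  n_cases <- round(n_population * stats::runif(n, 5e-4, 2e-3))
  pairs <- median_pairs(sprintf("REF%02d", seq_len(n)), sex, x, y,
                        n_cases, n_population)
  attr(pairs, "truth") <- data.frame(
    unit_id = pairs$unit_id, x = x, line = line, y = y, noise = y - line
  )
  pairs
}

#' Generate study-area median pairs with injected shifts
#'
#' Per area: draws a population median `x`, sets the target onset median
#' `y* = true_alpha + true_beta x + shift` and, under the default
#' `study_noise = "sampling"`, simulates `n_cases` individual onset ages
#' `~ Normal(y*, sd_onset^2)` and reports their sample median — so
#' small-n sampling noise is present exactly as in real sparse areas, and
#' areas with 0 cases have an undefined onset median. Under `study_noise
#' = "model"` the onset median is drawn directly from the reference
#' generative model (`shift + Normal(0, true_sigma)` around the line),
#' the exact null of the method.
#'
#' @inheritParams generate_reference_pairs
#' @return A [median_pairs()] data frame with attribute `truth` (per-area
#'   `x`, line value, `shift`, target and realized onset median).
#' @export
generate_study_pairs <- function(config, sex = "male") {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed + 1L)
  n <- config$n_study
  x <- stats::runif(n, config$x_range[1], config$x_range[2])
  line <- config$true_alpha + config$true_beta * x
  target <- line + config$shifts
  n_cases <- config$study_case_counts
  y <- numeric(n)
  if (config$study_noise == "model") {
    y <- target + stats::rnorm(n, 0, config$true_sigma)
    y[n_cases == 0] <- NA_real_
  } else {
    for (i in seq_len(n)) {
      y[i] <- if (n_cases[i] >= 1) {
        stats::median(stats::rnorm(n_cases[i], target[i], config$sd_onset))
      } else NA_real_
    }
  }
  n_population <- round(stats::runif(n, 50, 12000))
  pairs <- median_pairs(sprintf("AREA%02d", seq_len(n)), sex, x, y,
                        n_cases, n_population)
  attr(pairs, "truth") <- data.frame(
    unit_id = pairs$unit_id, x = x, line = line, shift = config$shifts,
    y_target = target, y_realized = y, n_cases = n_cases
  )
  pairs
}

#' Age-binned counts whose grouped median equals a target
#'
#' Inverse of [grouped_median()]: allocates a total count `n` across the
#' two bins straddling `target` so that the interpolated grouped median
#' reproduces `target` exactly. Counts are real-valued by default (exact
#' inversion is impossible on the integer lattice, where the achievable
#' medians form a discrete set); `integer_counts = TRUE` rounds the
#' allocation, trading exactness for integer cases.
#'
#' @param target Target median in years; must fall inside the closed-bin
#'   range (and, when below the midpoint of the first bin, cannot be
#'   represented).
#' @param n Total count (>= 1).
#' @param scheme An [age_bin_scheme()].
#' @param integer_counts Round the two allocated counts to integers
#'   (preserving the total).
#' @return Numeric vector of per-bin counts.
#' @examples
#' s <- age_bin_scheme()
#' counts <- binned_counts_for_median(57, 10, s)
#' grouped_median(counts, s)$value  # 57
#' @export
binned_counts_for_median <- function(target, n, scheme = age_bin_scheme(),
                                     integer_counts = FALSE) {
  stopifnot(n >= 1)
  top <- scheme$edges[length(scheme$edges)]
  if (!is.finite(target) || target < 0 || target >= top) {
    stop("target median must lie within the closed-bin range [0, ", top, ")",
         call. = FALSE)
  }
  j <- findInterval(target, scheme$edges)
  frac <- (target - scheme$edges[j]) / scheme$width
  counts <- numeric(length(scheme$labels))
  if (frac >= 0.5) {
    # mass a in the target bin, remainder above: median = L_j + (n/2 / a) h
    a <- n / (2 * frac)
    counts[j] <- a
    counts[j + 1] <- n - a
  } else {
    if (j == 1) {
      stop("target below the midpoint of the first bin cannot be represented",
           call. = FALSE)
    }
    # remainder b below the target bin: median = L_j + ((n/2 - b) / a) h
    a <- n / (2 - 2 * frac)
    counts[j] <- a
    counts[j - 1] <- n - a
  }
  if (integer_counts) {
    idx <- which(counts > 0)
    counts[idx[1]] <- round(counts[idx[1]])
    if (length(idx) == 2) counts[idx[2]] <- n - counts[idx[1]]
    if (counts[j] == 0) { counts[] <- 0; counts[j] <- n }  # degenerate rounding
  }
  counts
}

#' Generate age-binned tables realizing a scenario
#'
#' Builds the binned-input route end-to-end: for each generated unit,
#' population counts (real-valued, mid-period style) and case counts
#' (integer) are allocated so their grouped medians reproduce the unit's
#' generated medians (cases only approximately, by integer rounding).
#'
#' @param pairs A [median_pairs()] data frame (reference or study).
#' @param scheme An [age_bin_scheme()].
#' @return A list of [age_binned_table()] objects; units with an
#'   undefined onset median get zero cases.
#' @export
generate_binned_tables <- function(pairs, scheme = age_bin_scheme()) {
  stopifnot(inherits(pairs, "median_pairs"))
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    pop <- binned_counts_for_median(p$x, p$n_population, scheme)
    cs <- if (!is.na(p$y) && p$n_cases >= 1) {
      binned_counts_for_median(p$y, p$n_cases, scheme, integer_counts = TRUE)
    } else numeric(length(scheme$labels))
    out[[paste(p$unit_id, p$sex, sep = "|")]] <-
      age_binned_table(p$unit_id, p$sex, cs, pop, scheme)
  }
  out
}

#' Write a scenario's fixture files
#'
#' Writes the reference and study pair CSVs (the [read_median_pairs()]
#' dialect), the binned-table CSVs (the [read_binned_tables()] dialect)
#' and the truth tables to a directory.
#'
#' @param config A [scenario_config()].
#' @param out_dir Output directory (created if needed).
#' @param sex Sex label.
#' @return Named character vector of file paths, invisibly.
#' @export
write_scenario_fixtures <- function(config, out_dir, sex = "male") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference_pairs(config, sex)
  st <- generate_study_pairs(config, sex)
  paths <- c(
    reference_pairs = file.path(out_dir, "reference_pairs.csv"),
    study_pairs = file.path(out_dir, "study_pairs.csv"),
    reference_binned = file.path(out_dir, "reference_binned.csv"),
    study_binned = file.path(out_dir, "study_binned.csv"),
    reference_truth = file.path(out_dir, "reference_truth.csv"),
    study_truth = file.path(out_dir, "study_truth.csv")
  )
  write_median_pairs(ref, paths["reference_pairs"])
  write_median_pairs(st, paths["study_pairs"])
  write_binned_csv(generate_binned_tables(ref), paths["reference_binned"])
  write_binned_csv(generate_binned_tables(st), paths["study_binned"])
  utils::write.csv(attr(ref, "truth"), paths["reference_truth"], row.names = FALSE)
  utils::write.csv(attr(st, "truth"), paths["study_truth"], row.names = FALSE)
  invisible(paths)
}

#' Write age-binned tables to the CSV input dialect
#'
#' @param tables A list of [age_binned_table()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_binned_csv <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    data.frame(unit_id = tb$unit_id, sex = tb$sex,
               age_group = tb$scheme$labels,
               cases = fmt_full(tb$cases),
               population = fmt_full(tb$population),
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
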