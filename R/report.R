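# FNV-1a over a character representation; enough to fingerprint a config.
# 32-bit arithmetic done in 16-bit halves: R has no unsigned 32-bit ints.
fnv1a_hash <- function(x) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 +
      bitwXor(a %% 65536, b %% 65536)
  }
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run manifest
#'
#' Provenance record attached to every rendered report: input paths,
#' seed, configuration fingerprint, per-sex eligible counts and
#' thresholds, package version and timestamp.
#'
#' @param analysis A [run_divergence_analysis()] object.
#' @param inputs Named character vector of input file paths (may be
#'   empty for in-memory runs).
#' @param config Any configuration object to fingerprint.
#' @param timestamp Override the timestamp (useful for reproducible
#'   reports).
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(analysis, inputs = character(0), config = NULL,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  stopifnot(inherits(analysis, "divergence_analysis"))
  plans <- lapply(analysis$plans, function(p)
    if (is.null(p)) NULL else list(n_eligible = p$n_eligible,
                                   threshold = p$threshold))
  seeds <- vapply(analysis$curves, function(cv)
    if (is.null(cv$settings)) NA_integer_ else cv$settings$seed, integer(1))
  structure(
    list(inputs = inputs,
         config_hash = fnv1a_hash(config),
         seed = unname(seeds[1]),
         version = as.character(utils::packageVersion("earlyonset")),
         alpha = analysis$alpha, mode = analysis$mode,
         plans = plans, timestamp = timestamp),
    class = "run_manifest"
  )
}

#' Quick single-area threshold check
#'
#' The quick workflow: once the median age of any population and the
#' corresponding median age at onset are known, the fitted standard
#' curve immediately gives the probability of an onset that early (or
#' late). The comparison is against the uncorrected alpha — a single
#' comparison, no multiplicity family — and the result is labeled
#' accordingly.
#'
#' @param curve A fitted `standard_curve`, or a [median_pairs()] data
#'   frame of reference registries from which one is fitted.
#' @param x Median population age of the area, years.
#' @param y Median onset age of the area, years.
#' @param n_cases Incident-case count of the area; must exceed 1.
#' @param alpha Uncorrected significance level; default 0.05.
#' @param mode PP mode; default "predictive".
#' @param ... Passed to [fit_standard_curve()] when `curve` is a pair
#'   table.
#' @return A one-row divergence result data frame (with
#'   `threshold_basis = "uncorrected"`).
#' @export
check_single_area <- function(curve, x, y, n_cases, alpha = 0.05,
                              mode = c("predictive", "parameter"), ...) {
  mode <- match.arg(mode)
  if (inherits(curve, "median_pairs")) {
    curve <- fit_standard_curve(curve, ...)
  }
  stopifnot(inherits(curve, "standard_curve"))
  if (is.na(n_cases) || n_cases <= 1) {
    stop("area not eligible: more than 1 incident case is required",
         call. = FALSE)
  }
  if (is.na(y)) stop("area not eligible: onset median is undefined",
                     call. = FALSE)
  pair <- list(x = x, y = y)
  rs <- residual_summary(curve, pair, mode = mode)
  pp <- posterior_probability(curve, pair, mode = mode)
  plan <- testing_plan(alpha, 1L)
  cl <- classify_unit(rs$residual, pp, plan)
  out <- divergence_row(
    "single-area", curve$sex, n_cases, NA_real_, x, y,
    expected = expected_onset(curve, x), residual = rs$residual, ci = rs$ci,
    pp = pp,
    pp_predictive = posterior_probability(curve, pair, mode = "predictive"),
    pp_parameter = posterior_probability(curve, pair, mode = "parameter"),
    eligible = TRUE, significant_early = cl$significant_early,
    significant_late = cl$significant_late, category = cl$category)
  out$threshold_basis <- "uncorrected"
  out
}

round_display <- function(results) {
  out <- results
  for (cc in c("x", "y_observed", "expected", "residual", "ci_low", "ci_high")) {
    if (cc %in% names(out)) out[[cc]] <- round(out[[cc]], 1)
  }
  for (cc in c("pp", "pp_predictive", "pp_parameter")) {
    if (cc %in% names(out)) out[[cc]] <- signif(out[[cc]], 5)
  }
  out
}

#' Render a full report
#'
#' Writes machine-readable CSV and JSON reports (full precision), an
#' optional GeoJSON attribute join, and a human-readable text summary
#' listing significant-early and significant-late units per sex
#' (residuals shown to 1 decimal, PPs to 5 significant digits). Given
#' the same analysis and manifest the outputs are byte-identical.
#'
#' @param analysis A [run_divergence_analysis()] object.
#' @param manifest A [run_manifest()].
#' @param out_prefix Path prefix; files `<prefix>.csv`, `<prefix>.json`,
#'   `<prefix>_summary.txt`, `<prefix>_manifest.json` (and
#'   `<prefix>.geojson`) are written.
#' @param polygons Optional GeoJSON FeatureCollection path for the
#'   attribute join.
#' @param mask_small_counts Mask case counts <= 3 in the human-readable
#'   summary (privacy convention for sparse registry tables); machine
#'   output is never masked.
#' @return Named character vector of written paths, invisibly.
#' @export
render_report <- function(analysis, manifest, out_prefix, polygons = NULL,
                          mask_small_counts = FALSE) {
  stopifnot(inherits(analysis, "divergence_analysis"),
            inherits(manifest, "run_manifest"))
  results <- analysis$results
  paths <- c(csv = paste0(out_prefix, ".csv"),
             json = paste0(out_prefix, ".json"),
             summary = paste0(out_prefix, "_summary.txt"),
             manifest = paste0(out_prefix, "_manifest.json"))
  write_report(results, paths["csv"], "csv")
  write_report(results, paths["json"], "json")
  jsonlite::write_json(unclass(manifest), paths["manifest"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(polygons)) {
    paths <- c(paths, geojson = paste0(out_prefix, ".geojson"))
    write_report(results, paths["geojson"], "geojson", polygons = polygons)
  }

  disp <- round_display(results)
  lines <- c(
    sprintf("Divergence report (version %s, config %s, seed %s)",
            manifest$version, manifest$config_hash, manifest$seed),
    sprintf("PP mode: %s; familywise alpha = %g", analysis$mode, analysis$alpha)
  )
  for (s in names(analysis$plans)) {
    pl <- analysis$plans[[s]]
    lines <- c(lines, "", sprintf("== %s ==", s))
    if (is.null(pl)) {
      lines <- c(lines, "no eligible study units; threshold not computed")
      next
    }
    lines <- c(lines, sprintf("%d eligible areas; Bonferroni threshold %.5g",
                              pl$n_eligible, pl$threshold))
    for (direction in c("early", "late")) {
      flag <- disp[[paste0("significant_", direction)]] & disp$sex == s
      lines <- c(lines, sprintf("significant %s onset: %d area(s)",
                                direction, sum(flag, na.rm = TRUE)))
      for (i in which(flag)) {
        ncase <- if (mask_small_counts && disp$n_cases[i] <= 3) "<=3"
                 else format(disp$n_cases[i])
        lines <- c(lines, sprintf(
          "  %s: residual %+.1f years (95%% CI %.1f ; %.1f), PP %.5g, cases %s [%s]",
          disp$unit_id[i], disp$residual[i], disp$ci_low[i], disp$ci_high[i],
          disp$pp[i], ncase, disp$category[i]))
      }
    }
  }
  writeLines(lines, paths["summary"])
  invisible(paths)
}
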