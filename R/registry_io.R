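#' Read age-binned registry tables from CSV
#'
#' Expects one row per (unit, sex, age bin) with case and population
#' counts, the layout used by registry incidence exports. Column names can
#' be remapped through `layout` to accommodate other dialects.
#'
#' Bins absent from the file are filled with zero counts (with a warning
#' naming the unit); duplicated (unit, sex, bin) rows and negative counts
#' are rejected. Non-integer population values are accepted (mid-period
#' estimates); non-integer case counts are rejected.
#'
#' @param path CSV file path.
#' @param layout Named list mapping the roles `unit`, `sex`, `age`,
#'   `cases`, `population` to column names in the file. Defaults to
#'   `unit_id`, `sex`, `age_group`, `cases`, `population`.
#' @param scheme An [age_bin_scheme()].
#' @return A list of [age_binned_table()] objects, named `"unit|sex"`.
#' @export
read_binned_tables <- function(path, layout = NULL, scheme = age_bin_scheme()) {
  default <- list(unit = "unit_id", sex = "sex", age = "age_group",
                  cases = "cases", population = "population")
  if (!is.null(layout)) default[names(layout)] <- layout
  layout <- default

  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  missing_cols <- setdiff(unlist(layout), names(df))
  if (length(missing_cols)) {
    stop("CSV '", path, "' lacks column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }

  unit <- as.character(df[[layout$unit]])
  sex <- normalize_sex(df[[layout$sex]])
  bin <- match_age_labels(df[[layout$age]], scheme)
  cases <- df[[layout$cases]]
  population <- df[[layout$population]]

  bad <- which(!is.finite(cases) | cases < 0 | !is.finite(population) | population < 0)
  if (length(bad)) {
    stop("negative or non-finite count at data line ", bad[1],
         " (unit ", unit[bad[1]], ")", call. = FALSE)
  }
  key <- paste(unit, sex, sep = "|")
  dup <- duplicated(cbind(key, bin))
  if (any(dup)) {
    stop("duplicate (unit, sex, age bin) rows, e.g. unit ", unit[which(dup)[1]],
         " bin ", scheme$labels[bin[which(dup)[1]]], call. = FALSE)
  }

  nb <- length(scheme$labels)
  out <- list()
  for (k in unique(key)) {
    sel <- key == k
    cs <- numeric(nb); ps <- numeric(nb)
    cs[bin[sel]] <- cases[sel]
    ps[bin[sel]] <- population[sel]
    if (sum(sel) < nb) {
      missing_bins <- scheme$labels[setdiff(seq_len(nb), bin[sel])]
      warning("unit ", sub("\\|.*$", "", k), " (", sub("^.*\\|", "", k),
              "): bins ", paste(missing_bins, collapse = ", "),
              " absent from file, filled with 0", call. = FALSE)
    }
    out[[k]] <- age_binned_table(sub("\\|.*$", "", k), sub("^.*\\|", "", k),
                                 cs, ps, scheme)
  }
  out
}

#' Read pre-computed median pairs from CSV
#'
#' Supports users who hold only the medians (e.g. from registry reports
#' with exact ages): columns `unit_id`, `sex`, `median_population_age`,
#' `median_onset_age` (may be empty when undefined), `n_cases`,
#' `n_population`.
#'
#' @param path CSV file path.
#' @return A [median_pairs()] data frame.
#' @export
read_median_pairs <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("malformed CSV '", path, "': ", conditionMessage(e),
                             call. = FALSE)
  )
  need <- c("unit_id", "sex", "median_population_age", "median_onset_age",
            "n_cases", "n_population")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("CSV '", path, "' lacks column(s): ",
         paste(sQuote(missing_cols), collapse = ", "), call. = FALSE)
  }
  x <- suppressWarnings(as.numeric(df$median_population_age))
  if (anyNA(x)) {
    stop("median_population_age missing or non-numeric at data line ",
         which(is.na(x))[1], " — the predictor is mandatory", call. = FALSE)
  }
  y <- suppressWarnings(as.numeric(df$median_onset_age))  # empty -> NA: undefined
  median_pairs(df$unit_id, df$sex, x, y, df$n_cases, df$n_population)
}

# full-precision numeric formatting so CSV round-trips are exact
fmt_full <- function(v) {
  ifelse(is.na(v), "", sprintf("%.17g", v))
}

#' Write median pairs to CSV
#'
#' Numeric fields are written with 17 significant digits so that
#' [read_median_pairs()] reproduces them exactly.
#'
#' @param pairs A [median_pairs()] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_median_pairs <- function(pairs, path) {
  stopifnot(inherits(pairs, "median_pairs"))
  out <- data.frame(
    unit_id = pairs$unit_id, sex = pairs$sex,
    median_population_age = fmt_full(pairs$x),
    median_onset_age = fmt_full(pairs$y),
    n_cases = fmt_full(pairs$n_cases),
    n_population = fmt_full(pairs$n_population),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

results_frame <- function(results) {
  stopifnot(is.data.frame(results), nrow(results) > 0)
  results
}

#' Write a divergence report
#'
#' One record per study unit with the residual (years early/late), its 95%
#' credibility interval, the posterior probability, significance flags and
#' the five-level map category. Units without a defined onset median are
#' written with empty numeric fields and status "insufficient cases".
#'
#' @param results The `results` data frame of a [run_divergence_analysis()]
#'   object (or the object itself).
#' @param path Output file path.
#' @param format "csv", "json", or "geojson" (attribute join onto
#'   user-supplied polygon features).
#' @param polygons For `format = "geojson"`: path to a GeoJSON
#'   FeatureCollection whose features carry a `unit_id` property. Matched
#'   features get the report fields appended to their properties;
#'   unmatched report units are listed in a warning.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json", "geojson"),
                         polygons = NULL) {
  if (inherits(results, "divergence_analysis")) results <- results$results
  results <- results_frame(results)
  format <- match.arg(format)

  if (format == "csv") {
    out <- results
    numcols <- names(out)[vapply(out, is.numeric, logical(1))]
    for (cc in numcols) out[[cc]] <- fmt_full(out[[cc]])
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else if (format == "json") {
    jsonlite::write_json(results, path, auto_unbox = FALSE, digits = NA,
                         na = "null", dataframe = "rows", pretty = TRUE)
  } else {
    if (is.null(polygons)) stop("geojson format requires a polygons file",
                                call. = FALSE)
    gj <- jsonlite::read_json(polygons)
    if (is.null(gj$features)) stop("'", polygons, "' is not a GeoJSON FeatureCollection",
                                   call. = FALSE)
    feat_ids <- vapply(gj$features, function(f) {
      id <- f$properties$unit_id
      if (is.null(id)) NA_character_ else as.character(id)
    }, character(1))
    matched <- character(0)
    for (i in seq_along(gj$features)) {
      j <- match(feat_ids[i], results$unit_id)
      if (is.na(j)) next
      matched <- c(matched, feat_ids[i])
      add <- as.list(results[j, setdiff(names(results), "unit_id")])
      add[vapply(add, function(v) length(v) == 1 && is.na(v), logical(1))] <- NULL
      gj$features[[i]]$properties <- c(gj$features[[i]]$properties, add)
    }
    orphans <- setdiff(results$unit_id, matched)
    if (length(orphans)) {
      warning("no polygon feature for unit(s): ",
              paste(orphans, collapse = ", "), call. = FALSE)
    }
    jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  invisible(path)
}

#' Re-read a CSV divergence report
#'
#' Inverse of [write_report()] with `format = "csv"`; restores numeric and
#' logical column types at full precision.
#'
#' @param path CSV report path.
#' @return A data frame.
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cc in names(df)) {
    if (cc %in% c("unit_id", "sex", "category", "status", "pp_mode")) next
    if (all(df[[cc]] %in% c("TRUE", "FALSE", NA))) {
      df[[cc]] <- as.logical(df[[cc]])
    } else {
      df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
    }
  }
  df
}
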