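#' Quinquennial age-bin scheme
#'
#' The canonical age grouping used by cancer-registry incidence tables:
#' half-open five-year bins `[0,5), [5,10), ..., [80,85)` plus one open
#' top bin `[85, Inf)`. Both cases and resident population are tabulated
#' on this scheme.
#'
#' @param width Width of the closed bins in years. Default 5.
#' @param top Lower edge of the open top bin in years. Default 85.
#' @return An object of class `age_bin_scheme`: a list with `edges`
#'   (lower bounds, years), `width`, `open_top` (always `TRUE`) and
#'   canonical `labels` ("0-4", ..., "85+").
#' @examples
#' s <- age_bin_scheme()
#' s$labels[c(1, 18)]
#' @export
age_bin_scheme <- function(width = 5, top = 85) {
  stopifnot(width > 0, top > 0, top %% width == 0)
  edges <- seq(0, top, by = width)
  labels <- c(
    paste0(edges[-length(edges)], "-", edges[-length(edges)] + width - 1),
    paste0(top, "+")
  )
  structure(
    list(edges = edges, width = width, open_top = TRUE, labels = labels),
    class = "age_bin_scheme"
  )
}

#' @export
print.age_bin_scheme <- function(x, ...) {
  cat(sprintf(
    "<age_bin_scheme> %d closed bins of %g years + open bin [%g, Inf): %s ... %s\n",
    length(x$edges) - 1, x$width, x$edges[length(x$edges)],
    x$labels[1], x$labels[length(x$labels)]
  ))
  invisible(x)
}

#' Match age-group labels to scheme bins
#'
#' Accepts the canonical dialect ("0-4", "85+") plus common registry-export
#' variants: en dashes, surrounding spaces, and a trailing "years".
#'
#' @param labels Character vector of age-group labels.
#' @param scheme An [age_bin_scheme()].
#' @return Integer vector of bin indices; unrecognized labels raise an error.
#' @export
match_age_labels <- function(labels, scheme = age_bin_scheme()) {
  norm <- tolower(trimws(labels))
  norm <- sub("\\s*(years|yrs|y)$", "", norm)
  norm <- gsub("–|—", "-", norm)   # en/em dash -> hyphen
  norm <- gsub("\\s*-\\s*", "-", norm)
  norm <- sub("^>=\\s*", "", norm)
  norm <- sub("^(\\d+)\\+$", "\\1+", norm)
  idx <- match(norm, tolower(scheme$labels))
  # also accept bare lower bounds, e.g. "85" for the top bin written ">=85"
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unrecognized age-group label(s): ", paste(sQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  idx
}

normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- ifelse(s %in% c("male", "m", "men", "1"), "male",
         ifelse(s %in% c("female", "f", "women", "2"), "female", NA_character_))
  if (anyNA(out)) {
    stop("sex must be male/female (or m/f, men/women); got ",
         paste(sQuote(unique(sex[is.na(out)])), collapse = ", "), call. = FALSE)
  }
  out
}

#' Age-binned case/population table for one unit and sex
#'
#' @param unit_id Unit label (registry or small-area id).
#' @param sex "male" or "female" (common variants accepted).
#' @param cases Nonnegative counts of incident cases per bin.
#' @param population Nonnegative resident-population counts per bin; may be
#'   a non-integer mid-period estimate.
#' @param scheme An [age_bin_scheme()].
#' @return An object of class `age_binned_table`.
#' @export
age_binned_table <- function(unit_id, sex, cases, population,
                             scheme = age_bin_scheme()) {
  nb <- length(scheme$labels)
  if (length(cases) != nb || length(population) != nb) {
    stop("cases and population must have one entry per bin (", nb, ")",
         call. = FALSE)
  }
  if (any(!is.finite(cases)) || any(cases < 0)) {
    stop("cases must be finite and nonnegative", call. = FALSE)
  }
  if (any(cases != round(cases))) {
    stop("cases must be integer counts", call. = FALSE)
  }
  if (any(!is.finite(population)) || any(population < 0)) {
    stop("population must be finite and nonnegative", call. = FALSE)
  }
  structure(
    list(unit_id = as.character(unit_id), sex = normalize_sex(sex),
         cases = as.numeric(cases), population = as.numeric(population),
         scheme = scheme),
    class = "age_binned_table"
  )
}

#' @export
print.age_binned_table <- function(x, ...) {
  cat(sprintf("<age_binned_table> %s (%s): %g cases, %g population in %d bins\n",
              x$unit_id, x$sex, sum(x$cases), sum(x$population),
              length(x$scheme$labels)))
  invisible(x)
}
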