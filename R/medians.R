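#' Grouped median by linear interpolation
#'
#' Estimates the median of an age distribution given only per-bin counts,
#' by the classical interpolation formula
#' \deqn{m = L + \frac{N/2 - CF}{f} \, h,}
#' where `L` is the lower edge of the median bin, `CF` the cumulative count
#' below it, `f` the count in it, and `h` the bin width. This equals the
#' exact median of the continuum density that spreads each bin's count
#' uniformly over the bin.
#'
#' The median bin is the first bin whose cumulative count strictly exceeds
#' N/2; when N/2 falls exactly on a bin edge the formula is therefore
#' applied in the bin above the edge and returns its lower edge (the upper
#' endpoint of the continuum median set). If the median bin is the open top
#' bin the median has no defined value and the estimate is flagged
#' undefined rather than extrapolated.
#'
#' @param counts Nonnegative per-bin counts (cases or population); need not
#'   be integer.
#' @param scheme An [age_bin_scheme()].
#' @return A list of class `grouped_median_estimate` with `value` (years,
#'   `NA` when undefined), `bin_index`, `n` (total count) and `open_top`
#'   (`TRUE` when the median falls in the open bin).
#' @examples
#' s <- age_bin_scheme()
#' counts <- numeric(18); counts[13] <- 10  # all mass in [60, 65)
#' grouped_median(counts, s)$value          # 62.5
#' @export
grouped_median <- function(counts, scheme = age_bin_scheme()) {
  nb <- length(scheme$labels)
  if (length(counts) != nb) {
    stop("counts must have one entry per bin (", nb, ")", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  n <- sum(counts)
  if (n <= 0) stop("no observations: total count is zero", call. = FALSE)

  cum <- cumsum(counts)
  j <- which(cum > n / 2)[1]
  if (j == nb) {
    # median sits in (or exactly at the lower edge of) the open top bin
    return(structure(
      list(value = NA_real_, bin_index = j, n = n, open_top = TRUE),
      class = "grouped_median_estimate"
    ))
  }
  L <- scheme$edges[j]
  cf <- cum[j] - counts[j]
  value <- L + (n / 2 - cf) / counts[j] * scheme$width
  structure(
    list(value = value, bin_index = j, n = n, open_top = FALSE),
    class = "grouped_median_estimate"
  )
}

#' @export
print.grouped_median_estimate <- function(x, ...) {
  if (x$open_top) {
    cat(sprintf("<grouped_median> undefined (median in open top bin), n = %g\n",
                x$n))
  } else {
    cat(sprintf("<grouped_median> %.3f years (bin %d), n = %g\n",
                x$value, x$bin_index, x$n))
  }
  invisible(x)
}

#' Collection of (population median, onset median) pairs
#'
#' Builds the canonical pair table: one row per unit and sex, with the
#' median age of the resident population (`x`, the predictor), the median
#' age at cancer onset (`y`, the response; `NA` when too few cases or when
#' the median falls in the open top bin), and the underlying totals.
#'
#' @param unit_id,sex,x,y,n_cases,n_population Vectors of equal length.
#' @return A `data.frame` of class `median_pairs`.
#' @export
median_pairs <- function(unit_id, sex, x, y, n_cases, n_population) {
  sex <- normalize_sex(sex)
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("median population age x must be finite and nonnegative", call. = FALSE)
  }
  if (any(n_cases < 0) || any(n_population < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  df <- data.frame(
    unit_id = as.character(unit_id), sex = sex,
    x = as.numeric(x), y = as.numeric(y),
    n_cases = as.numeric(n_cases), n_population = as.numeric(n_population),
    stringsAsFactors = FALSE
  )
  class(df) <- c("median_pairs", "data.frame")
  df
}

#' Reduce an age-binned table to its median pair
#'
#' @param table An [age_binned_table()].
#' @return A one-row [median_pairs()] data frame. `y` is `NA` when there
#'   are no cases or the case median falls in the open top bin (a warning
#'   is issued in the latter situation).
#' @export
median_pair_from_table <- function(table) {
  stopifnot(inherits(table, "age_binned_table"))
  if (sum(table$population) <= 0) {
    stop("unit ", table$unit_id, ": total population is zero, population median undefined",
         call. = FALSE)
  }
  gx <- grouped_median(table$population, table$scheme)
  if (gx$open_top) {
    stop("unit ", table$unit_id, ": population median falls in the open top bin",
         call. = FALSE)
  }
  n_cases <- sum(table$cases)
  y <- NA_real_
  if (n_cases >= 1) {
    gy <- grouped_median(table$cases, table$scheme)
    if (gy$open_top) {
      warning("unit ", table$unit_id, " (", table$sex,
              "): onset median falls in the open top bin; treated as undefined",
              call. = FALSE)
    } else {
      y <- gy$value
    }
  }
  median_pairs(table$unit_id, table$sex, gx$value, y,
               n_cases, sum(table$population))
}
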