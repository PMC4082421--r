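#' Absolute minute differences from a result table
#'
#' Extracts the absolute algorithm-vs-reference differences for every
#' patient with both times, and reports how many were excluded for a
#' missing time (never silently dropped).
#'
#' @param results Result tibble ([read_results()] schema).
#' @return List with `diffs` (integer vector) and `n_excluded`.
#' @export
time_differences <- function(results) {
  validate_results(results)
  both <- !is.na(results$algorithm_time) & !is.na(results$reference_time)
  diffs <- abs(minute_diff(results$algorithm_time[both],
                           results$reference_time[both]))
  list(diffs = diffs, n_excluded = sum(!both))
}

#' Percent agreement at a tolerance
#'
#' `100 * #\{d <= tolerance\} / n`, returned exact (unrounded). Reported
#' figures round half away from zero to the nearest integer percent; use
#' [round_half_away()].
#'
#' @param diffs Integer vector of absolute minute differences.
#' @param tolerance Tolerance in minutes.
#' @return Exact percent (numeric scalar).
#' @export
percent_agreement <- function(diffs, tolerance) {
  if (length(diffs) == 0) vz_abort("empty difference multiset")
  100 * mean(diffs <= tolerance)
}

#' Agreement curve over a tolerance grid
#'
#' Percent agreement at each tolerance; non-decreasing by construction.
#'
#' @param diffs Integer vector of absolute minute differences.
#' @param tolerances Ordered tolerance grid in minutes.
#' @return Tibble `tolerance_min`, `percent` (exact), `percent_rounded`.
#' @export
agreement_curve <- function(diffs, tolerances = c(0, 1, 2, 3, 4, 5, 10, 15, 30, 60)) {
  if (length(diffs) == 0) vz_abort("empty difference multiset")
  tolerances <- sort(unique(tolerances))
  pct <- vapply(tolerances, function(t) percent_agreement(diffs, t), numeric(1))
  tibble::tibble(tolerance_min = tolerances, percent = pct,
                 percent_rounded = as.integer(round_half_away(pct)))
}

#' Kappa agreement statistic
#'
#' Two conventions are provided.
#'
#' `"zero_chance"` (default) takes chance agreement as nil, so kappa equals
#' the observed proportion of patients whose times agree within `tolerance`
#' minutes. This reproduces reported clinical-agreement kappas that
#' numerically equal the percent agreement: with times on a minute grid
#' spread over months of admissions, the probability of two raters matching
#' by chance is negligible.
#'
#' `"minute_category"` is the textbook Cohen computation, treating each
#' rater's per-patient minute as a nominal category: `p_o` is the observed
#' within-tolerance agreement and `p_e` sums the products of the two
#' raters' marginal category frequencies over all category pairs within the
#' tolerance. It requires the paired times, i.e. a result table.
#'
#' @param x Integer vector of absolute differences (zero_chance only) or a
#'   result tibble with both time columns (either convention).
#' @param tolerance Agreement tolerance in minutes.
#' @param convention `"zero_chance"` or `"minute_category"`.
#' @return Kappa value in \[-1, 1\].
#' @export
agreement_kappa <- function(x, tolerance = 0,
                            convention = c("zero_chance", "minute_category")) {
  convention <- match.arg(convention)
  if (is.data.frame(x)) {
    td <- time_differences(x)
    diffs <- td$diffs
  } else {
    diffs <- x
  }
  if (length(diffs) == 0) vz_abort("empty difference multiset")
  p_o <- mean(diffs <= tolerance)
  if (convention == "zero_chance") {
    return(p_o)
  }
  if (!is.data.frame(x)) {
    vz_abort("minute_category kappa needs the paired times (a result table), not bare differences")
  }
  both <- !is.na(x$algorithm_time) & !is.na(x$reference_time)
  a <- as.numeric(x$algorithm_time[both]) / 60
  r <- as.numeric(x$reference_time[both]) / 60
  cats <- sort(unique(c(a, r)))
  pa <- tabulate(match(a, cats), length(cats)) / length(a)
  pr <- tabulate(match(r, cats), length(cats)) / length(r)
  within <- abs(outer(cats, cats, "-")) <= tolerance
  p_e <- sum(outer(pa, pr) * within)
  if (p_e >= 1) return(if (p_o >= 1) 1 else NaN)
  (p_o - p_e) / (1 - p_e)
}

#' Summarize algorithm-vs-reference agreement
#'
#' Aggregates the agreement statistics for a result table: evaluable and
#' excluded counts, rounded percent agreement at 0/1/5 minutes, the maximum
#' absolute difference, kappa (zero-chance convention at tolerance 0,
#' rounded to two decimals) and the full agreement curve.
#'
#' @param results Result tibble.
#' @param tolerances Tolerance grid for the curve.
#' @param kappa_convention Convention passed to [agreement_kappa()].
#' @return An object of class `agreement_summary`: a list with fields
#'   `n_evaluable`, `n_excluded_missing`, `pct_exact`, `pct_within_1min`,
#'   `pct_within_5min`, `max_abs_diff`, `kappa` and `curve`.
#' @export
summarize_agreement <- function(results,
                                tolerances = c(0, 1, 2, 3, 4, 5, 10, 15, 30, 60),
                                kappa_convention = "zero_chance") {
  td <- time_differences(results)
  if (length(td$diffs) == 0) {
    vz_abort("no evaluable results (all missing a time)")
  }
  curve <- agreement_curve(td$diffs, tolerances)
  out <- list(
    n_evaluable = length(td$diffs),
    n_excluded_missing = td$n_excluded,
    pct_exact = as.integer(round_half_away(percent_agreement(td$diffs, 0))),
    pct_within_1min = as.integer(round_half_away(percent_agreement(td$diffs, 1))),
    pct_within_5min = as.integer(round_half_away(percent_agreement(td$diffs, 5))),
    max_abs_diff = max(td$diffs),
    kappa = round_half_away(
      agreement_kappa(if (kappa_convention == "zero_chance") td$diffs else results,
                      tolerance = 0, convention = kappa_convention), 2),
    curve = curve)
  structure(out, class = "agreement_summary")
}

#' @export
print.agreement_summary <- function(x, ...) {
  cat("Agreement summary\n")
  cat(sprintf("  evaluable patients: %d (excluded for missing time: %d)\n",
              x$n_evaluable, x$n_excluded_missing))
  cat(sprintf("  exact match:        %d%%\n", x$pct_exact))
  cat(sprintf("  within 1 minute:    %d%%\n", x$pct_within_1min))
  cat(sprintf("  within 5 minutes:   %d%%\n", x$pct_within_5min))
  cat(sprintf("  max |difference|:   %d min\n", x$max_abs_diff))
  cat(sprintf("  kappa:              %.2f\n", x$kappa))
  invisible(x)
}

#' Write an agreement summary as JSON (plus optional curve CSV)
#'
#' @param summary An `agreement_summary`.
#' @param path Output JSON path.
#' @param curve_path Optional CSV path for the agreement curve
#'   (`tolerance_min,percent`).
#' @return `path`, invisibly.
#' @export
write_agreement_summary <- function(summary, path, curve_path = NULL) {
  stopifnot(inherits(summary, "agreement_summary"))
  obj <- unclass(summary)
  obj$curve <- NULL
  obj$curve <- stats::setNames(as.list(summary$curve$percent),
                               as.character(summary$curve$tolerance_min))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(curve_path)) {
    readr::write_csv(summary$curve[, c("tolerance_min", "percent")], curve_path)
  }
  invisible(path)
}
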