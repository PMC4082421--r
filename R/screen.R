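#' Search configuration
#'
#' Tunable parameters of the screening and detection steps.
#'
#' @param completeness_threshold Minimum fraction of cohort patients that
#'   must have at least one queryable record of a candidate variable for it
#'   to survive screening (default 0.85, the "<15% missing data" rule).
#' @param agreement_tolerance_min Screening tolerance in minutes: a
#'   candidate's first-record time counts as agreeing with the reference
#'   when within this many minutes (default 5).
#' @param anchor_mode `"note_anchored"` (default) restricts detection to a
#'   window around the intubation procedure note, falling back to
#'   `"first_in_stay"` with a warning when no note exists;
#'   `"first_in_stay"` searches the whole stay.
#' @param anchor_window_min Half-width of the note-anchored window, minutes.
#' @param pre_icu_gap_min Fallback gap (minutes after admission) used by
#'   [flag_in_icu_initiation()] when the emergent flag is absent.
#' @return An object of class `search_config`.
#' @export
search_config <- function(completeness_threshold = 0.85,
                          agreement_tolerance_min = 5,
                          anchor_mode = c("note_anchored", "first_in_stay"),
                          anchor_window_min = 60,
                          pre_icu_gap_min = 60) {
  anchor_mode <- match.arg(anchor_mode)
  if (completeness_threshold <= 0 || completeness_threshold > 1 ||
      agreement_tolerance_min <= 0 || anchor_window_min <= 0 ||
      pre_icu_gap_min <= 0) {
    vz_abort("all search_config thresholds must be positive", "ventzero_config_error")
  }
  structure(list(completeness_threshold = completeness_threshold,
                 agreement_tolerance_min = agreement_tolerance_min,
                 anchor_mode = anchor_mode,
                 anchor_window_min = anchor_window_min,
                 pre_icu_gap_min = pre_icu_gap_min),
            class = "search_config")
}

#' Completeness of a candidate variable
#'
#' Fraction of cohort patients with at least one record of the variable in
#' the queryable (`datamart`) view during their stay (`[icu_admit,
#' icu_discharge)`). For `"note_time"` it is the fraction of patients whose
#' event row carries a note time.
#'
#' @param flowsheet Flowsheet tibble (both views).
#' @param stays Stay tibble defining the cohort (one row per patient).
#' @param variable One of `"PEEP"`, `"PIP"`, `"ETCO2"`, `"note_time"`.
#' @param events Event tibble; required for `variable = "note_time"`.
#' @return A fraction in \[0, 1\].
#' @export
compute_completeness <- function(flowsheet, stays, variable, events = NULL) {
  if (nrow(stays) == 0) vz_abort("empty cohort", "ventzero_config_error")
  variable <- match.arg(variable, vz_variables)
  if (variable == "note_time") {
    if (is.null(events)) vz_abort("events table required for note_time completeness")
    note <- events$note_time[match(stays$patient_id, events$patient_id)]
    return(mean(!is.na(note)))
  }
  dm <- flowsheet[flowsheet$view == "datamart" &
                    flowsheet$parameter == variable, ]
  j <- match(dm$patient_id, stays$patient_id)
  in_stay <- !is.na(j) & dm$timestamp >= stays$icu_admit[j] &
    dm$timestamp < stays$icu_discharge[j]
  mean(stays$patient_id %in% dm$patient_id[in_stay])
}

## First in-stay datamart record time per cohort patient for one variable;
## for note_time, the note itself. NA when absent.
first_variable_time <- function(flowsheet, stays, variable, events = NULL) {
  if (variable == "note_time") {
    return(events$note_time[match(stays$patient_id, events$patient_id)])
  }
  dm <- flowsheet[flowsheet$view == "datamart" &
                    flowsheet$parameter == variable, ]
  j <- match(dm$patient_id, stays$patient_id)
  keep <- !is.na(j) & dm$timestamp >= stays$icu_admit[j] &
    dm$timestamp < stays$icu_discharge[j]
  dm <- dm[keep, ]
  firsts <- tapply(as.numeric(dm$timestamp), dm$patient_id, min)
  .POSIXct(unname(firsts[stays$patient_id]), tz = "UTC")
}

#' Screen candidate time-zero variables
#'
#' Evaluates each candidate charting variable (intubation note time,
#' end-tidal CO2, PIP, PEEP) on a derivation cohort: variables whose
#' datamart completeness falls below `completeness_threshold` are excluded
#' for missingness and receive no agreement estimate; the rest are scored by
#' percent agreement of their first-record time with the manual reference
#' within `agreement_tolerance_min` minutes.
#'
#' @param stays Stay tibble for the derivation cohort (one row per patient).
#' @param flowsheet Flowsheet tibble (both views).
#' @param events Event tibble.
#' @param reference Tibble `patient_id`, `reference_time` (manual-review
#'   reference standard, e.g. from [reference_time_zero()]).
#' @param config A [search_config()].
#' @return Tibble with one row per candidate: `variable`, `completeness`,
#'   `pct_within_tol` (exact percent, `NA` when excluded), `n_evaluable`,
#'   `excluded_reason` (`"none"` or `"missingness"`).
#' @export
screen_variables <- function(stays, flowsheet, events, reference,
                             config = search_config()) {
  if (nrow(stays) == 0) vz_abort("empty derivation cohort", "ventzero_config_error")
  ref <- reference$reference_time[match(stays$patient_id, reference$patient_id)]
  rows <- lapply(vz_variables, function(v) {
    comp <- compute_completeness(flowsheet, stays, v, events)
    if (comp < config$completeness_threshold) {
      return(tibble::tibble(variable = v, completeness = comp,
                            pct_within_tol = NA_real_, n_evaluable = NA_integer_,
                            excluded_reason = "missingness"))
    }
    tv <- first_variable_time(flowsheet, stays, v, events)
    ok <- !is.na(tv) & !is.na(ref)
    pct <- 100 * mean(abs(minute_diff(tv[ok], ref[ok])) <=
                        config$agreement_tolerance_min)
    tibble::tibble(variable = v, completeness = comp, pct_within_tol = pct,
                   n_evaluable = sum(ok), excluded_reason = "none")
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$excluded_reason == "none")) {
    vz_abort("no candidate variable survives screening", "ventzero_no_candidate")
  }
  out
}

#' Select the search variable from screening reports
#'
#' Returns the surviving candidate with the highest percent agreement; ties
#' are broken by the fixed priority PEEP > PIP > note_time > ETCO2.
#'
#' @param reports Tibble from [screen_variables()].
#' @return A single variable name.
#' @export
select_search_variable <- function(reports) {
  surv <- reports[reports$excluded_reason == "none", ]
  if (nrow(surv) == 0) {
    vz_abort("no candidate variable survives screening", "ventzero_no_candidate")
  }
  priority <- c(PEEP = 4, PIP = 3, note_time = 2, ETCO2 = 1)
  surv <- surv[order(-surv$pct_within_tol, -priority[surv$variable]), ]
  surv$variable[1]
}
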