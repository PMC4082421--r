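#' Detect time zero for one patient
#'
#' Returns the earliest queryable (`datamart`) record time of the search
#' variable. With `anchor_mode = "first_in_stay"` the search spans the stay,
#' `[icu_admit, icu_discharge)`. With `"note_anchored"` it is restricted to
#' the closed window `[note_time - anchor_window_min, note_time +
#' anchor_window_min]`, which keeps an early noninvasive-ventilation PEEP
#' series from masquerading as the intubation; when the patient has no note
#' time the search falls back to the whole stay with a warning.
#'
#' @param patient Patient id.
#' @param stays,events,flowsheet Cohort tables.
#' @param variable Search variable, usually `"PEEP"`.
#' @param config A [search_config()].
#' @return POSIXct time, or `NA` when no qualifying record exists.
#' @export
detect_time_zero <- function(patient, stays, events, flowsheet,
                             variable = "PEEP", config = search_config()) {
  st <- stays[stays$patient_id == patient, ]
  if (nrow(st) == 0) vz_abort(sprintf("unknown patient '%s'", patient))
  if (variable == "note_time") {
    note <- events$note_time[match(patient, events$patient_id)]
    return(if (length(note) == 0) na_time() else note)
  }
  dm <- flowsheet[flowsheet$patient_id == patient &
                    flowsheet$view == "datamart" &
                    flowsheet$parameter == variable, ]
  mode <- config$anchor_mode
  note <- events$note_time[match(patient, events$patient_id)]
  if (mode == "note_anchored" && (length(note) == 0 || is.na(note))) {
    rlang::warn(sprintf(
      "patient '%s': note_anchored requested but no note time; falling back to first_in_stay",
      patient), class = "ventzero_anchor_fallback")
    mode <- "first_in_stay"
  }
  keep <- if (mode == "note_anchored") {
    dm$timestamp >= note - mins(config$anchor_window_min) &
      dm$timestamp <= note + mins(config$anchor_window_min)
  } else {
    dm$timestamp >= st$icu_admit & dm$timestamp < st$icu_discharge
  }
  ts <- dm$timestamp[keep]
  if (length(ts) == 0) na_time() else min(ts)
}

#' Reference time zero for one patient
#'
#' The manual-review reference standard: the earliest peak inspiratory
#' pressure (PIP) record in the complete chart (`full_record` view) during
#' the stay. Returns `NA` when the patient has none; such patients are
#' counted and excluded from agreement statistics, never silently dropped.
#'
#' @param patient Patient id.
#' @param stays,flowsheet Cohort tables.
#' @return POSIXct time or `NA`.
#' @export
reference_time_zero <- function(patient, stays, flowsheet) {
  st <- stays[stays$patient_id == patient, ]
  if (nrow(st) == 0) vz_abort(sprintf("unknown patient '%s'", patient))
  fr <- flowsheet[flowsheet$patient_id == patient &
                    flowsheet$view == "full_record" &
                    flowsheet$parameter == "PIP" &
                    flowsheet$timestamp >= st$icu_admit &
                    flowsheet$timestamp < st$icu_discharge, ]
  if (nrow(fr) == 0) na_time() else min(fr$timestamp)
}

#' Compute time-zero results for a cohort
#'
#' Runs [detect_time_zero()] and [reference_time_zero()] for each patient
#' and assembles the per-patient result table with signed and absolute
#' minute differences (algorithm minus reference). Patients without a note
#' time under `note_anchored` mode trigger a single summary warning.
#'
#' @param patients Character vector of patient ids (normally the in-ICU
#'   initiation subset).
#' @param stays,events,flowsheet Cohort tables.
#' @param variable Search variable, usually `"PEEP"`.
#' @param config A [search_config()].
#' @return Result tibble in the [read_results()] schema.
#' @export
compute_time_zero <- function(patients, stays, events, flowsheet,
                              variable = "PEEP", config = search_config()) {
  n_fallback <- 0L
  alg <- na_time(length(patients))
  for (j in seq_along(patients)) {
    alg[j] <- withCallingHandlers(
      detect_time_zero(patients[j], stays, events, flowsheet, variable, config),
      ventzero_anchor_fallback = function(w) {
        n_fallback <<- n_fallback + 1L
        rlang::cnd_muffle(w)
      })
  }
  if (n_fallback > 0) {
    rlang::warn(sprintf(
      "%d patient(s) had no note time; fell back to first_in_stay detection",
      n_fallback))
  }
  ref <- na_time(length(patients))
  for (j in seq_along(patients)) {
    ref[j] <- reference_time_zero(patients[j], stays, flowsheet)
  }
  both <- !is.na(alg) & !is.na(ref)
  d <- rep(NA_integer_, length(patients))
  d[both] <- minute_diff(alg[both], ref[both])
  tibble::tibble(patient_id = patients, algorithm_time = alg,
                 reference_time = ref, diff_minutes = d,
                 abs_diff_minutes = abs(d))
}
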