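## Readers and writers for the five CSV interchange tables. Every reader
## validates the full type contract and refuses (never silently drops) bad
## rows; errors name the offending file line (header = line 1). Writers
## validate, sort deterministically, and emit ISO-8601 minute timestamps
## with missing values as empty fields.

flowsheet_cols <- c("patient_id", "timestamp", "parameter", "value", "view")
stays_cols <- c("patient_id", "icu_admit", "icu_discharge", "age_years",
                "research_authorization", "first_icu_admission", "unit",
                "calendar_year")
events_cols <- c("patient_id", "true_intubation_time", "location",
                 "emergent_icu_flag", "note_time")
episodes_cols <- c("patient_id", "mode", "start", "end")
results_cols <- c("patient_id", "algorithm_time", "reference_time",
                  "diff_minutes", "abs_diff_minutes")

vz_read_raw <- function(path, expected) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    vz_abort(sprintf("input file not found: %s", path), "ventzero_io_error")
  }
  df <- readr::read_csv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        na = character(), progress = FALSE,
                        show_col_types = FALSE)
  if (!identical(names(df), expected)) {
    vz_abort(sprintf(
      "%s: header mismatch; expected columns %s, found %s",
      path, paste(expected, collapse = ","), paste(names(df), collapse = ",")),
      "ventzero_io_error")
  }
  df
}

## `bad` holds 1-based data-row indices; the file line is one more (header).
abort_lines <- function(bad, what, path) {
  if (length(bad) == 0) return(invisible(NULL))
  lines <- bad + 1L
  vz_abort(sprintf("%s: %s at line%s %s", path, what,
                   if (length(lines) > 1) "s" else "",
                   paste(utils::head(lines, 5), collapse = ", ")),
           "ventzero_io_error")
}

read_time_field <- function(x, field, path, required = FALSE) {
  p <- parse_minute_times(x)
  abort_lines(p$bad, sprintf("malformed timestamp in '%s' (expected YYYY-MM-DDTHH:MM with zero seconds)", field), path)
  if (required) {
    abort_lines(which(is.na(p$times)), sprintf("missing required '%s'", field), path)
  }
  p$times
}

read_enum_field <- function(x, field, levels, path) {
  bad <- which(!(x %in% levels))
  abort_lines(bad, sprintf("unknown %s code (allowed: %s)", field,
                           paste(levels, collapse = ", ")), path)
  x
}

read_logical_field <- function(x, field, path) {
  p <- parse_logical_field(x)
  abort_lines(p$bad, sprintf("invalid logical in '%s'", field), path)
  p$values
}

read_int_field <- function(x, field, path, required = TRUE, min = NULL) {
  blank <- x == ""
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!blank & (is.na(v) | v != floor(v)))
  abort_lines(bad, sprintf("invalid integer in '%s'", field), path)
  if (required) abort_lines(which(blank), sprintf("missing required '%s'", field), path)
  if (!is.null(min)) {
    abort_lines(which(!blank & v < min),
                sprintf("'%s' below %s", field, min), path)
  }
  as.integer(v)
}

check_unique_key <- function(keys, what, path) {
  dup <- which(duplicated(keys))
  if (length(dup) > 0) {
    vz_abort(sprintf("%s: duplicate %s '%s' at line %d", path, what,
                     keys[dup[1]], dup[1] + 1L), "ventzero_io_error")
  }
}

# ---------------------------------------------------------------------------
# flowsheet

#' Read a flowsheet CSV
#'
#' Parses a long-format flowsheet extract: one charted ventilator-parameter
#' value per row, on a one-minute timestamp grid, in one of two views
#' (`datamart`, the queryable extract, or `full_record`, the complete chart a
#' human reviewer sees). All type invariants are enforced; a violating row
#' aborts the read with its file line number.
#'
#' @param path Path to a CSV with columns
#'   `patient_id,timestamp,parameter,value,view`.
#' @return A tibble with typed columns: `timestamp` as UTC POSIXct,
#'   `value` numeric (>= 0), `parameter` one of PEEP/PIP/ETCO2 and `view`
#'   one of datamart/full_record.
#' @export
read_flowsheet <- function(path) {
  df <- vz_read_raw(path, flowsheet_cols)
  ts <- read_time_field(df$timestamp, "timestamp", path, required = TRUE)
  param <- read_enum_field(df$parameter, "parameter", vz_parameters, path)
  view <- read_enum_field(df$view, "view", vz_views, path)
  val <- suppressWarnings(as.numeric(df$value))
  abort_lines(which(is.na(val)), "invalid numeric 'value'", path)
  abort_lines(which(val < 0), "negative 'value'", path)
  check_unique_key(paste(df$patient_id, fmt_time(ts), param, view, sep = "\r"),
                   "(patient_id, timestamp, parameter, view) key", path)
  tibble::tibble(patient_id = df$patient_id, timestamp = ts,
                 parameter = param, value = val, view = view)
}

validate_flowsheet <- function(records) {
  stopifnot(is.data.frame(records), identical(names(records), flowsheet_cols))
  if (nrow(records) == 0) return(invisible(records))
  if (any(is.na(records$timestamp))) vz_abort("flowsheet timestamps must be present")
  if (any(as.numeric(records$timestamp) %% 60 != 0)) {
    vz_abort("flowsheet timestamps must fall on the minute grid")
  }
  if (!all(records$parameter %in% vz_parameters)) vz_abort("unknown parameter code")
  if (!all(records$view %in% vz_views)) vz_abort("unknown view code")
  if (any(is.na(records$value) | records$value < 0)) vz_abort("values must be non-negative")
  key <- paste(records$patient_id, fmt_time(records$timestamp),
               records$parameter, records$view, sep = "\r")
  if (anyDuplicated(key)) vz_abort("duplicate (patient_id, timestamp, parameter, view) key")
  invisible(records)
}

#' Write a flowsheet CSV
#'
#' Validates the record invariants, sorts rows deterministically by
#' (patient_id, timestamp, parameter, view) and writes ISO-8601 minute
#' timestamps.
#'
#' @param records Flowsheet tibble as returned by [read_flowsheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flowsheet <- function(records, path) {
  validate_flowsheet(records)
  out <- records[order(records$patient_id, records$timestamp,
                       records$parameter, records$view), ]
  out$timestamp <- fmt_time(out$timestamp)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# stays

#' Read an ICU-stay CSV
#'
#' One row per ICU admission, with the eligibility attributes used by
#' [filter_study_cohort()].
#'
#' @param path Path to a CSV with columns
#'   `patient_id,icu_admit,icu_discharge,age_years,research_authorization,first_icu_admission,unit,calendar_year`.
#' @return Typed tibble; `icu_admit < icu_discharge` is enforced.
#' @export
read_stays <- function(path) {
  df <- vz_read_raw(path, stays_cols)
  admit <- read_time_field(df$icu_admit, "icu_admit", path, required = TRUE)
  disch <- read_time_field(df$icu_discharge, "icu_discharge", path, required = TRUE)
  abort_lines(which(admit >= disch), "icu_admit not before icu_discharge", path)
  age <- read_int_field(df$age_years, "age_years", path, min = 0)
  auth <- read_logical_field(df$research_authorization, "research_authorization", path)
  first <- read_logical_field(df$first_icu_admission, "first_icu_admission", path)
  unit <- read_enum_field(df$unit, "unit", vz_units, path)
  year <- read_int_field(df$calendar_year, "calendar_year", path)
  check_unique_key(paste(df$patient_id, fmt_time(admit), sep = "\r"),
                   "(patient_id, icu_admit) key", path)
  tibble::tibble(patient_id = df$patient_id, icu_admit = admit,
                 icu_discharge = disch, age_years = age,
                 research_authorization = auth, first_icu_admission = first,
                 unit = unit, calendar_year = year)
}

validate_stays <- function(stays) {
  stopifnot(is.data.frame(stays), identical(names(stays), stays_cols))
  if (nrow(stays) == 0) return(invisible(stays))
  if (any(is.na(stays$icu_admit) | is.na(stays$icu_discharge))) {
    vz_abort("stay bounds must be present")
  }
  if (any(stays$icu_admit >= stays$icu_discharge)) {
    vz_abort("icu_admit must precede icu_discharge")
  }
  if (any(is.na(stays$age_years) | stays$age_years < 0)) vz_abort("invalid age_years")
  if (!all(stays$unit %in% vz_units)) vz_abort("unknown unit code")
  if (anyDuplicated(paste(stays$patient_id, fmt_time(stays$icu_admit), sep = "\r"))) {
    vz_abort("duplicate (patient_id, icu_admit) key")
  }
  invisible(stays)
}

#' Write an ICU-stay CSV
#' @param stays Stay tibble as returned by [read_stays()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stays <- function(stays, path) {
  validate_stays(stays)
  out <- stays[order(stays$patient_id, stays$icu_admit), ]
  out$icu_admit <- fmt_time(out$icu_admit)
  out$icu_discharge <- fmt_time(out$icu_discharge)
  out$research_authorization <- tolower(as.character(out$research_authorization))
  out$first_icu_admission <- tolower(as.character(out$first_icu_admission))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# intubation events

#' Read an intubation-event CSV
#'
#' One row per patient: synthetic ground-truth intubation time (absent for
#' real data), intubation location, the emergent-in-ICU flag produced by the
#' upstream note-search classifier, and the intubation procedure note time.
#'
#' @param path Path to a CSV with columns
#'   `patient_id,true_intubation_time,location,emergent_icu_flag,note_time`.
#' @return Typed tibble. Rows with `emergent_icu_flag = TRUE` must have
#'   `location = "ICU"`.
#' @export
read_events <- function(path) {
  df <- vz_read_raw(path, events_cols)
  tt <- read_time_field(df$true_intubation_time, "true_intubation_time", path)
  loc <- read_enum_field(df$location, "location", vz_locations, path)
  flag <- read_logical_field(df$emergent_icu_flag, "emergent_icu_flag", path)
  note <- read_time_field(df$note_time, "note_time", path)
  abort_lines(which(!is.na(flag) & flag & loc != "ICU"),
              "emergent_icu_flag=true outside the ICU", path)
  check_unique_key(df$patient_id, "patient_id", path)
  tibble::tibble(patient_id = df$patient_id, true_intubation_time = tt,
                 location = loc, emergent_icu_flag = flag, note_time = note)
}

validate_events <- function(events) {
  stopifnot(is.data.frame(events), identical(names(events), events_cols))
  if (nrow(events) == 0) return(invisible(events))
  if (!all(events$location %in% vz_locations)) vz_abort("unknown location code")
  bad <- !is.na(events$emergent_icu_flag) & events$emergent_icu_flag &
    events$location != "ICU"
  if (any(bad)) vz_abort("emergent_icu_flag=true requires location=ICU")
  if (anyDuplicated(events$patient_id)) vz_abort("duplicate patient_id in events")
  invisible(events)
}

#' Write an intubation-event CSV
#' @param events Event tibble as returned by [read_events()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- events[order(events$patient_id), ]
  out$true_intubation_time <- fmt_time(out$true_intubation_time)
  out$note_time <- fmt_time(out$note_time)
  out$emergent_icu_flag <- tolower(as.character(out$emergent_icu_flag))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# ventilation episodes

#' Read a ventilation-episode CSV
#'
#' Intervals of invasive or noninvasive ventilation per patient, interpreted
#' half-open (`[start, end)`). Episodes of one patient may touch but not
#' overlap.
#'
#' @param path Path to a CSV with columns `patient_id,mode,start,end`.
#' @return Typed tibble.
#' @export
read_episodes <- function(path) {
  df <- vz_read_raw(path, episodes_cols)
  mode <- read_enum_field(df$mode, "mode", vz_modes, path)
  start <- read_time_field(df$start, "start", path, required = TRUE)
  end <- read_time_field(df$end, "end", path, required = TRUE)
  abort_lines(which(start >= end), "episode start not before end", path)
  out <- tibble::tibble(patient_id = df$patient_id, mode = mode,
                        start = start, end = end)
  check_episode_overlap(out, path)
  out
}

check_episode_overlap <- function(episodes, path = "episodes") {
  by_pat <- split(seq_len(nrow(episodes)), episodes$patient_id)
  for (idx in by_pat) {
    if (length(idx) < 2) next
    o <- idx[order(episodes$start[idx])]
    if (any(episodes$start[o][-1] < episodes$end[o][-length(o)])) {
      vz_abort(sprintf("%s: overlapping episodes for patient '%s'",
                       path, episodes$patient_id[o[1]]), "ventzero_io_error")
    }
  }
  invisible(episodes)
}

validate_episodes <- function(episodes) {
  stopifnot(is.data.frame(episodes), identical(names(episodes), episodes_cols))
  if (nrow(episodes) == 0) return(invisible(episodes))
  if (!all(episodes$mode %in% vz_modes)) vz_abort("unknown mode code")
  if (any(is.na(episodes$start) | is.na(episodes$end))) vz_abort("episode bounds must be present")
  if (any(episodes$start >= episodes$end)) vz_abort("episode start must precede end")
  check_episode_overlap(episodes)
  invisible(episodes)
}

#' Write a ventilation-episode CSV
#' @param episodes Episode tibble as returned by [read_episodes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_episodes <- function(episodes, path) {
  validate_episodes(episodes)
  out <- episodes[order(episodes$patient_id, episodes$start, episodes$mode), ]
  out$start <- fmt_time(out$start)
  out$end <- fmt_time(out$end)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# time-zero results

#' Read a time-zero result CSV
#'
#' Per-patient algorithm and reference onset times with signed and absolute
#' minute differences. The difference fields must be present exactly when
#' both times are, and must be mutually consistent.
#'
#' @param path Path to a CSV with columns
#'   `patient_id,algorithm_time,reference_time,diff_minutes,abs_diff_minutes`.
#' @return Typed tibble.
#' @export
read_results <- function(path) {
  df <- vz_read_raw(path, results_cols)
  alg <- read_time_field(df$algorithm_time, "algorithm_time", path)
  ref <- read_time_field(df$reference_time, "reference_time", path)
  d <- read_int_field(df$diff_minutes, "diff_minutes", path, required = FALSE)
  ad <- read_int_field(df$abs_diff_minutes, "abs_diff_minutes", path, required = FALSE)
  both <- !is.na(alg) & !is.na(ref)
  abort_lines(which(both != !is.na(d) | both != !is.na(ad)),
              "difference fields must be present exactly when both times are", path)
  abort_lines(which(both & d != minute_diff(alg, ref)),
              "diff_minutes inconsistent with the two times", path)
  abort_lines(which(both & ad != abs(d)),
              "abs_diff_minutes must equal |diff_minutes|", path)
  check_unique_key(df$patient_id, "patient_id", path)
  tibble::tibble(patient_id = df$patient_id, algorithm_time = alg,
                 reference_time = ref, diff_minutes = d, abs_diff_minutes = ad)
}

validate_results <- function(results) {
  stopifnot(is.data.frame(results), identical(names(results), results_cols))
  if (nrow(results) == 0) return(invisible(results))
  both <- !is.na(results$algorithm_time) & !is.na(results$reference_time)
  if (any(both != !is.na(results$diff_minutes)) ||
      any(both != !is.na(results$abs_diff_minutes))) {
    vz_abort("difference fields must be present exactly when both times are")
  }
  if (any(both &
          results$diff_minutes != minute_diff(results$algorithm_time,
                                              results$reference_time))) {
    vz_abort("diff_minutes inconsistent with the two times")
  }
  if (any(both & results$abs_diff_minutes != abs(results$diff_minutes))) {
    vz_abort("abs_diff_minutes must equal |diff_minutes|")
  }
  if (anyDuplicated(results$patient_id)) vz_abort("duplicate patient_id in results")
  invisible(results)
}

#' Write a time-zero result CSV
#' @param results Result tibble as returned by [read_results()] or
#'   [compute_time_zero()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  validate_results(results)
  out <- results[order(results$patient_id), ]
  out$algorithm_time <- fmt_time(out$algorithm_time)
  out$reference_time <- fmt_time(out$reference_time)
  readr::write_csv(out, path, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# empty-table constructors (used by fixtures and tests)

empty_flowsheet <- function() {
  tibble::tibble(patient_id = character(), timestamp = na_time(0),
                 parameter = character(), value = numeric(),
                 view = character())
}

empty_events <- function() {
  tibble::tibble(patient_id = character(), true_intubation_time = na_time(0),
                 location = character(), emergent_icu_flag = logical(),
                 note_time = na_time(0))
}
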