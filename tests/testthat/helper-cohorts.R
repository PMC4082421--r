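# Shared fixtures and oracles. Fixtures are deterministic, so they are
# built once per test run and cached.

vz_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name) {
  if (is.null(vz_cache[[name]])) vz_cache[[name]] <- make_fixture(name)
  vz_cache[[name]]
}

# Run the detection pipeline (flag -> detect vs reference) on a fixture.
fixture_results <- function(name, variable = "PEEP",
                            config = search_config()) {
  key <- paste0("res_", name, "_", variable, "_", config$anchor_mode)
  if (!is.null(vz_cache[[key]])) return(vz_cache[[key]])
  fx <- cached_fixture(name)
  fl <- flag_in_icu_cohort(fx$stays$patient_id, fx$stays, fx$events,
                           fx$flowsheet, config)
  icu <- fl$patient_id[fl$in_icu]
  res <- compute_time_zero(icu, fx$stays, fx$events, fx$flowsheet,
                           variable, config)
  vz_cache[[key]] <- res
  res
}

cached_sim <- function(n = 500, seed = 42) {
  key <- sprintf("sim_%d_%d", n, seed)
  if (is.null(vz_cache[[key]])) {
    vz_cache[[key]] <- simulate_cohort(sim_config(n_patients = n, seed = seed))
  }
  vz_cache[[key]]
}

# Independent oracle: exhaustive row scan, no grouping/joins.
brute_force_detect <- function(patient, stays, events, flowsheet,
                               variable = "PEEP", config = search_config()) {
  st <- stays[stays$patient_id == patient, ]
  note <- events$note_time[events$patient_id == patient]
  mode <- config$anchor_mode
  if (mode == "note_anchored" && (length(note) == 0 || is.na(note))) {
    mode <- "first_in_stay"
  }
  pid <- flowsheet$patient_id
  vw <- flowsheet$view
  par <- flowsheet$parameter
  tss <- as.numeric(flowsheet$timestamp)
  lo <- if (mode == "note_anchored") as.numeric(note) - 60 * config$anchor_window_min
        else as.numeric(st$icu_admit)
  hi <- if (mode == "note_anchored") as.numeric(note) + 60 * config$anchor_window_min
        else as.numeric(st$icu_discharge)
  best <- NA_real_
  for (k in seq_along(tss)) {
    if (pid[k] != patient || vw[k] != "datamart" || par[k] != variable) next
    ok <- if (mode == "note_anchored") tss[k] >= lo && tss[k] <= hi
          else tss[k] >= lo && tss[k] < hi
    if (ok && (is.na(best) || tss[k] < best)) best <- tss[k]
  }
  .POSIXct(best, tz = "UTC")
}

# Minimal valid stay row(s) for hand-built cases.
test_stays <- function(patient_id, admit, discharge = NULL,
                       age = 50L, auth = TRUE, first = TRUE, year = 2010L) {
  admit <- as.POSIXct(admit, tz = "UTC")
  if (is.null(discharge)) discharge <- admit + 3 * 86400
  tibble::tibble(patient_id = patient_id, icu_admit = admit,
                 icu_discharge = as.POSIXct(discharge, tz = "UTC"),
                 age_years = as.integer(age),
                 research_authorization = auth, first_icu_admission = first,
                 unit = "MICU", calendar_year = as.integer(year))
}

test_events <- function(patient_id, true_time = NA, location = "ICU",
                        emergent = TRUE, note = NA) {
  as_t <- function(x) {
    if (length(x) == 1 && is.na(x)) return(.POSIXct(rep(NA_real_, length(patient_id)), tz = "UTC"))
    as.POSIXct(x, tz = "UTC")
  }
  tibble::tibble(patient_id = patient_id, true_intubation_time = as_t(true_time),
                 location = location, emergent_icu_flag = emergent,
                 note_time = as_t(note))
}

test_flow <- function(patient_id, times, parameter = "PEEP", value = 8,
                      view = "datamart") {
  tibble::tibble(patient_id = patient_id,
                 timestamp = as.POSIXct(times, tz = "UTC"),
                 parameter = parameter, value = value, view = view)
}
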