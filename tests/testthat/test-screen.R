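# Hand-built 20-patient screening cohort: completeness and agreement are
# hand-countable. etCO2 on 3/20 patients (0.15), datamart PIP on 8/20
# (0.40), note for all 20 with 9/20 within five minutes, PEEP for all 20
# exactly at the reference.
screen_cohort <- function() {
  n <- 20
  ids <- sprintf("p%02d", seq_len(n))
  base <- as.POSIXct("2010-03-01 08:00", tz = "UTC")
  admit <- base + (seq_len(n) - 1) * 86400
  stays <- dplyr::bind_rows(lapply(seq_len(n), function(i)
    test_stays(ids[i], admit[i])))
  ref_time <- admit + 3600
  note <- ref_time + ifelse(seq_len(n) <= 9, 0, 30) * 60
  events <- tibble::tibble(patient_id = ids, true_intubation_time = ref_time,
                           location = "ICU", emergent_icu_flag = TRUE,
                           note_time = note)
  fs <- dplyr::bind_rows(
    test_flow(ids, ref_time, "PEEP"),
    test_flow(ids[1:8], ref_time[1:8], "PIP", value = 24),
    test_flow(ids[1:3], ref_time[1:3], "ETCO2", value = 38),
    test_flow(ids, ref_time, "PIP", value = 24, view = "full_record"))
  list(stays = stays, events = events, flowsheet = fs,
       reference = tibble::tibble(patient_id = ids, reference_time = ref_time))
}

test_that("compute_completeness counts patients with any queryable record", {
  sc <- screen_cohort()
  expect_equal(compute_completeness(sc$flowsheet, sc$stays, "ETCO2"), 0.15)
  expect_equal(compute_completeness(sc$flowsheet, sc$stays, "PIP"), 0.40)
  expect_equal(compute_completeness(sc$flowsheet, sc$stays, "PEEP"), 1.0)
  expect_equal(compute_completeness(sc$flowsheet, sc$stays, "note_time",
                                    sc$events), 1.0)
  # records outside the stay do not count
  out <- test_flow("p01", sc$stays$icu_admit[1] - 3600, "ETCO2")
  expect_equal(compute_completeness(out, sc$stays[1, ], "ETCO2"), 0)
  expect_error(compute_completeness(sc$flowsheet, sc$stays[0, ], "PEEP"),
               class = "ventzero_config_error")
})

test_that("screening excludes sparse variables and scores the rest", {
  sc <- screen_cohort()
  rep <- screen_variables(sc$stays, sc$flowsheet, sc$events, sc$reference)
  rep <- rep[order(rep$variable), ]
  by_var <- function(v) rep[rep$variable == v, ]
  expect_equal(by_var("ETCO2")$excluded_reason, "missingness")
  expect_equal(by_var("PIP")$excluded_reason, "missingness")
  expect_true(is.na(by_var("ETCO2")$pct_within_tol))
  expect_equal(by_var("note_time")$excluded_reason, "none")
  expect_equal(by_var("note_time")$pct_within_tol, 45)
  expect_equal(by_var("PEEP")$pct_within_tol, 100)
  expect_equal(select_search_variable(rep), "PEEP")
})

test_that("perfectly complete, perfectly agreeing variables all score 100", {
  sc <- screen_cohort()
  ids <- sc$stays$patient_id
  ref_time <- sc$reference$reference_time
  fs <- dplyr::bind_rows(
    test_flow(ids, ref_time, "PEEP"),
    test_flow(ids, ref_time, "PIP", value = 24),
    test_flow(ids, ref_time, "ETCO2", value = 38))
  ev <- sc$events
  ev$note_time <- ref_time
  rep <- screen_variables(sc$stays, fs, ev, sc$reference)
  expect_true(all(rep$excluded_reason == "none"))
  expect_true(all(rep$pct_within_tol == 100))
  # full tie at 100% resolves to PEEP by fixed priority
  expect_equal(select_search_variable(rep), "PEEP")
})

test_that("selection tie-breaks by fixed priority and errors when all excluded", {
  rep <- tibble::tibble(
    variable = c("note_time", "PEEP", "ETCO2"),
    completeness = c(1, 1, 0.1),
    pct_within_tol = c(99, 99, NA),
    n_evaluable = c(20L, 20L, NA),
    excluded_reason = c("none", "none", "missingness"))
  expect_equal(select_search_variable(rep), "PEEP")
  expect_equal(select_search_variable(rep[1, ]), "note_time")
  expect_error(select_search_variable(rep[3, ]), class = "ventzero_no_candidate")
  sc <- screen_cohort()
  expect_error(screen_variables(sc$stays[0, ], sc$flowsheet, sc$events,
                                sc$reference),
               class = "ventzero_config_error")
})

test_that("screening the derivation fixture selects PEEP under the <15% rule", {
  fx <- cached_fixture("derivation")
  fl <- flag_in_icu_cohort(fx$stays$patient_id, fx$stays, fx$events,
                           fx$flowsheet)
  icu <- fl$patient_id[fl$in_icu]
  icu_stays <- fx$stays[fx$stays$patient_id %in% icu, ]
  ref <- tibble::tibble(
    patient_id = icu,
    reference_time = as.POSIXct(vapply(icu, function(p)
      as.numeric(reference_time_zero(p, fx$stays, fx$flowsheet)),
      numeric(1)), origin = "1970-01-01", tz = "UTC"))
  rep <- screen_variables(icu_stays, fx$flowsheet, fx$events, ref)
  excluded <- rep$variable[rep$excluded_reason == "missingness"]
  expect_setequal(excluded, c("ETCO2", "PIP"))
  expect_lt(rep$completeness[rep$variable == "ETCO2"], 0.15)
  expect_lt(rep$completeness[rep$variable == "PIP"], 0.85)
  expect_equal(select_search_variable(rep), "PEEP")
})
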