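test_that("detection returns the earliest qualifying record", {
  stays <- test_stays("a", "2010-02-01 08:00")
  ev <- test_events("a", true_time = stays$icu_admit + 7200)
  cfg <- search_config(anchor_mode = "first_in_stay")
  one <- test_flow("a", "2010-02-01 10:02")
  expect_equal(detect_time_zero("a", stays, ev, one, "PEEP", cfg),
               as.POSIXct("2010-02-01 10:02", tz = "UTC"))
  # min over an unordered set
  three <- test_flow("a", c("2010-02-01 11:00", "2010-02-01 10:02",
                            "2010-02-01 10:05"))
  expect_equal(detect_time_zero("a", stays, ev, three, "PEEP", cfg),
               as.POSIXct("2010-02-01 10:02", tz = "UTC"))
  # no qualifying record -> NA
  expect_true(is.na(detect_time_zero("a", stays, ev, one[0, ], "PEEP", cfg)))
  # records outside [admit, discharge) are ignored
  outside <- test_flow("a", c("2010-01-31 10:00", "2010-02-10 10:00"))
  expect_true(is.na(detect_time_zero("a", stays, ev, outside, "PEEP", cfg)))
})

test_that("note anchoring skips an early NIV PEEP series; first_in_stay does not", {
  # NIV PEEP on day 1, invasive intubation on day 3 with a 09:00 note
  stays <- test_stays("a", "2010-02-01 08:00", "2010-02-06 08:00")
  note <- as.POSIXct("2010-02-03 09:00", tz = "UTC")
  ev <- test_events("a", true_time = note, note = note)
  fs <- dplyr::bind_rows(
    test_flow("a", as.POSIXct("2010-02-01 12:00", tz = "UTC") + (0:5) * 900),
    test_flow("a", note + c(3, 33, 63) * 60))
  anchored <- detect_time_zero("a", stays, ev, fs, "PEEP", search_config())
  expect_equal(anchored, note + 3 * 60)  # earliest PEEP in [08:00, 10:00]
  plain <- detect_time_zero("a", stays, ev, fs, "PEEP",
                            search_config(anchor_mode = "first_in_stay"))
  expect_equal(plain, as.POSIXct("2010-02-01 12:00", tz = "UTC"))
  # the anchored window is closed: a record exactly at note - 60 min counts
  edge <- dplyr::bind_rows(fs, test_flow("a", note - 3600))
  expect_equal(detect_time_zero("a", stays, ev, edge, "PEEP", search_config()),
               note - 3600)
})

test_that("note_anchored without a note falls back with a warning", {
  stays <- test_stays("a", "2010-02-01 08:00")
  ev <- test_events("a", emergent = NA, location = "other")
  fs <- test_flow("a", "2010-02-01 10:02")
  expect_warning(
    out <- detect_time_zero("a", stays, ev, fs, "PEEP", search_config()),
    class = "ventzero_anchor_fallback")
  expect_equal(out, as.POSIXct("2010-02-01 10:02", tz = "UTC"))
  # cohort wrapper condenses the fallbacks into one summary warning
  expect_warning(res <- compute_time_zero("a", stays, ev, fs, "PEEP"),
                 "no note time")
  expect_equal(res$algorithm_time, as.POSIXct("2010-02-01 10:02", tz = "UTC"))
})

test_that("reference standard is the first full-record PIP in the stay", {
  stays <- test_stays("a", "2010-02-01 08:00")
  fs <- dplyr::bind_rows(
    test_flow("a", c("2010-02-01 10:07", "2010-02-01 10:04"), "PIP",
              view = "full_record"),
    test_flow("a", "2010-02-01 09:00", "PIP", view = "datamart"))
  expect_equal(reference_time_zero("a", stays, fs),
               as.POSIXct("2010-02-01 10:04", tz = "UTC"))
  # PIP only in the datamart view -> absent reference
  dm_only <- fs[fs$view == "datamart", ]
  expect_true(is.na(reference_time_zero("a", stays, dm_only)))
})

test_that("detection is monotone under record insertion", {
  stays <- test_stays("a", "2010-02-01 08:00")
  note <- stays$icu_admit + 4 * 3600
  ev <- test_events("a", true_time = note, note = note)
  withr::with_seed(101, {
    for (rep in seq_len(25)) {
      k <- sample(1:8, 1)
      ts <- stays$icu_admit + sort(sample(1:4000, k)) * 60
      fs <- test_flow("a", ts)
      for (cfg in list(search_config(),
                       search_config(anchor_mode = "first_in_stay"))) {
        base <- detect_time_zero("a", stays, ev, fs, "PEEP", cfg)
        # adding a record later than the detected time never changes it
        if (!is.na(base)) {
          later <- dplyr::bind_rows(fs, test_flow("a", max(ts) + 60))
          expect_identical(detect_time_zero("a", stays, ev, later, "PEEP", cfg),
                           base)
        }
        # adding an earlier in-window record can only move the result earlier
        lo <- if (cfg$anchor_mode == "note_anchored") note - 3600
              else stays$icu_admit
        new_ts <- lo + sample(0:30, 1) * 60
        more <- dplyr::bind_rows(fs, test_flow("a", new_ts))
        more <- more[!duplicated(more[c("patient_id", "timestamp",
                                        "parameter", "view")]), ]
        shifted <- detect_time_zero("a", stays, ev, more, "PEEP", cfg)
        expect_true(is.na(base) || shifted <= base)
      }
    }
  })
})

test_that("detection matches a brute-force record scan on a 50-patient cohort", {
  sim <- simulate_cohort(sim_config(n_patients = 50, seed = 17))
  cfgs <- list(search_config(), search_config(anchor_mode = "first_in_stay"))
  for (cfg in cfgs) {
    for (pid in sim$stays$patient_id) {
      fast <- suppressWarnings(
        detect_time_zero(pid, sim$stays, sim$events, sim$flowsheet, "PEEP", cfg))
      slow <- brute_force_detect(pid, sim$stays, sim$events, sim$flowsheet,
                                 "PEEP", cfg)
      expect_equal(as.numeric(fast), as.numeric(slow))
    }
  }
})

test_that("cohort-level results agree with per-patient calls and self-validate", {
  res <- fixture_results("derivation")
  expect_silent(ventzero:::validate_results(res))
  fx <- cached_fixture("derivation")
  for (pid in res$patient_id[c(1, 40, 83)]) {
    expect_equal(res$algorithm_time[res$patient_id == pid],
                 detect_time_zero(pid, fx$stays, fx$events, fx$flowsheet,
                                  "PEEP", search_config()))
    expect_equal(res$reference_time[res$patient_id == pid],
                 reference_time_zero(pid, fx$stays, fx$flowsheet))
  }
})
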