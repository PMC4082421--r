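#' Simulation configuration
#'
#' Parameters of the synthetic ICU cohort generator. The defaults encode the
#' documented charting pathology of real ICU data marts: most intubations
#' happen before ICU arrival (about 82%, and of those about 80% in the
#' operating room); end-tidal CO2 is recorded for only about 15% of
#' patients; peak inspiratory pressure is charted in the full record but
#' missing from the queryable extract for about 60% of patients; and the
#' intubation procedure note is timestamped more than 30 minutes away from
#' the ventilator parameters for about 60% of patients (more than 60 minutes
#' for about 40%).
#'
#' @param n_patients Number of ICU stays to simulate.
#' @param frac_pre_icu_intubation Fraction intubated before ICU arrival.
#' @param frac_or_among_pre_icu Fraction of pre-ICU intubations performed in
#'   the operating room (the rest come from the emergency department).
#' @param etco2_presence_prob Probability a patient has any end-tidal CO2
#'   records.
#' @param pip_datamart_missing_prob Probability the PIP series is absent
#'   from the datamart view (it is always present in the full record).
#' @param note_offset_gt30min_prob Probability the note time differs from
#'   the true onset by more than 30 minutes.
#' @param note_offset_gt60min_prob Probability of a difference above 60
#'   minutes; must not exceed `note_offset_gt30min_prob`. Offsets above 60
#'   minutes are drawn just above the bound (61-65 min) so that a +/- 60
#'   minute note-anchored search window still reaches the minute-dense
#'   charting that follows ventilation onset.
#' @param peep_charting_lag_max Maximum delay, in minutes, between true
#'   onset and the first charted PEEP value (lag uniform on 0..max).
#' @param niv_before_intubation_prob Probability an in-ICU intubation is
#'   preceded by a noninvasive ventilation episode earlier in the stay.
#' @param stay_duration_range Two-element numeric, stay length bounds in
#'   hours.
#' @param seed Integer seed; the generator uses a single RNG stream seeded
#'   from this value and never touches the global RNG state.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 450,
                       frac_pre_icu_intubation = 0.82,
                       frac_or_among_pre_icu = 0.80,
                       etco2_presence_prob = 0.15,
                       pip_datamart_missing_prob = 0.60,
                       note_offset_gt30min_prob = 0.60,
                       note_offset_gt60min_prob = 0.40,
                       peep_charting_lag_max = 5,
                       niv_before_intubation_prob = 0.50,
                       stay_duration_range = c(48, 168),
                       seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              frac_pre_icu_intubation = frac_pre_icu_intubation,
              frac_or_among_pre_icu = frac_or_among_pre_icu,
              etco2_presence_prob = etco2_presence_prob,
              pip_datamart_missing_prob = pip_datamart_missing_prob,
              note_offset_gt30min_prob = note_offset_gt30min_prob,
              note_offset_gt60min_prob = note_offset_gt60min_prob,
              peep_charting_lag_max = as.integer(peep_charting_lag_max),
              niv_before_intubation_prob = niv_before_intubation_prob,
              stay_duration_range = as.numeric(stay_duration_range),
              seed = as.integer(seed))
  fracs <- c("frac_pre_icu_intubation", "frac_or_among_pre_icu",
             "etco2_presence_prob", "pip_datamart_missing_prob",
             "note_offset_gt30min_prob", "note_offset_gt60min_prob",
             "niv_before_intubation_prob")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      vz_abort(sprintf("'%s' must be a fraction in [0, 1]", f), "ventzero_config_error")
    }
  }
  if (cfg$note_offset_gt60min_prob > cfg$note_offset_gt30min_prob) {
    vz_abort("note_offset_gt60min_prob must not exceed note_offset_gt30min_prob",
             "ventzero_config_error")
  }
  if (cfg$n_patients < 1) vz_abort("n_patients must be at least 1", "ventzero_config_error")
  if (cfg$peep_charting_lag_max < 0 || cfg$peep_charting_lag_max > 60) {
    vz_abort("peep_charting_lag_max must be in 0..60 minutes", "ventzero_config_error")
  }
  if (length(cfg$stay_duration_range) != 2 ||
      any(cfg$stay_duration_range <= 0) ||
      diff(cfg$stay_duration_range) < 0 ||
      cfg$stay_duration_range[1] < 48) {
    vz_abort("stay_duration_range must be increasing and start at >= 48 hours",
             "ventzero_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a synthetic ICU cohort
#'
#' Generates stays, ventilation episodes, intubation events (with synthetic
#' ground truth) and flowsheet records in both the queryable `datamart` view
#' and the complete `full_record` view. Timestamps, not physiologic values,
#' are the point: parameter values are plausible constants with jitter.
#'
#' Charting model: the datamart PEEP series starts within
#' `peep_charting_lag_max` minutes of true ventilation onset, runs
#' minute-dense for the first ten minutes (ventilators auto-download on
#' connection), then every 30 minutes until the invasive episode ends.
#' PIP is charted in the full record from onset (0-2 min lag, every 30 min)
#' and copied into the datamart only for patients whose PIP survived
#' extraction. Pre-ICU patients have ventilation records beginning before
#' `icu_admit` and no procedure note; in-ICU patients carry the emergent
#' flag and a note time offset from true onset per the configured exceedance
#' probabilities. A configurable fraction of in-ICU intubations is preceded
#' by a noninvasive episode (with its own PEEP charting) ending at least 75
#' minutes before the intubation.
#'
#' @param config A [sim_config()] object.
#' @return A list with tibbles `stays`, `episodes`, `events`, `flowsheet`
#'   (both views in one table).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    vz_abort("config must be created with sim_config()", "ventzero_config_error")
  }
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_patients
  id <- sprintf("S%05d", seq_len(n))
  base <- vz_time("2010-01-01 00:00")
  admit <- base + mins(floor(runif(n, 0, 729 * 1440)))
  dur_min <- round(runif(n, config$stay_duration_range[1] * 60,
                         config$stay_duration_range[2] * 60))
  discharge <- admit + mins(dur_min)

  pre_icu <- runif(n) < config$frac_pre_icu_intubation
  onset_off <- ifelse(pre_icu,
                      -round(runif(n, 30, 240)),
                      90 + round(runif(n, 0, pmin(dur_min - 180, 2880) - 90)))
  onset <- admit + mins(onset_off)
  lag <- sample(0:config$peep_charting_lag_max, n, replace = TRUE)
  location <- ifelse(pre_icu,
                     ifelse(runif(n) < config$frac_or_among_pre_icu, "OR", "ED"),
                     "ICU")

  # note-time offsets (positive: notes are documented after the procedure),
  # drawn to satisfy the configured >30 min / >60 min exceedance fractions
  u <- runif(n)
  off <- integer(n)
  gt60 <- u < config$note_offset_gt60min_prob
  mid <- !gt60 & u < config$note_offset_gt30min_prob
  low <- !gt60 & !mid
  off[gt60] <- sample(61:65, sum(gt60), replace = TRUE)
  off[mid] <- sample(31:60, sum(mid), replace = TRUE)
  off[low] <- sample(1:30, sum(low), replace = TRUE)
  note <- onset + mins(off)
  note[pre_icu] <- NA

  inv_end <- pmin(onset + mins(round(runif(n, 12 * 60, 96 * 60))), discharge)

  niv_before <- !pre_icu & runif(n) < config$niv_before_intubation_prob
  niv_end <- onset - mins(round(runif(n, 75, 360)))
  niv_start <- pmax(admit, niv_end - mins(round(runif(n, 60, 240))))
  niv_ok <- niv_before & as.numeric(difftime(niv_end, niv_start, units = "mins")) >= 15

  post_start <- inv_end
  post_end <- pmin(post_start + mins(round(runif(n, 2 * 60, 12 * 60))), discharge)
  post_ok <- !niv_ok & as.numeric(difftime(post_end, post_start, units = "mins")) >= 30

  etco2 <- runif(n) < config$etco2_presence_prob
  pip_in_dm <- runif(n) >= config$pip_datamart_missing_prob
  pip_lag <- sample(0:2, n, replace = TRUE)
  peep_base <- sample(5:14, n, replace = TRUE)
  pip_base <- sample(18:32, n, replace = TRUE)
  et_base <- sample(30:42, n, replace = TRUE)

  flows <- vector("list", n)
  for (i in seq_len(n)) {
    peep_ts <- onset[i] + mins(lag[i]:10)
    if (inv_end[i] > onset[i] + mins(40)) {
      peep_ts <- c(peep_ts, seq(onset[i] + mins(40), inv_end[i] - 1, by = 1800))
    }
    niv_ts <- if (niv_ok[i]) seq(niv_start[i], niv_end[i] - 1, by = 900) else peep_ts[0]
    pip_ts <- seq(onset[i] + mins(pip_lag[i]), inv_end[i] - 1, by = 1800)
    et_ts <- if (etco2[i]) onset[i] + mins(c(0, 2, 5, 10)) else peep_ts[0]

    ts <- c(peep_ts, niv_ts, pip_ts, et_ts, pip_ts[pip_in_dm[i]], et_ts)
    par <- c(rep("PEEP", length(peep_ts) + length(niv_ts)),
             rep("PIP", length(pip_ts)), rep("ETCO2", length(et_ts)),
             rep("PIP", length(pip_ts) * pip_in_dm[i]),
             rep("ETCO2", length(et_ts)))
    vw <- c(rep("datamart", length(peep_ts) + length(niv_ts)),
            rep("full_record", length(pip_ts) + length(et_ts)),
            rep("datamart", length(pip_ts) * pip_in_dm[i] + length(et_ts)))
    bases <- c(rep(peep_base[i], length(peep_ts) + length(niv_ts)),
               rep(pip_base[i], length(pip_ts)), rep(et_base[i], length(et_ts)),
               rep(pip_base[i], length(pip_ts) * pip_in_dm[i]),
               rep(et_base[i], length(et_ts)))
    flows[[i]] <- tibble::tibble(
      patient_id = id[i], timestamp = ts, parameter = par,
      value = round(bases + runif(length(ts), -1, 1), 1), view = vw)
  }
  flowsheet <- dplyr::bind_rows(flows)

  stays <- tibble::tibble(
    patient_id = id, icu_admit = admit, icu_discharge = discharge,
    age_years = sample(18:95, n, replace = TRUE),
    research_authorization = TRUE, first_icu_admission = TRUE,
    unit = sample(vz_units, n, replace = TRUE),
    calendar_year = as.integer(format(admit, "%Y")))

  episodes <- dplyr::bind_rows(
    tibble::tibble(patient_id = id, mode = "invasive", start = onset, end = inv_end),
    tibble::tibble(patient_id = id[niv_ok], mode = "noninvasive",
                   start = niv_start[niv_ok], end = niv_end[niv_ok]),
    tibble::tibble(patient_id = id[post_ok], mode = "noninvasive",
                   start = post_start[post_ok], end = post_end[post_ok]))

  events <- tibble::tibble(
    patient_id = id, true_intubation_time = onset, location = location,
    emergent_icu_flag = !pre_icu, note_time = note)

  list(stays = stays, episodes = episodes, events = events,
       flowsheet = flowsheet)
}
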