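#' Filter the study cohort
#'
#' Applies the eligibility rules in sequence and reports per-rule attrition:
#' first ICU admission, at least one ventilation episode overlapping the
#' stay (half-open `[icu_admit, icu_discharge)`), prior research
#' authorization, and age 18 or older. A patient is counted under the first
#' rule that excludes them.
#'
#' @param stays Stay tibble ([read_stays()] schema).
#' @param episodes Episode tibble ([read_episodes()] schema).
#' @return A list with `patients` (character vector of eligible ids, in stay
#'   order), `exclusions` (tibble `rule`, `n_excluded`), `n_input` and
#'   `n_retained`.
#' @export
filter_study_cohort <- function(stays, episodes) {
  validate_stays(stays)
  validate_episodes(episodes)
  # episode overlaps stay: start < discharge and end > admit
  ep <- dplyr::inner_join(episodes, stays, by = "patient_id",
                          relationship = "many-to-many")
  ok <- ep$start < ep$icu_discharge & ep$end > ep$icu_admit
  vented_ids <- unique(ep$patient_id[ok])
  has_vent <- stays$patient_id %in% vented_ids

  excl_first <- !stays$first_icu_admission
  excl_vent <- !excl_first & !has_vent
  excl_auth <- !excl_first & !excl_vent & !stays$research_authorization
  excl_age <- !excl_first & !excl_vent & !excl_auth & stays$age_years < 18
  keep <- !excl_first & !excl_vent & !excl_auth & !excl_age

  list(patients = stays$patient_id[keep],
       exclusions = tibble::tibble(
         rule = c("not_first_admission", "no_ventilation_episode",
                  "no_research_authorization", "under_age"),
         n_excluded = c(sum(excl_first), sum(excl_vent),
                        sum(excl_auth), sum(excl_age))),
       n_input = nrow(stays),
       n_retained = sum(keep))
}

#' Draw a random patient subset from one calendar year
#'
#' Uniform sampling without replacement, deterministic given `seed`. The
#' global RNG state is left untouched.
#'
#' @param stays Stay tibble.
#' @param n Subset size.
#' @param year Calendar year to sample from.
#' @param seed Integer seed.
#' @param patients Optional character vector restricting the sampling frame
#'   (e.g. the eligible set from [filter_study_cohort()]).
#' @return Character vector of `n` patient ids.
#' @export
select_random_subset <- function(stays, n, year, seed, patients = NULL) {
  pool <- stays$patient_id[stays$calendar_year == year]
  if (!is.null(patients)) pool <- pool[pool %in% patients]
  if (n > length(pool)) {
    vz_abort(sprintf("requested %d patients but only %d are eligible in %d",
                     n, length(pool), year), "ventzero_config_error")
  }
  if (n == length(pool)) return(pool)
  withr::with_seed(seed, sample(pool, n))
}

#' Flag in-ICU initiation of mechanical ventilation
#'
#' Decides whether a patient's invasive ventilation began inside the ICU.
#' The decision defers to the emergent-intubation flag supplied in the event
#' table (output of the upstream note-search classifier). When that flag is
#' absent, a labelled fallback heuristic is used: initiation is called
#' in-ICU when the patient's first datamart ventilator-parameter record
#' occurs at least `pre_icu_gap_min` minutes after ICU admission; records at
#' or before admission, or within the gap, indicate the patient arrived
#' already ventilated.
#'
#' @param patient Patient id.
#' @param stays,events,flowsheet Cohort tables.
#' @param config A [search_config()].
#' @return List with `in_icu` (logical) and `reason` (character).
#' @export
flag_in_icu_initiation <- function(patient, stays, events, flowsheet,
                                   config = search_config()) {
  res <- flag_in_icu_cohort(patient, stays, events, flowsheet, config)
  list(in_icu = res$in_icu, reason = res$reason)
}

#' Flag in-ICU initiation for a whole cohort
#'
#' Vectorised form of [flag_in_icu_initiation()].
#'
#' @inheritParams flag_in_icu_initiation
#' @param patients Character vector of patient ids.
#' @return Tibble `patient_id`, `in_icu`, `reason`.
#' @export
flag_in_icu_cohort <- function(patients, stays, events, flowsheet,
                               config = search_config()) {
  out <- tibble::tibble(patient_id = patients, in_icu = NA, reason = NA_character_)
  ev <- events[match(patients, events$patient_id), ]
  flagged <- !is.na(ev$emergent_icu_flag)
  out$in_icu[flagged] <- ev$emergent_icu_flag[flagged]
  out$reason[flagged] <- ifelse(ev$emergent_icu_flag[flagged],
                                "emergent_flag_true", "emergent_flag_false")
  if (any(!flagged)) {
    st <- stays[match(patients, stays$patient_id), ]
    dm <- flowsheet[flowsheet$view == "datamart" &
                      flowsheet$patient_id %in% patients[!flagged], ]
    first_rec <- tapply(as.numeric(dm$timestamp), dm$patient_id, min)
    for (j in which(!flagged)) {
      fr <- first_rec[out$patient_id[j]]
      if (is.na(fr)) {
        out$in_icu[j] <- FALSE
        out$reason[j] <- "no_vent_records"
      } else {
        gap_ok <- fr >= as.numeric(st$icu_admit[j]) + mins(config$pre_icu_gap_min)
        out$in_icu[j] <- gap_ok
        out$reason[j] <- if (gap_ok) "first_record_after_gap" else "first_record_within_gap"
      }
    }
  }
  out
}
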