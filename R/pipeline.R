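## End-to-end workflow: data (fixture or simulation) -> cohort filter ->
## in-ICU flag -> variable screening -> detection -> agreement summary.
## Per-stage patient counts are logged to stderr so cohort attrition is
## always visible.

log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[ventzero] ", fmt), ...))
}

write_run_manifest <- function(out_dir, command, config, seed, inputs, outputs) {
  manifest <- list(
    command = command,
    config_hash = rlang::hash(config),
    seed = if (is.null(seed)) NA else seed,
    inputs = as.list(inputs),
    outputs = as.list(outputs),
    tool_version = as.character(packageVersion("ventzero")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Run the full time-zero pipeline
#'
#' Generates (or fixes) a cohort, filters it, flags in-ICU initiation,
#' screens the candidate variables on the in-ICU subset, detects time zero
#' with the selected variable and summarizes agreement against the
#' reference standard. All tables, the summary JSON, the agreement-curve
#' CSV and a run manifest are written to `out_dir`.
#'
#' @param config A list with either `fixture` (one of `"derivation"`,
#'   `"validation"`, `"master"`) or `simulate` (arguments for
#'   [sim_config()]); optionally `search` (arguments for [search_config()]),
#'   `variable` (skip screening and force a search variable) and
#'   `tolerances` (agreement-curve grid).
#' @param out_dir Output directory, created if needed.
#' @param seed Integer seed forwarded to the simulator (ignored for
#'   fixtures, which are deterministic).
#' @return Invisibly, a list with the `summary`, the screening `reports`,
#'   the selected `variable`, the `results` table and output `paths`.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- "configuration"
  res <- tryCatch(
    run_pipeline_stages(config, out_dir, seed),
    error = function(e) {
      vz_abort(sprintf("pipeline failed in stage '%s': %s",
                       attr(e, "ventzero_stage") %||% stage,
                       conditionMessage(e)),
               "ventzero_pipeline_error")
    })
  res
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    attr(e, "ventzero_stage") <- name
    stop(e)
  })
}

run_pipeline_stages <- function(config, out_dir, seed) {
  data <- with_stage("data", {
    if (!is.null(config$fixture)) {
      log_stage("building fixture '%s'", config$fixture)
      make_fixture(config$fixture)
    } else if (!is.null(config$simulate)) {
      args <- config$simulate
      if (!is.null(seed)) args$seed <- seed
      cfg <- do.call(sim_config, args)
      log_stage("simulating cohort of %d patients (seed %d)",
                cfg$n_patients, cfg$seed)
      simulate_cohort(cfg)
    } else {
      vz_abort("config must name either a fixture or simulate parameters",
               "ventzero_config_error")
    }
  })

  paths <- with_stage("write_inputs", write_cohort(data, out_dir))
  scfg <- do.call(search_config, config$search %||% list())

  cohort <- with_stage("filter", filter_study_cohort(data$stays, data$episodes))
  log_stage("cohort: %d stays in, %d eligible (%s)",
            cohort$n_input, cohort$n_retained,
            paste(sprintf("%s: -%d", cohort$exclusions$rule,
                          cohort$exclusions$n_excluded), collapse = ", "))
  if (cohort$n_retained == 0) vz_abort("no eligible patients after filtering")

  flags <- with_stage("flag", flag_in_icu_cohort(
    cohort$patients, data$stays, data$events, data$flowsheet, scfg))
  icu_patients <- flags$patient_id[flags$in_icu]
  log_stage("in-ICU initiation: %d of %d patients (pre-ICU: %d)",
            length(icu_patients), cohort$n_retained,
            cohort$n_retained - length(icu_patients))
  if (length(icu_patients) == 0) vz_abort("no in-ICU initiation patients")

  icu_stays <- data$stays[data$stays$patient_id %in% icu_patients, ]
  reference <- with_stage("reference", tibble::tibble(
    patient_id = icu_patients,
    reference_time = .POSIXct(vapply(icu_patients, function(p) {
      as.numeric(reference_time_zero(p, data$stays, data$flowsheet))
    }, numeric(1)), tz = "UTC")))

  if (is.null(config$variable)) {
    reports <- with_stage("screen", screen_variables(
      icu_stays, data$flowsheet, data$events, reference, scfg))
    variable <- select_search_variable(reports)
    log_stage("screening selected '%s' (completeness %s)", variable,
              paste(sprintf("%s=%.2f", reports$variable, reports$completeness),
                    collapse = ", "))
  } else {
    reports <- NULL
    variable <- config$variable
    log_stage("using configured search variable '%s'", variable)
  }

  results <- with_stage("detect", compute_time_zero(
    icu_patients, data$stays, data$events, data$flowsheet, variable, scfg))
  summary <- with_stage("evaluate", summarize_agreement(
    results, tolerances = config$tolerances %||% c(0, 1, 2, 3, 4, 5, 10, 15, 30, 60)))
  log_stage("agreement: exact %d%%, within 1 min %d%%, kappa %.2f (n=%d)",
            summary$pct_exact, summary$pct_within_1min, summary$kappa,
            summary$n_evaluable)

  out <- with_stage("write_outputs", {
    results_path <- file.path(out_dir, "results.csv")
    write_results(results, results_path)
    summary_path <- file.path(out_dir, "summary.json")
    curve_path <- file.path(out_dir, "curve.csv")
    write_agreement_summary(summary, summary_path, curve_path)
    if (!is.null(reports)) {
      readr::write_csv(reports, file.path(out_dir, "screening.csv"))
    }
    c(paths, results = results_path, summary = summary_path, curve = curve_path)
  })
  write_run_manifest(out_dir, "run", config, seed, character(0), out)

  invisible(list(summary = summary, reports = reports, variable = variable,
                 results = results, paths = out))
}
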