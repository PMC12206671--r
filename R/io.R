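MEASUREMENT_COLS <- c("user_id", "date", "slot", "sbp", "dbp", "hr", "taken")

#' Read and validate a measurement log CSV
#'
#' Expected header: `user_id,date,slot,sbp,dbp,hr,taken` (ISO-8601 dates;
#' optional extra columns `measurement_id`, `protocol_level`, `week_start`
#' are preserved). A missing required column is a schema error. Malformed
#' rows — unparseable dates, unknown slots, vitals on a missed slot,
#' non-positive vitals or systolic not above diastolic on a taken slot — are
#' dropped and collected, with their line numbers, into the `row_errors`
#' attribute of the result.
#'
#' @param path CSV path.
#' @return Measurement log tibble; `attr(, "row_errors")` is a tibble with
#'   `line` (1-based file line including the header) and `reason`.
#' @export
read_measurement_log <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(raw))
  if (length(missing_cols) > 0)
    data_error(paste("measurement log lacks columns:",
                     paste(missing_cols, collapse = ", ")))
  n <- nrow(raw)
  date <- as.Date(raw$date, format = "%Y-%m-%d")
  taken <- tolower(raw$taken) %in% c("true", "t", "1")
  taken_bad <- !tolower(raw$taken) %in% c("true", "t", "1", "false", "f", "0")
  sbp <- suppressWarnings(as.numeric(raw$sbp))
  dbp <- suppressWarnings(as.numeric(raw$dbp))
  hr <- suppressWarnings(as.numeric(raw$hr))
  has_vitals <- !is.na(sbp) | !is.na(dbp) | !is.na(hr)

  reason <- rep(NA_character_, n)
  reason[is.na(date)] <- "unparseable date"
  reason[is.na(reason) & !raw$slot %in% MEASUREMENT_SLOTS] <- "unknown slot"
  reason[is.na(reason) & taken_bad] <- "unparseable taken flag"
  reason[is.na(reason) & !taken & has_vitals] <- "vitals present on missed slot"
  reason[is.na(reason) & taken &
           (is.na(sbp) | is.na(dbp) | is.na(hr))] <- "missing vitals on taken slot"
  reason[is.na(reason) & taken &
           (sbp <= 0 | dbp <= 0 | hr <= 0)] <- "non-positive vital"
  reason[is.na(reason) & taken & sbp <= dbp] <- "sbp not above dbp"

  bad <- !is.na(reason)
  log <- tibble::tibble(
    user_id = raw$user_id, date = date, slot = raw$slot,
    sbp = sbp, dbp = dbp, hr = hr, taken = taken
  )
  if ("protocol_level" %in% names(raw))
    log$protocol_level <- suppressWarnings(as.integer(raw$protocol_level))
  if ("week_start" %in% names(raw))
    log$week_start <- as.Date(raw$week_start, format = "%Y-%m-%d")
  log <- tibble::add_column(
    log,
    measurement_id = if ("measurement_id" %in% names(raw)) raw$measurement_id
                     else measurement_id(raw$user_id, date, raw$slot),
    .before = 1)
  log <- log[!bad, , drop = FALSE]
  attr(log, "row_errors") <- tibble::tibble(
    line = which(bad) + 1L, reason = reason[bad])
  log
}

#' Write a measurement log CSV
#'
#' Canonical dialect: comma-separated, UTF-8, header, ISO dates, unquoted
#' numerics, lower-case `true`/`false` flags. Round-trips through
#' [read_measurement_log()].
#'
#' @param measurements Measurement log tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurement_log <- function(measurements, path) {
  out <- as.data.frame(measurements)
  out$date <- format(out$date)
  if ("week_start" %in% names(out)) out$week_start <- format(out$week_start)
  out$taken <- ifelse(out$taken, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write / read an alert log CSV
#'
#' @param alerts Alert log tibble.
#' @param path File path.
#' @return Writer: `path` invisibly. Reader: alert log tibble.
#' @export
write_alert_log <- function(alerts, path) {
  out <- as.data.frame(alerts)
  out$trigger_date <- format(out$trigger_date)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_alert_log
#' @export
read_alert_log <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  tibble::tibble(
    alert_id = raw$alert_id, user_id = raw$user_id,
    trigger_date = as.Date(raw$trigger_date),
    alert_type = raw$alert_type,
    source_measurement_ids = raw$source_measurement_ids,
    n_sources = as.integer(raw$n_sources),
    exceedance = suppressWarnings(as.numeric(raw$exceedance)),
    routing = raw$routing
  )
}

#' Full pipeline configuration
#'
#' Bundles every stage's configuration. The single `seed` drives all
#' randomness: the cohort generator uses it directly and action
#' classification uses `seed + 1`.
#'
#' @param cohort A [cohort_config()] (its own seed is overridden by `seed`).
#' @param ladder A [protocol_ladder()].
#' @param thresholds An [alert_thresholds()].
#' @param policy Routing policy (see [route_alerts()]).
#' @param action_model An [action_class_model()].
#' @param workload A [workload_model()].
#' @param scenarios List of [scenario_spec()]s, or `NULL` to stop the
#'   pipeline after the summaries.
#' @param rule Week-evaluation rule.
#' @param seed Master seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            ladder = build_default_ladder(),
                            thresholds = alert_thresholds(),
                            policy = default_routing_policy(),
                            action_model = action_class_model(),
                            workload = workload_model(),
                            scenarios = default_scenario_specs(),
                            rule = "mean",
                            seed = 20220601L) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, ladder = ladder, thresholds = thresholds,
                 policy = policy, action_model = action_model,
                 workload = workload, scenarios = scenarios, rule = rule,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Each top-level block (`cohort`, `thresholds`, `action_model`, `workload`,
#' `ladder`, `scenarios`, plus scalar `seed` and `rule`) overrides the
#' corresponding defaults; omitted blocks keep them. The ladder block is a
#' list of protocol records `{protocol_id, level, sbp_target, dbp_target,
#' week_interval_days, measurements_per_day}`; scenarios are records
#' `{alert_type, current_threshold, new_threshold}`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(cfg$cohort)) {
    co <- cfg$cohort
    for (f in c("study_start", "study_end"))
      if (!is.null(co[[f]])) co[[f]] <- as.Date(co[[f]])
    for (f in c("user_mean_sbp_dist", "user_mean_dbp_dist",
                "user_mean_hr_dist", "adherence_dist"))
      if (!is.null(co[[f]])) co[[f]] <- unlist(co[[f]])
    args$cohort <- do.call(cohort_config, co)
  }
  if (!is.null(cfg$thresholds))
    args$thresholds <- do.call(alert_thresholds, cfg$thresholds)
  if (!is.null(cfg$action_model)) {
    am <- cfg$action_model
    if (!is.null(am$clinical_subtype_probs))
      am$clinical_subtype_probs <- unlist(am$clinical_subtype_probs)
    args$action_model <- do.call(action_class_model, am)
  }
  if (!is.null(cfg$workload))
    args$workload <- do.call(workload_model, cfg$workload)
  if (!is.null(cfg$ladder))
    args$ladder <- protocol_ladder(
      lapply(cfg$ladder, function(p) do.call(monitoring_protocol, p)))
  if (!is.null(cfg$policy)) args$policy <- unlist(cfg$policy)
  if (!is.null(cfg$scenarios))
    args$scenarios <- lapply(cfg$scenarios,
                             function(s) do.call(scenario_spec, s))
  if (!is.null(cfg$rule)) args$rule <- cfg$rule
  if (!is.null(cfg$seed)) args$seed <- cfg$seed
  do.call(pipeline_config, args)
}

#' Serialize a protocol ladder to YAML or JSON
#'
#' @param ladder A [protocol_ladder()].
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_ladder <- function(ladder, path) {
  recs <- lapply(seq_len(nrow(ladder)), function(i) as.list(ladder[i, ]))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' Run the full telemonitoring analysis pipeline
#'
#' Stages, in order: simulate the cohort, run the alert engine (detect +
#' route), cluster manual alerts into actions, classify actions, summarise
#' alerts and actions, and (if scenarios are configured) run the scenario
#' table. Writes seven artifacts to `out_dir` — `users.csv`,
#' `measurements.csv`, `alerts.csv`, `actions.csv`, `alert_summary.json`,
#' `action_summary.json`, `scenarios.csv` — or six without scenarios. Every
#' JSON artifact carries the seed and a config hash; a rerun with the same
#' config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with all in-memory artifacts (`users`,
#'   `measurements`, `alerts`, `actions`, `alert_summary`, `action_summary`,
#'   `scenarios`) and `files` (written paths).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = config$seed, config_hash = rlang::hash(unclass(config)))

  cohort <- generate_cohort(config$cohort, config$ladder, config$rule)
  alerts <- run_engine(cohort$measurements, cohort$users, config$ladder,
                       config$thresholds, config$policy, config$rule)
  manual <- alerts[alerts$routing == "manual", , drop = FALSE]
  actions <- classify_actions(cluster_actions(manual), config$action_model,
                              seed = config$seed + 1L)
  alert_summary <- summarize_alerts(cohort$measurements, alerts, cohort$users)
  action_summary <- summarize_actions(actions)

  files <- c(
    users = file.path(out_dir, "users.csv"),
    measurements = file.path(out_dir, "measurements.csv"),
    alerts = file.path(out_dir, "alerts.csv"),
    actions = file.path(out_dir, "actions.csv"),
    alert_summary = file.path(out_dir, "alert_summary.json"),
    action_summary = file.path(out_dir, "action_summary.json")
  )
  users_out <- as.data.frame(cohort$users)
  for (f in c("enrollment_date", "dropout_date"))
    users_out[[f]] <- format(users_out[[f]])
  utils::write.csv(users_out, files[["users"]], row.names = FALSE,
                   quote = FALSE, na = "")
  write_measurement_log(cohort$measurements, files[["measurements"]])
  write_alert_log(alerts, files[["alerts"]])
  actions_out <- as.data.frame(actions)
  actions_out$processing_date <- format(actions_out$processing_date)
  utils::write.csv(actions_out, files[["actions"]], row.names = FALSE,
                   quote = FALSE, na = "")
  write_summary_json(alert_summary, files[["alert_summary"]], meta = meta)
  write_summary_json(action_summary, files[["action_summary"]], meta = meta)

  scen <- NULL
  if (!is.null(config$scenarios) && length(config$scenarios) > 0) {
    scen <- scenario_table(config$scenarios, alerts, cohort$measurements,
                           actions, config$workload)
    files <- c(files, scenarios = file.path(out_dir, "scenarios.csv"))
    utils::write.csv(as.data.frame(scen), files[["scenarios"]],
                     row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(list(users = cohort$users, measurements = cohort$measurements,
                 alerts = alerts, actions = actions,
                 alert_summary = alert_summary,
                 action_summary = action_summary,
                 scenarios = scen, files = files))
}
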