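#' Counterfactual threshold scenario specification
#'
#' One simple-alert threshold change to evaluate against the recorded
#' measurements: for a high alert the new threshold must be at or above the
#' current one (an alert-reduction scenario); for a low alert, at or below.
#'
#' @param alert_type One of the six simple alert types.
#' @param current_threshold Operating threshold (mmHg or bpm).
#' @param new_threshold Counterfactual threshold, same units.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(alert_type, current_threshold, new_threshold) {
  if (!alert_type %in% SIMPLE_TYPES)
    config_error("scenario alert_type must be a simple alert type", "alert_type")
  hi <- grepl("_high$", alert_type)
  if (hi && new_threshold < current_threshold)
    config_error("new_threshold must be >= current_threshold for high alerts",
                 "new_threshold")
  if (!hi && new_threshold > current_threshold)
    config_error("new_threshold must be <= current_threshold for low alerts",
                 "new_threshold")
  structure(list(alert_type = alert_type,
                 current_threshold = current_threshold,
                 new_threshold = new_threshold,
                 high = hi),
            class = "scenario_spec")
}

#' The six blood-pressure reduction scenarios evaluated by default
#'
#' Diastolic simple alert raised from >=105 to >=110/115/120 mmHg and
#' systolic from >=170 to >=180/190/200 mmHg.
#'
#' @return List of [scenario_spec()] objects.
#' @export
default_scenario_specs <- function() {
  list(
    scenario_spec("simple_dbp_high", 105, 110),
    scenario_spec("simple_dbp_high", 105, 115),
    scenario_spec("simple_dbp_high", 105, 120),
    scenario_spec("simple_sbp_high", 170, 180),
    scenario_spec("simple_sbp_high", 170, 190),
    scenario_spec("simple_sbp_high", 170, 200)
  )
}

scenario_vital <- function(alert_type) {
  switch(sub("^simple_(sbp|dbp|hr)_.*$", "\\1", alert_type),
         sbp = "sbp", dbp = "dbp", hr = "hr")
}

#' Re-score alerts under a counterfactual threshold
#'
#' No re-simulation: each alert of the scenario's type survives if and only
#' if the absolute value of its recorded source measurement still meets the
#' new threshold; alerts of every other type pass through untouched. An
#' alert of the scenario type whose source measurement cannot be found in
#' the log is a broken linkage and raises a data error.
#'
#' @param alerts Alert log (each simple alert references one measurement).
#' @param measurements Measurement log the alerts were generated from.
#' @param spec A [scenario_spec()].
#' @return The surviving subset of `alerts`.
#' @export
rescore_alerts <- function(alerts, measurements, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  sel <- alerts$alert_type == spec$alert_type
  if (!any(sel)) return(alerts)
  ids <- alerts$source_measurement_ids[sel]
  if (any(grepl(";", ids)) || any(ids == ""))
    data_error("scenario alerts must reference exactly one source measurement")
  pos <- match(ids, measurements$measurement_id)
  if (anyNA(pos))
    data_error("broken linkage: scenario alert source measurement not in log")
  val <- measurements[[scenario_vital(spec$alert_type)]][pos]
  keep <- if (spec$high) val >= spec$new_threshold else val <= spec$new_threshold
  drop_idx <- which(sel)[!keep]
  if (length(drop_idx) > 0) alerts <- alerts[-drop_idx, , drop = FALSE]
  alerts
}

#' Attach each alert's telemonitoring-action class
#'
#' Maps alerts to the administrative/clinical class of the action that
#' processed them (via the action's member-alert list). Alerts outside any
#' action (auto-routed ones) get `NA`.
#'
#' @param alerts Alert log with `alert_id`.
#' @param actions Classified actions with `member_alert_ids`.
#' @return `alerts` with an `action_class` column.
#' @export
label_alerts_with_actions <- function(alerts, actions) {
  members <- strsplit(actions$member_alert_ids, ";", fixed = TRUE)
  map <- stats::setNames(
    rep(actions$action_class, lengths(members)), unlist(members))
  alerts$action_class <- unname(map[alerts$alert_id])
  alerts
}

#' Extrapolate processing proportions to surviving alerts
#'
#' Empirical mode (default when labels are present) recomputes the
#' administrative/clinical proportions among the survivors themselves,
#' capturing the shift toward clinical processing as milder alerts are
#' filtered out. Carry-forward mode applies the current proportions
#' unchanged; the mode used is recorded in the result.
#'
#' @param surviving_alerts Survivors of [rescore_alerts()], restricted to the
#'   scenario's alert type, carrying `action_class` labels (empirical mode).
#' @param p_administrative_current Current administrative proportion
#'   (required for carry-forward mode).
#' @param mode `"empirical"` or `"carry_forward"`.
#' @return List: `mode`, `n_surviving`, `p_administrative`, `p_clinical`,
#'   `n_administrative_projected`, `n_clinical_projected`, `empty` flag.
#'   Projected counts always sum to the survivor count.
#' @export
extrapolate_processing <- function(surviving_alerts,
                                   p_administrative_current = NULL,
                                   mode = c("empirical", "carry_forward")) {
  mode <- match.arg(mode)
  n <- nrow(surviving_alerts)
  if (n == 0) {
    return(list(mode = mode, n_surviving = 0L,
                p_administrative = NA_real_, p_clinical = NA_real_,
                n_administrative_projected = 0L, n_clinical_projected = 0L,
                empty = TRUE))
  }
  if (mode == "empirical") {
    if (!"action_class" %in% names(surviving_alerts) ||
        anyNA(surviving_alerts$action_class))
      contract_error("empirical extrapolation needs action_class labels")
    n_adm <- sum(surviving_alerts$action_class == "administrative")
    p_adm <- n_adm / n
  } else {
    if (is.null(p_administrative_current))
      config_error("carry_forward mode needs p_administrative_current",
                   "p_administrative_current")
    p_adm <- p_administrative_current
    n_adm <- round_half_up(n * p_adm)
  }
  list(mode = mode, n_surviving = as.integer(n),
       p_administrative = p_adm, p_clinical = 1 - p_adm,
       n_administrative_projected = as.integer(n_adm),
       n_clinical_projected = as.integer(n - n_adm),
       empty = FALSE)
}

#' Projected e-nurse time saving of a threshold scenario
#'
#' Baseline and counterfactual workloads both use the proportion-mode
#' formula ([workload_from_proportions()]) with the administrative
#' proportions carried at two decimals; the saving is their difference.
#'
#' @param n_current Current alert count of the scenario type.
#' @param p_admin_current Current administrative proportion.
#' @param n_surviving Alerts surviving the new threshold.
#' @param p_admin_new Administrative proportion among survivors.
#' @param model A [workload_model()].
#' @return List: `baseline_minutes`, `new_minutes`, `minutes_saved`.
#' @export
scenario_time_saving <- function(n_current, p_admin_current,
                                 n_surviving, p_admin_new,
                                 model = workload_model()) {
  p_cur <- round_half_up(p_admin_current, 2)
  p_new <- round_half_up(p_admin_new, 2)
  baseline <- workload_from_proportions(n_current, p_cur, model)
  new <- if (n_surviving == 0) 0 else
    workload_from_proportions(n_surviving, p_new, model)
  list(baseline_minutes = baseline, new_minutes = new,
       minutes_saved = baseline - new)
}

#' Scenario analysis table over a set of threshold specifications
#'
#' One row per scenario: current and surviving alert counts, percentage
#' reduction, empirical administrative/clinical split before and after, and
#' the projected time saving. Rows are independent; a failing or empty row
#' (no alerts of its type) is flagged rather than aborting the others.
#'
#' @param specs List of [scenario_spec()] objects.
#' @param alerts Routed alert log (only manual alerts of each scenario type
#'   enter that row).
#' @param measurements Measurement log.
#' @param actions Classified actions supplying per-alert labels (or pass
#'   `alerts` pre-labelled with `action_class` and `actions = NULL`).
#' @param model A [workload_model()].
#' @return Tibble with one row per spec: `alert_type`, `current_threshold`,
#'   `new_threshold`, `n_alerts_current`, `n_alerts_surviving`,
#'   `n_alerts_removed`, `pct_reduction`, `p_administrative_current`,
#'   `p_clinical_current`, `p_administrative_new`, `p_clinical_new`,
#'   `baseline_minutes`, `new_minutes`, `minutes_saved`, `empty`.
#' @export
scenario_table <- function(specs, alerts, measurements, actions = NULL,
                           model = workload_model()) {
  if (length(specs) == 0) config_error("specs must be non-empty", "specs")
  if (!is.null(actions)) alerts <- label_alerts_with_actions(alerts, actions)
  rows <- lapply(specs, function(spec) {
    base <- tibble::tibble(
      alert_type = spec$alert_type,
      current_threshold = spec$current_threshold,
      new_threshold = spec$new_threshold)
    cur <- alerts[alerts$alert_type == spec$alert_type &
                    alerts$routing == "manual", , drop = FALSE]
    n_cur <- nrow(cur)
    if (n_cur == 0) {
      return(tibble::add_column(
        base, n_alerts_current = 0L, n_alerts_surviving = 0L,
        n_alerts_removed = 0L, pct_reduction = NA_real_,
        p_administrative_current = NA_real_, p_clinical_current = NA_real_,
        p_administrative_new = NA_real_, p_clinical_new = NA_real_,
        baseline_minutes = 0, new_minutes = 0, minutes_saved = 0,
        empty = TRUE))
    }
    surv <- rescore_alerts(cur, measurements, spec)
    p_cur <- mean(cur$action_class == "administrative")
    ext <- extrapolate_processing(surv)
    saving <- scenario_time_saving(
      n_cur, p_cur, ext$n_surviving,
      if (ext$empty) p_cur else ext$p_administrative, model)
    tibble::add_column(
      base,
      n_alerts_current = n_cur,
      n_alerts_surviving = ext$n_surviving,
      n_alerts_removed = n_cur - ext$n_surviving,
      pct_reduction = pct_of(n_cur - ext$n_surviving, n_cur),
      p_administrative_current = p_cur,
      p_clinical_current = 1 - p_cur,
      p_administrative_new = ext$p_administrative,
      p_clinical_new = ext$p_clinical,
      baseline_minutes = saving$baseline_minutes,
      new_minutes = saving$new_minutes,
      minutes_saved = saving$minutes_saved,
      empty = ext$empty)
  })
  dplyr::bind_rows(rows)
}
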