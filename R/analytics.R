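#' Alert summary from raw breakdown counts
#'
#' Builds the full descriptive alert summary (totals, auto/manual split,
#' within-route breakdowns, manual alerts per user) from the seven breakdown
#' counts. All percentages are computed from the unrounded ratios and rounded
#' half-up once; a zero denominator yields an undefined (`NA`) percentage,
#' never an error.
#'
#' @param n_users Number of active users.
#' @param n_measurements Total taken measurements.
#' @param n_auto_complex Auto-processed complex (on-target) alerts.
#' @param n_auto_missed Auto-processed overdue/inactivity alerts.
#' @param n_manual_simple,n_manual_complex,n_manual_inactive Manually
#'   processed alerts by kind.
#' @param mean_active_days Optional mean days active (carried through).
#' @return An `alert_summary`: named list of counts and rounded percentages.
#' @export
alert_summary_from_counts <- function(n_users, n_measurements,
                                      n_auto_complex, n_auto_missed,
                                      n_manual_simple, n_manual_complex,
                                      n_manual_inactive,
                                      mean_active_days = NA_real_) {
  n_auto <- n_auto_complex + n_auto_missed
  n_manual <- n_manual_simple + n_manual_complex + n_manual_inactive
  n_alerts <- n_auto + n_manual
  out <- list(
    n_users = n_users,
    mean_active_days = mean_active_days,
    n_measurements = n_measurements,
    n_alerts = n_alerts,
    pct_alerts_of_measurements = pct_of(n_alerts, n_measurements),
    n_auto = n_auto,
    pct_auto_of_alerts = pct_of(n_auto, n_alerts),
    n_auto_complex = n_auto_complex,
    pct_auto_complex = pct_of(n_auto_complex, n_auto),
    n_auto_missed = n_auto_missed,
    pct_auto_missed = pct_of(n_auto_missed, n_auto),
    n_manual = n_manual,
    pct_manual_of_alerts = pct_of(n_manual, n_alerts),
    n_manual_simple = n_manual_simple,
    pct_manual_simple = pct_of(n_manual_simple, n_manual),
    n_manual_complex = n_manual_complex,
    pct_manual_complex = pct_of(n_manual_complex, n_manual),
    n_manual_inactive = n_manual_inactive,
    pct_manual_inactive = pct_of(n_manual_inactive, n_manual),
    manual_alerts_per_user = if (n_users == 0) NA_real_ else
      round_half_up(n_manual / n_users)
  )
  structure(out, class = "alert_summary")
}

#' Summarise a measurement and alert log
#'
#' Pure function of the logs: counts taken measurements, splits alerts by
#' routing and kind, and delegates the arithmetic (single half-up rounding
#' of each percentage) to [alert_summary_from_counts()].
#'
#' @param measurements Measurement log.
#' @param alerts Routed alert log.
#' @param users Optional user table; supplies `n_users` and mean active days
#'   (otherwise users are counted from the measurement log).
#' @return An `alert_summary`.
#' @export
summarize_alerts <- function(measurements, alerts, users = NULL) {
  ty <- alerts$alert_type
  auto <- alerts$routing == "auto"
  is_simple <- ty %in% SIMPLE_TYPES
  is_complex <- ty %in% c("complex_off_target", "complex_on_target_switch")
  is_missed <- ty %in% c("overdue", "inactive")
  alert_summary_from_counts(
    n_users = if (is.null(users)) length(unique(measurements$user_id))
              else nrow(users),
    n_measurements = sum(measurements$taken),
    n_auto_complex = sum(auto & is_complex),
    n_auto_missed = sum(auto & is_missed),
    n_manual_simple = sum(!auto & is_simple),
    n_manual_complex = sum(!auto & is_complex),
    n_manual_inactive = sum(!auto & is_missed),
    mean_active_days = if (is.null(users)) NA_real_ else mean(users$active_days)
  )
}

#' Action summary from breakdown counts
#'
#' @param n_administrative Administrative action count.
#' @param subtype_counts Named counts of the four clinical subtypes
#'   (`phone_no_adjust`, `phone_adjust`, `message_no_adjust`,
#'   `message_adjust`); clinical total is their sum.
#' @return An `action_summary`: counts plus half-up-rounded percentages
#'   (subtype percentages are of the clinical total).
#' @export
action_summary_from_counts <- function(n_administrative, subtype_counts) {
  subtype_names <- c("phone_no_adjust", "phone_adjust",
                     "message_no_adjust", "message_adjust")
  if (!setequal(names(subtype_counts), subtype_names))
    config_error("subtype_counts must name the 4 clinical subtypes",
                 "subtype_counts")
  subtype_counts <- subtype_counts[subtype_names]
  n_clinical <- sum(subtype_counts)
  n_actions <- n_administrative + n_clinical
  out <- c(
    list(
      n_actions = n_actions,
      n_administrative = n_administrative,
      pct_administrative = pct_of(n_administrative, n_actions),
      n_clinical = n_clinical,
      pct_clinical = pct_of(n_clinical, n_actions)
    ),
    stats::setNames(as.list(unname(subtype_counts)),
                    paste0("n_", subtype_names)),
    stats::setNames(as.list(pct_of(unname(subtype_counts), n_clinical)),
                    paste0("pct_", subtype_names))
  )
  structure(out, class = "action_summary")
}

#' Summarise classified telemonitoring actions
#'
#' @param actions Classified actions (see [classify_actions()]).
#' @return An `action_summary`.
#' @export
summarize_actions <- function(actions) {
  if (nrow(actions) > 0 &&
      (!"action_class" %in% names(actions) || anyNA(actions$action_class)))
    contract_error("summarize_actions requires classified actions")
  subtype_names <- c("phone_no_adjust", "phone_adjust",
                     "message_no_adjust", "message_adjust")
  counts <- vapply(subtype_names,
                   function(s) sum(actions$clinical_subtype == s), integer(1))
  action_summary_from_counts(
    n_administrative = sum(actions$action_class == "administrative"),
    subtype_counts = counts)
}

per_user_burden <- function(alerts, actions = NULL) {
  manual <- alerts[alerts$routing == "manual", , drop = FALSE]
  b <- tibble::tibble(
    user_id = manual$user_id,
    simple = manual$alert_type %in% SIMPLE_TYPES,
    complex = manual$alert_type %in% c("complex_off_target",
                                       "complex_on_target_switch"))
  b <- dplyr::summarise(
    dplyr::group_by(b, .data$user_id),
    simple_alerts = sum(.data$simple),
    complex_alerts = sum(.data$complex),
    manual_alerts = dplyr::n(), .groups = "drop")
  if (!is.null(actions)) {
    a <- dplyr::count(actions, .data$user_id, name = "actions")
    b <- dplyr::full_join(b, a, by = "user_id")
    b[is.na(b)] <- 0
  }
  b
}

#' Top-user alert-burden concentration
#'
#' Ranks users by a burden metric and reports the share of every available
#' metric attributable to the top fraction `f` of users — the analysis behind
#' alert-fatigue review of the few users who generate most of the manual
#' workload. Users are ranked descending with deterministic ties broken by
#' `user_id`; the top group has `ceiling(f * n_users)` members.
#'
#' @param alerts Routed alert log (manual alerts are the burden universe).
#' @param actions Optional classified/unclassified actions; adds an
#'   `actions` metric.
#' @param top_fraction Fraction of users in the top group (default 0.15).
#' @param rank_by Metric to rank users by: `"manual_alerts"` (default),
#'   `"simple_alerts"`, `"complex_alerts"` or `"actions"`.
#' @param n_users Total user count (defaults to users observed in the burden
#'   table; pass the cohort size to include zero-burden users).
#' @return A `concentration_report`: list with `top_fraction`, `n_users`,
#'   `n_top`, `rank_by`, `top_users`, `shares` (named vector in `[0, 1]`
#'   per metric) and the full `ranking` tibble.
#' @export
concentration <- function(alerts, actions = NULL, top_fraction = 0.15,
                          rank_by = "manual_alerts", n_users = NULL) {
  if (top_fraction <= 0 || top_fraction > 1)
    config_error("top_fraction must be in (0, 1]", "top_fraction")
  b <- per_user_burden(alerts, actions)
  if (nrow(b) == 0) data_error("no manual alerts to rank")
  if (!rank_by %in% setdiff(names(b), "user_id"))
    config_error(sprintf("unknown rank_by metric '%s'", rank_by), "rank_by")
  if (is.null(n_users)) n_users <- nrow(b)
  if (n_users > nrow(b)) {
    pad <- tibble::tibble(user_id = sprintf("zzz-unobserved-%04d",
                                            seq_len(n_users - nrow(b))))
    for (m in setdiff(names(b), "user_id")) pad[[m]] <- 0
    b <- dplyr::bind_rows(b, pad)
  }
  b <- b[order(-b[[rank_by]], b$user_id), ]
  n_top <- ceiling(top_fraction * n_users)
  top <- b[seq_len(n_top), , drop = FALSE]
  metrics <- setdiff(names(b), "user_id")
  shares <- vapply(metrics, function(m) {
    tot <- sum(b[[m]])
    if (tot == 0) NA_real_ else sum(top[[m]]) / tot
  }, numeric(1))
  structure(list(
    top_fraction = top_fraction, n_users = n_users, n_top = n_top,
    rank_by = rank_by, top_users = top$user_id,
    shares = shares, ranking = tibble::as_tibble(b)
  ), class = "concentration_report")
}

#' Lorenz-style cumulative burden curve
#'
#' Users ordered by descending burden; cumulative user fraction versus
#' cumulative burden fraction. The share of any top fraction of users can be
#' read off the curve.
#'
#' @param alerts Routed alert log.
#' @param metric Burden metric (see [concentration()]).
#' @param actions Optional actions table for the `"actions"` metric.
#' @return Tibble with `cum_user_frac`, `cum_burden_frac`.
#' @export
lorenz_curve <- function(alerts, metric = "manual_alerts", actions = NULL) {
  b <- per_user_burden(alerts, actions)
  x <- sort(b[[metric]], decreasing = TRUE)
  tibble::tibble(
    cum_user_frac = seq_along(x) / length(x),
    cum_burden_frac = cumsum(x) / sum(x)
  )
}

#' Write or read a summary as JSON
#'
#' Round-trip faithful: reading back reproduces the summary exactly.
#'
#' @param summary An `alert_summary` or `action_summary`.
#' @param path File path.
#' @param meta Optional named list stored under `"_meta"`.
#' @return `write_summary_json` returns `path` invisibly;
#'   `read_summary_json` returns the summary list (class restored from the
#'   stored `"_class"` field).
#' @export
write_summary_json <- function(summary, path, meta = NULL) {
  payload <- unclass(summary)
  payload[["_class"]] <- class(summary)[1]
  if (!is.null(meta)) payload[["_meta"]] <- meta
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- payload[["_class"]]
  payload[["_class"]] <- NULL
  payload[["_meta"]] <- NULL
  payload <- lapply(payload, function(x) if (is.null(x)) NA_real_ else x)
  structure(payload, class = cls)
}
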