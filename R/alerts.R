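#' Simple-alert thresholds and series-rule parameters
#'
#' One-off ("simple") alert bounds for a single measurement, plus the two
#' series parameters: the run length of consecutive off-target measurements
#' that fires a complex alert, and the inactivity window (days of scheduled
#' measurement with nothing taken) that fires an inactive alert. High bounds
#' are inclusive `>=`, low bounds inclusive `<=`. The blood-pressure high
#' defaults (>=170 systolic, >=105 diastolic) are the program's operating
#' thresholds; the low-BP and heart-rate bounds have no published reference
#' values and ship as overridable defaults.
#'
#' @param simple_sbp_high,simple_dbp_high High BP bounds, mmHg (>= fires).
#' @param simple_sbp_low,simple_dbp_low Low BP bounds, mmHg (<= fires).
#' @param simple_hr_high,simple_hr_low Heart-rate bounds, bpm.
#' @param complex_consecutive_k Consecutive off-target taken measurements
#'   needed for a complex off-target alert (default 4 = one measurement day).
#' @param inactivity_window_days Scheduled measurement-week days with zero
#'   taken measurements needed for an inactive alert (default 7).
#' @return An `alert_thresholds` object.
#' @export
alert_thresholds <- function(simple_sbp_high = 170, simple_dbp_high = 105,
                             simple_sbp_low = 90, simple_dbp_low = 50,
                             simple_hr_high = 110, simple_hr_low = 45,
                             complex_consecutive_k = 4,
                             inactivity_window_days = 7) {
  if (simple_sbp_high <= simple_sbp_low)
    config_error("simple_sbp_high must exceed simple_sbp_low", "simple_sbp_high")
  if (simple_dbp_high <= simple_dbp_low)
    config_error("simple_dbp_high must exceed simple_dbp_low", "simple_dbp_high")
  if (simple_hr_high <= simple_hr_low)
    config_error("simple_hr_high must exceed simple_hr_low", "simple_hr_high")
  if (complex_consecutive_k < 2)
    config_error("complex_consecutive_k must be >= 2", "complex_consecutive_k")
  if (inactivity_window_days < 1)
    config_error("inactivity_window_days must be >= 1", "inactivity_window_days")
  structure(list(
    simple_sbp_high = simple_sbp_high, simple_dbp_high = simple_dbp_high,
    simple_sbp_low = simple_sbp_low, simple_dbp_low = simple_dbp_low,
    simple_hr_high = simple_hr_high, simple_hr_low = simple_hr_low,
    complex_consecutive_k = as.integer(complex_consecutive_k),
    inactivity_window_days = as.integer(inactivity_window_days)
  ), class = "alert_thresholds")
}

ALERT_TYPES <- c("simple_sbp_high", "simple_sbp_low", "simple_dbp_high",
                 "simple_dbp_low", "simple_hr_high", "simple_hr_low",
                 "complex_off_target", "complex_on_target_switch",
                 "overdue", "inactive")
SIMPLE_TYPES <- ALERT_TYPES[1:6]

#' Default auto/manual routing policy
#'
#' Which alert types the telemonitoring platform processes automatically and
#' which go to the e-nurses: single overdue alerts and on-target (protocol
#' switch / positive feedback) alerts are automatic; all simple alerts,
#' off-target complex alerts and inactive alerts are manual.
#'
#' @return Named character vector mapping every alert type to `"auto"` or
#'   `"manual"`.
#' @export
default_routing_policy <- function() {
  c(simple_sbp_high = "manual", simple_sbp_low = "manual",
    simple_dbp_high = "manual", simple_dbp_low = "manual",
    simple_hr_high = "manual", simple_hr_low = "manual",
    complex_off_target = "manual", complex_on_target_switch = "auto",
    overdue = "auto", inactive = "manual")
}

empty_alerts <- function() {
  tibble::tibble(
    user_id = character(), trigger_date = as.Date(character()),
    alert_type = character(), source_measurement_ids = character(),
    n_sources = integer(), exceedance = numeric()
  )
}

#' Detect simple (single-measurement) alerts
#'
#' Scans taken measurements against the six one-off bounds; one alert per
#' violated bound, so a single reading can raise several simple alerts (e.g.
#' systolic and diastolic both high). `exceedance` records how far past the
#' bound the reading was (mmHg or bpm), which downstream action
#' classification can use as a severity covariate.
#'
#' @param measurements Tibble of taken measurements (a single row works).
#'   Passing a missed slot is a contract violation: missed slots belong to
#'   [detect_missed()].
#' @param thresholds An [alert_thresholds()].
#' @return Alert tibble (no routing, no ids yet).
#' @export
detect_simple <- function(measurements, thresholds = alert_thresholds()) {
  if (nrow(measurements) == 0) return(empty_alerts())
  if (any(!measurements$taken))
    contract_error("detect_simple received a missed slot")
  bounds <- list(
    simple_sbp_high = list(v = "sbp", cut = thresholds$simple_sbp_high, hi = TRUE),
    simple_sbp_low  = list(v = "sbp", cut = thresholds$simple_sbp_low,  hi = FALSE),
    simple_dbp_high = list(v = "dbp", cut = thresholds$simple_dbp_high, hi = TRUE),
    simple_dbp_low  = list(v = "dbp", cut = thresholds$simple_dbp_low,  hi = FALSE),
    simple_hr_high  = list(v = "hr",  cut = thresholds$simple_hr_high,  hi = TRUE),
    simple_hr_low   = list(v = "hr",  cut = thresholds$simple_hr_low,   hi = FALSE)
  )
  out <- lapply(names(bounds), function(ty) {
    b <- bounds[[ty]]
    x <- measurements[[b$v]]
    hit <- if (b$hi) x >= b$cut else x <= b$cut
    hit[is.na(hit)] <- FALSE
    m <- measurements[hit, , drop = FALSE]
    if (nrow(m) == 0) return(NULL)
    tibble::tibble(
      user_id = m$user_id, trigger_date = m$date, alert_type = ty,
      source_measurement_ids = m$measurement_id, n_sources = 1L,
      exceedance = if (b$hi) m[[b$v]] - b$cut else b$cut - m[[b$v]]
    )
  })
  dplyr::bind_rows(c(list(empty_alerts()), out))
}

#' Detect complex (measurement-series) alerts for one user under one protocol
#'
#' Two series events are detected on a single user's time-ordered
#' measurements taken under one protocol:
#' \itemize{
#'   \item `complex_off_target`: a run of at least `complex_consecutive_k`
#'     consecutive taken measurements at or above the protocol target
#'     (systolic >= target or diastolic >= target). One alert per maximal run,
#'     firing at the k-th measurement of the run with the first k readings as
#'     sources.
#'   \item `complex_on_target_switch`: a measurement week whose taken
#'     readings are on target under `rule` — the event that drives automatic
#'     protocol step-down (and on-target feedback at the chronic floor).
#'     Requires a `week_start` column.
#' }
#'
#' @param measurements One user's measurements (taken and missed rows),
#'   sorted by date then slot; unsorted input is a contract violation.
#' @param protocol The [monitoring_protocol()] the rows ran under.
#' @param thresholds An [alert_thresholds()].
#' @param rule Week-evaluation rule for the on-target event.
#' @return Alert tibble.
#' @export
detect_complex <- function(measurements, protocol,
                           thresholds = alert_thresholds(), rule = "mean") {
  if (nrow(measurements) == 0) return(empty_alerts())
  if (length(unique(measurements$user_id)) > 1)
    contract_error("detect_complex expects a single user")
  ord <- order(measurements$date, match(measurements$slot, MEASUREMENT_SLOTS))
  if (!identical(ord, seq_len(nrow(measurements))))
    contract_error("detect_complex expects measurements sorted by date and slot")

  taken <- measurements[measurements$taken, , drop = FALSE]
  out <- list(empty_alerts())

  if (nrow(taken) > 0) {
    off <- taken$sbp >= protocol$sbp_target | taken$dbp >= protocol$dbp_target
    r <- rle(off)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- thresholds$complex_consecutive_k
    fire <- which(r$values & r$lengths >= k)
    if (length(fire) > 0) {
      out[[length(out) + 1L]] <- dplyr::bind_rows(lapply(fire, function(j) {
        idx <- starts[j]:(starts[j] + k - 1L)
        tibble::tibble(
          user_id = taken$user_id[1], trigger_date = taken$date[idx[k]],
          alert_type = "complex_off_target",
          source_measurement_ids = paste(taken$measurement_id[idx], collapse = ";"),
          n_sources = as.integer(k),
          exceedance = max(pmax(taken$sbp[idx] - protocol$sbp_target,
                                taken$dbp[idx] - protocol$dbp_target))
        )
      }))
    }
  }

  if ("week_start" %in% names(measurements)) {
    weeks <- split(measurements, measurements$week_start)
    on_weeks <- lapply(weeks, function(w) {
      ev <- evaluate_week(w, protocol, rule = rule)
      if (!isTRUE(ev$on_target)) return(NULL)
      tk <- w[w$taken, , drop = FALSE]
      tibble::tibble(
        user_id = w$user_id[1], trigger_date = max(w$date),
        alert_type = "complex_on_target_switch",
        source_measurement_ids = paste(tk$measurement_id, collapse = ";"),
        n_sources = nrow(tk), exceedance = NA_real_
      )
    })
    out[[length(out) + 1L]] <- dplyr::bind_rows(on_weeks)
  }
  dplyr::bind_rows(out)
}

#' Detect overdue and inactive alerts
#'
#' The measurement log carries every scheduled slot, taken or not. Each
#' missed slot raises one overdue alert. Separately, a maximal run of at
#' least `inactivity_window_days` consecutive scheduled measurement-week
#' days with zero taken measurements raises one inactive alert, triggered on
#' the day the window is first complete. Both kinds are emitted; under the
#' default routing policy overdue alerts are automatic and inactive alerts
#' manual.
#'
#' @param measurements Measurement log (any number of users) with `taken`.
#' @param thresholds An [alert_thresholds()].
#' @return Alert tibble.
#' @export
detect_missed <- function(measurements, thresholds = alert_thresholds()) {
  if (nrow(measurements) == 0) return(empty_alerts())
  missed <- measurements[!measurements$taken, , drop = FALSE]
  overdue <- if (nrow(missed) > 0) {
    tibble::tibble(
      user_id = missed$user_id, trigger_date = missed$date,
      alert_type = "overdue", source_measurement_ids = "",
      n_sources = 0L, exceedance = NA_real_
    )
  } else empty_alerts()

  x <- thresholds$inactivity_window_days
  by_day <- dplyr::summarise(
    dplyr::group_by(measurements, .data$user_id, .data$date),
    any_taken = any(.data$taken), .groups = "drop")
  by_day <- dplyr::arrange(by_day, .data$user_id, .data$date)
  inactive <- dplyr::bind_rows(lapply(
    split(by_day, by_day$user_id), function(u) {
      r <- rle(!u$any_taken)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      j <- which(r$values & r$lengths >= x)
      if (length(j) == 0) return(NULL)
      tibble::tibble(
        user_id = u$user_id[1],
        trigger_date = u$date[starts[j] + x - 1L],
        alert_type = "inactive", source_measurement_ids = "",
        n_sources = 0L, exceedance = NA_real_
      )
    }))
  dplyr::bind_rows(empty_alerts(), overdue, inactive)
}

#' Apply an auto/manual routing policy to alerts
#'
#' @param alerts Alert tibble.
#' @param policy Named character vector alert type -> `"auto"`/`"manual"`
#'   covering every alert type present; an unmapped type is a configuration
#'   error. Auto + manual counts always sum to the total.
#' @return Alerts with a `routing` column.
#' @export
route_alerts <- function(alerts, policy = default_routing_policy()) {
  if (!all(policy %in% c("auto", "manual")))
    config_error("routing policy values must be 'auto' or 'manual'", "policy")
  unmapped <- setdiff(unique(alerts$alert_type), names(policy))
  if (length(unmapped) > 0)
    config_error(paste("alert types missing from routing policy:",
                       paste(unmapped, collapse = ", ")), "policy")
  alerts$routing <- unname(policy[alerts$alert_type])
  alerts
}

# Deterministic alert ids: user, date, type, ordinal within that triple.
assign_alert_ids <- function(alerts) {
  alerts <- dplyr::arrange(alerts, .data$user_id, .data$trigger_date,
                           .data$alert_type, .data$source_measurement_ids)
  key <- paste(alerts$user_id, alerts$trigger_date, alerts$alert_type)
  ord <- stats::ave(seq_along(key), key, FUN = seq_along)
  alerts <- tibble::add_column(
    alerts,
    alert_id = sprintf("A:%s:%s:%s:%d", alerts$user_id,
                       format(alerts$trigger_date), alerts$alert_type, ord),
    .before = 1)
  alerts
}

#' Reconstruct protocol level and measurement week for an external log
#'
#' Replays each user's walk down the protocol ladder from their enrollment
#' date and starting level, assigning `protocol_level` and `week_start` to
#' every logged slot and applying automatic step-down after each on-target
#' week — the same deterministic walk the synthetic generator performs.
#' Logged dates that fall outside any replayed measurement week are a data
#' error (the log does not fit the ladder's schedule).
#'
#' @param measurements Measurement log without (or with stale)
#'   `protocol_level`/`week_start` columns.
#' @param users User table with `user_id`, `enrollment_date`,
#'   `start_protocol_level`.
#' @param ladder A [protocol_ladder()].
#' @param rule Week-evaluation rule.
#' @return The log with `protocol_level` and `week_start` columns set.
#' @export
assign_protocol_weeks <- function(measurements, users,
                                  ladder = build_default_ladder(),
                                  rule = "mean") {
  measurements$protocol_level <- NULL
  measurements$week_start <- NULL
  per_user <- split(measurements, measurements$user_id)
  out <- lapply(names(per_user), function(uid) {
    log <- per_user[[uid]]
    log <- log[order(log$date, match(log$slot, MEASUREMENT_SLOTS)), ]
    u <- users[users$user_id == uid, ]
    if (nrow(u) != 1) data_error(sprintf("user %s absent from user table", uid))
    level <- u$start_protocol_level
    week_start <- u$enrollment_date
    last_day <- max(log$date)
    log$protocol_level <- NA_integer_
    log$week_start <- as.Date(NA)
    while (week_start <= last_day) {
      proto <- ladder_protocol(ladder, level)
      in_week <- log$date >= week_start & log$date <= week_start + 6
      log$protocol_level[in_week] <- level
      log$week_start[in_week] <- week_start
      ev <- evaluate_week(log[in_week, , drop = FALSE], proto, rule = rule)
      if (identical(ev$decision, "step-down")) level <- level - 1L
      if (identical(ev$decision, "step-up")) level <- level + 1L
      week_start <- week_start + proto$week_interval_days
    }
    if (anyNA(log$protocol_level))
      data_error(sprintf(
        "user %s has measurements outside any measurement week", uid))
    log
  })
  dplyr::bind_rows(out)
}

#' Run the full alert engine over a measurement log
#'
#' Concatenates the three detectors — simple (per taken measurement), complex
#' (per user and protocol segment), missed (overdue + inactive) — applies the
#' routing policy and assigns deterministic alert ids. Complex detection
#' needs each row's protocol context; logs from [generate_cohort()] carry it,
#' and for external logs it is reconstructed with [assign_protocol_weeks()].
#'
#' @param measurements Measurement log.
#' @param users User table (needed only when protocol context must be
#'   reconstructed).
#' @param ladder A [protocol_ladder()].
#' @param thresholds An [alert_thresholds()].
#' @param policy Routing policy (see [route_alerts()]).
#' @param rule Week-evaluation rule.
#' @return Alert log tibble: `alert_id`, `user_id`, `trigger_date`,
#'   `alert_type`, `source_measurement_ids` (semicolon-joined), `n_sources`,
#'   `exceedance`, `routing`. Deterministic for fixed inputs.
#' @export
run_engine <- function(measurements, users = NULL,
                       ladder = build_default_ladder(),
                       thresholds = alert_thresholds(),
                       policy = default_routing_policy(),
                       rule = "mean") {
  if (!all(c("protocol_level", "week_start") %in% names(measurements))) {
    if (is.null(users))
      data_error("log lacks protocol context and no user table was given")
    measurements <- assign_protocol_weeks(measurements, users, ladder, rule)
  }
  taken <- measurements[measurements$taken, , drop = FALSE]
  simple <- detect_simple(taken, thresholds)

  per_user <- split(measurements, measurements$user_id)
  complex_alerts <- dplyr::bind_rows(lapply(per_user, function(log) {
    log <- log[order(log$date, match(log$slot, MEASUREMENT_SLOTS)), ]
    seg <- cumsum(c(1L, diff(log$protocol_level) != 0))
    dplyr::bind_rows(lapply(split(log, seg), function(s) {
      detect_complex(s, ladder_protocol(ladder, s$protocol_level[1]),
                     thresholds, rule)
    }))
  }))
  missed <- detect_missed(measurements, thresholds)

  alerts <- dplyr::bind_rows(simple, complex_alerts, missed)
  alerts <- route_alerts(alerts, policy)
  assign_alert_ids(alerts)
}
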