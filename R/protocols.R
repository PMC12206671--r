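#' Monitoring protocol (one rung of the measurement-algorithm ladder)
#'
#' A monitoring protocol fixes the home blood-pressure target for a phase of
#' care and the cadence of its measurement weeks. Level 0 is the chronic
#' (maintenance) algorithm; levels 1 to 4 are acute titration algorithms,
#' level 4 being the most acute (highest target, most frequent weeks).
#'
#' @param protocol_id Short label, e.g. `"acute-4"`.
#' @param level Integer rank: 0 = chronic, 1..4 = acute (4 most acute).
#' @param sbp_target Systolic target in mmHg (exclusive upper bound:
#'   a week is on target when its summary SBP is strictly below this).
#' @param dbp_target Diastolic target in mmHg (exclusive upper bound).
#' @param week_interval_days Days between starts of consecutive measurement
#'   weeks (7 = weekly, 14 = biweekly, 28 = monthly).
#' @param measurements_per_day Scheduled slots per measurement day
#'   (default 4: two morning, two evening).
#' @return A `monitoring_protocol` object (named list).
#' @export
monitoring_protocol <- function(protocol_id, level, sbp_target, dbp_target,
                                week_interval_days, measurements_per_day = 4) {
  if (!is.numeric(sbp_target) || sbp_target <= 0)
    config_error("sbp_target must be strictly positive", "sbp_target")
  if (!is.numeric(dbp_target) || dbp_target <= 0)
    config_error("dbp_target must be strictly positive", "dbp_target")
  if (measurements_per_day < 1)
    config_error("measurements_per_day must be >= 1", "measurements_per_day")
  if (week_interval_days < 7)
    config_error("week_interval_days must be >= 7 (one measurement week)",
                 "week_interval_days")
  structure(
    list(protocol_id = protocol_id, level = as.integer(level),
         sbp_target = sbp_target, dbp_target = dbp_target,
         week_interval_days = as.integer(week_interval_days),
         measurements_per_day = as.integer(measurements_per_day)),
    class = "monitoring_protocol"
  )
}

#' Protocol ladder: ordered acute-to-chronic set of monitoring protocols
#'
#' Validates the ladder invariants: distinct levels, both blood-pressure
#' targets strictly decreasing as the level falls toward chronic (stricter
#' targets for more stable patients), and measurement-week intervals
#' non-decreasing toward chronic (stable patients measure less often).
#'
#' @param protocols List of [monitoring_protocol()] objects.
#' @return A `protocol_ladder`: a tibble with one row per protocol, ordered
#'   by descending level (most acute first).
#' @export
protocol_ladder <- function(protocols) {
  tab <- dplyr::bind_rows(lapply(protocols, function(p) tibble::as_tibble(unclass(p))))
  tab <- dplyr::arrange(tab, dplyr::desc(.data$level))
  if (anyDuplicated(tab$level))
    config_error("protocol levels must be distinct", "level")
  if (any(diff(tab$sbp_target) >= 0) || any(diff(tab$dbp_target) >= 0))
    config_error("targets must strictly decrease from acute to chronic",
                 "sbp_target/dbp_target")
  if (any(diff(tab$week_interval_days) < 0))
    config_error("week_interval_days must be non-decreasing toward chronic",
                 "week_interval_days")
  class(tab) <- c("protocol_ladder", class(tab))
  tab
}

#' Default five-protocol hypertension ladder
#'
#' Four acute titration algorithms with targets stepping from 180/110 down to
#' 150/95 mmHg, plus one chronic algorithm at 140/90 mmHg. The two most acute
#' levels run weekly measurement weeks, the lower acute levels biweekly, and
#' the chronic algorithm one measurement week per 28 days. All values are
#' overridable by constructing a [protocol_ladder()] directly.
#'
#' @return A `protocol_ladder` with 5 rows (levels 4..0).
#' @examples
#' ladder <- build_default_ladder()
#' ladder[ladder$level == 0, c("sbp_target", "dbp_target")]  # 140/90
#' @export
build_default_ladder <- function() {
  protocol_ladder(list(
    monitoring_protocol("acute-4", 4, 180, 110, 7),
    monitoring_protocol("acute-3", 3, 170, 105, 7),
    monitoring_protocol("acute-2", 2, 160, 100, 14),
    monitoring_protocol("acute-1", 1, 150, 95, 14),
    monitoring_protocol("chronic", 0, 140, 90, 28)
  ))
}

#' @rdname protocol_ladder
#' @param ladder A `protocol_ladder`.
#' @param level Protocol level to extract.
#' @export
ladder_protocol <- function(ladder, level) {
  row <- ladder[ladder$level == level, ]
  if (nrow(row) != 1)
    config_error(sprintf("no protocol at level %s", level), "level")
  monitoring_protocol(row$protocol_id, row$level, row$sbp_target,
                      row$dbp_target, row$week_interval_days,
                      row$measurements_per_day)
}

#' Scheduled measurement slots for a protocol
#'
#' Expands a protocol into its calendar of scheduled slots over a horizon.
#' Measurement weeks are 7 consecutive days starting at `enrollment_date` and
#' recurring every `week_interval_days`; each measurement day carries the
#' protocol's slots (by default morning-1, morning-2, evening-1, evening-2).
#'
#' @param protocol A [monitoring_protocol()].
#' @param enrollment_date `Date`: first day of the first measurement week.
#' @param horizon_days Number of days covered (slots on
#'   `enrollment_date + 0:(horizon_days-1)` only).
#' @return Tibble with columns `date`, `slot`, `week_start`, ordered by date
#'   then slot; deterministic for fixed inputs.
#' @export
schedule_slots <- function(protocol, enrollment_date, horizon_days) {
  if (!is.numeric(horizon_days) || horizon_days < 1)
    config_error("horizon_days must be >= 1", "horizon_days")
  enrollment_date <- as.Date(enrollment_date)
  last_day <- enrollment_date + horizon_days - 1
  week_starts <- seq(enrollment_date, last_day, by = protocol$week_interval_days)
  slots <- MEASUREMENT_SLOTS[seq_len(min(protocol$measurements_per_day, 4L))]
  out <- lapply(week_starts, function(ws) {
    days <- seq(ws, min(ws + 6, last_day), by = 1)
    tibble::tibble(
      date = rep(days, each = length(slots)),
      slot = rep(slots, length(days)),
      week_start = ws
    )
  })
  dplyr::bind_rows(out)
}

#' Evaluate one measurement week against a protocol target
#'
#' Implements the week-level decision that drives automatic movement between
#' protocols: a week is on target when its taken measurements, summarised by
#' `rule`, fall strictly below both the systolic and diastolic targets. An
#' on-target week at an acute level steps the user down one level; the chronic
#' level is the floor. Escalation on off-target weeks is available but off by
#' default (de-escalation is the only automatic movement modelled).
#'
#' A week with no taken measurements is indeterminate: no switch, flagged so
#' inactivity handling can take over.
#'
#' @param measurements Tibble of one user's measurements for one measurement
#'   week (columns `sbp`, `dbp`, `taken`; untaken rows are ignored).
#' @param protocol The [monitoring_protocol()] the week ran under.
#' @param rule Week summary rule: `"mean"` (default; mean of taken readings vs
#'   target), `"all"` (every reading below target) or `"majority"` (more than
#'   half of readings below target).
#' @param escalate If `TRUE`, an off-target week below the most acute level
#'   steps up one level. Default `FALSE`.
#' @return List with `on_target` (logical, `NA` if indeterminate), `decision`
#'   (`"step-down"`, `"stay"` or `"step-up"`), `n_taken`, `indeterminate`.
#' @export
evaluate_week <- function(measurements, protocol,
                          rule = c("mean", "all", "majority"),
                          escalate = FALSE) {
  rule <- match.arg(rule)
  taken <- measurements[measurements$taken, , drop = FALSE]
  n_taken <- nrow(taken)
  if (n_taken == 0) {
    return(list(on_target = NA, decision = "stay",
                n_taken = 0L, indeterminate = TRUE))
  }
  on_target <- switch(
    rule,
    mean = mean(taken$sbp) < protocol$sbp_target &&
      mean(taken$dbp) < protocol$dbp_target,
    all = all(taken$sbp < protocol$sbp_target & taken$dbp < protocol$dbp_target),
    majority = mean(taken$sbp < protocol$sbp_target &
                      taken$dbp < protocol$dbp_target) > 0.5
  )
  decision <- if (on_target && protocol$level > 0) {
    "step-down"
  } else if (!on_target && escalate && protocol$level < 4) {
    "step-up"
  } else {
    "stay"
  }
  list(on_target = on_target, decision = decision,
       n_taken = as.integer(n_taken), indeterminate = FALSE)
}
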