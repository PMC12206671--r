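#' Synthetic cohort configuration
#'
#' Parameters of the seeded synthetic home-monitoring cohort. Defaults emulate
#' the study population the package models: 174 users enrolled over a one-year
#' window, active about 207 days on average, 45% starting in the chronic
#' (monthly) algorithm, and a 15% elevated-blood-pressure subgroup whose
#' shifted means concentrate most of the manual alert burden in few users.
#' Per-user true means come from a two-component Gaussian mixture (background
#' plus elevated subgroup); within-user measurement noise is Gaussian;
#' adherence (the probability a scheduled slot is actually taken) is Beta
#' distributed across users; a fraction of users stop measuring at a dropout
#' date, which creates inactivity cases.
#'
#' @param n_users Number of users (default 174).
#' @param study_start,study_end Study window (`Date`), default one year.
#' @param frac_chronic_start Probability a user starts at the chronic level
#'   (default 0.45); remaining users start at an acute level drawn uniformly
#'   from 1..4.
#' @param mean_active_days,sd_active_days,min_active_days Per-user active-day
#'   distribution: normal, truncated to `[min_active_days, window length]`
#'   (defaults 207 / 70 / 14).
#' @param user_mean_sbp_dist,user_mean_dbp_dist,user_mean_hr_dist Named
#'   vectors `c(mean=, sd=)` of the background per-user true-mean
#'   distributions (mmHg, mmHg, bpm).
#' @param within_user_sd_sbp,within_user_sd_dbp,within_user_sd_hr Within-user
#'   measurement noise SDs.
#' @param adherence_dist Named vector `c(shape1=, shape2=)` of the Beta
#'   distribution of per-user adherence probability (default mean 0.72;
#'   `shape2 = 0` degenerates to full adherence).
#' @param high_alert_frac Fraction of users in the elevated subgroup
#'   (default 0.15; assigned as a fixed-size random draw of
#'   `round(high_alert_frac * n_users)` users).
#' @param high_alert_shift_sbp,high_alert_shift_dbp mmHg added to subgroup
#'   true means (defaults +25 / +15).
#' @param dropout_frac Fraction of users who stop measuring before the end of
#'   their active period (default 0.10).
#' @param seed Integer RNG seed; every random draw in the generator flows from
#'   it, so equal configs give byte-identical cohorts.
#' @return A validated `cohort_config` (named list).
#' @export
cohort_config <- function(n_users = 174,
                          study_start = as.Date("2022-06-01"),
                          study_end = as.Date("2023-05-31"),
                          frac_chronic_start = 0.45,
                          mean_active_days = 207,
                          sd_active_days = 70,
                          min_active_days = 14,
                          user_mean_sbp_dist = c(mean = 142, sd = 10),
                          user_mean_dbp_dist = c(mean = 88, sd = 7),
                          user_mean_hr_dist = c(mean = 72, sd = 8),
                          within_user_sd_sbp = 10,
                          within_user_sd_dbp = 6,
                          within_user_sd_hr = 5,
                          adherence_dist = c(shape1 = 7.2, shape2 = 2.8),
                          high_alert_frac = 0.15,
                          high_alert_shift_sbp = 25,
                          high_alert_shift_dbp = 15,
                          dropout_frac = 0.10,
                          seed = 20220601L) {
  cfg <- list(
    n_users = as.integer(n_users),
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    frac_chronic_start = frac_chronic_start,
    mean_active_days = mean_active_days, sd_active_days = sd_active_days,
    min_active_days = min_active_days,
    user_mean_sbp_dist = user_mean_sbp_dist,
    user_mean_dbp_dist = user_mean_dbp_dist,
    user_mean_hr_dist = user_mean_hr_dist,
    within_user_sd_sbp = within_user_sd_sbp,
    within_user_sd_dbp = within_user_sd_dbp,
    within_user_sd_hr = within_user_sd_hr,
    adherence_dist = adherence_dist,
    high_alert_frac = high_alert_frac,
    high_alert_shift_sbp = high_alert_shift_sbp,
    high_alert_shift_dbp = high_alert_shift_dbp,
    dropout_frac = dropout_frac,
    seed = as.integer(seed)
  )
  if (cfg$n_users < 1) config_error("n_users must be >= 1", "n_users")
  if (cfg$study_end <= cfg$study_start)
    config_error("study_end must be after study_start", "study_end")
  for (f in c("frac_chronic_start", "high_alert_frac", "dropout_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      config_error(sprintf("%s must be in [0, 1]", f), f)
  }
  for (f in c("sd_active_days", "within_user_sd_sbp", "within_user_sd_dbp",
              "within_user_sd_hr")) {
    if (cfg[[f]] < 0) config_error(sprintf("%s must be >= 0", f), f)
  }
  for (f in c("user_mean_sbp_dist", "user_mean_dbp_dist", "user_mean_hr_dist")) {
    v <- cfg[[f]]
    if (!all(c("mean", "sd") %in% names(v)) || v[["sd"]] < 0)
      config_error(sprintf("%s needs names mean, sd with sd >= 0", f), f)
  }
  if (!all(c("shape1", "shape2") %in% names(cfg$adherence_dist)) ||
      cfg$adherence_dist[["shape1"]] <= 0 || cfg$adherence_dist[["shape2"]] < 0)
    config_error(
      "adherence_dist needs shape1 > 0 and shape2 >= 0 (0 = full adherence)",
      "adherence_dist")
  structure(cfg, class = "cohort_config")
}

# Normal truncated to [lo, hi] by rejection (vectorised resampling).
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Draw the user table of a synthetic cohort
#'
#' Samples per-user attributes (enrollment, activity span, starting protocol
#' level, true vital means, adherence, subgroup and dropout status) without
#' simulating any measurements. Seeds the RNG from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Tibble with one row per user: `user_id`, `enrollment_date`,
#'   `active_days`, `start_protocol_level`, `true_mean_sbp`, `true_mean_dbp`,
#'   `true_mean_hr`, `adherence_p`, `high_alert_member`, `dropout_date`
#'   (`NA` for completers).
#' @export
draw_cohort_users <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_users
  window_len <- as.integer(config$study_end - config$study_start) + 1L

  active_days <- round(rnorm_trunc(
    n, config$mean_active_days, config$sd_active_days,
    config$min_active_days, window_len))
  enroll_offset <- floor(stats::runif(n, 0, window_len - active_days + 1))
  enrollment_date <- config$study_start + enroll_offset

  chronic <- stats::runif(n) < config$frac_chronic_start
  acute_level <- sample(1:4, n, replace = TRUE)
  start_level <- ifelse(chronic, 0L, acute_level)

  sbp <- stats::rnorm(n, config$user_mean_sbp_dist[["mean"]],
                      config$user_mean_sbp_dist[["sd"]])
  dbp <- stats::rnorm(n, config$user_mean_dbp_dist[["mean"]],
                      config$user_mean_dbp_dist[["sd"]])
  hr <- stats::rnorm(n, config$user_mean_hr_dist[["mean"]],
                     config$user_mean_hr_dist[["sd"]])
  n_high <- round(config$high_alert_frac * n)
  high_idx <- if (n_high > 0) sample.int(n, n_high) else integer(0)
  high <- seq_len(n) %in% high_idx
  sbp[high] <- sbp[high] + config$high_alert_shift_sbp
  dbp[high] <- dbp[high] + config$high_alert_shift_dbp

  adherence <- stats::rbeta(n, config$adherence_dist[["shape1"]],
                            config$adherence_dist[["shape2"]])

  dropout <- stats::runif(n) < config$dropout_frac
  dropout_frac_of_span <- stats::runif(n, 0.25, 0.9)
  dropout_date <- as.Date(ifelse(
    dropout,
    enrollment_date + floor(active_days * dropout_frac_of_span),
    NA), origin = "1970-01-01")

  tibble::tibble(
    user_id = sprintf("U%04d", seq_len(n)),
    enrollment_date = enrollment_date,
    active_days = as.integer(active_days),
    start_protocol_level = as.integer(start_level),
    true_mean_sbp = sbp, true_mean_dbp = dbp, true_mean_hr = hr,
    adherence_p = adherence,
    high_alert_member = high,
    dropout_date = dropout_date
  )
}

# Simulate one user's measurement rows, walking measurement weeks and
# applying automatic protocol switching after each evaluated week.
simulate_user <- function(user, config, ladder, rule) {
  level <- user$start_protocol_level
  week_start <- user$enrollment_date
  last_day <- user$enrollment_date + user$active_days - 1L
  weeks <- list()
  i <- 0L
  while (week_start <= last_day) {
    proto <- ladder[ladder$level == level, ]
    days <- seq(week_start, min(week_start + 6, last_day), by = 1)
    n_slots_day <- min(proto$measurements_per_day, 4L)
    slots <- MEASUREMENT_SLOTS[seq_len(n_slots_day)]
    date <- rep(days, each = n_slots_day)
    slot <- rep(slots, length(days))
    m <- length(date)

    taken <- stats::runif(m) < user$adherence_p
    if (!is.na(user$dropout_date)) taken[date >= user$dropout_date] <- FALSE

    sbp <- dbp <- hr <- rep(NA_real_, m)
    k <- sum(taken)
    if (k > 0) {
      s <- round(stats::rnorm(k, user$true_mean_sbp, config$within_user_sd_sbp))
      d <- round(stats::rnorm(k, user$true_mean_dbp, config$within_user_sd_dbp))
      h <- round(stats::rnorm(k, user$true_mean_hr, config$within_user_sd_hr))
      s <- pmax(s, 60)
      d <- pmax(pmin(d, s - 5), 30)  # keep sbp > dbp, both physiological
      h <- pmax(h, 30)
      sbp[taken] <- s; dbp[taken] <- d; hr[taken] <- h
    }

    i <- i + 1L
    weeks[[i]] <- data.frame(
      user_id = user$user_id, date = date, slot = slot,
      sbp = sbp, dbp = dbp, hr = hr, taken = taken,
      protocol_level = level, week_start = week_start
    )

    ev <- evaluate_week(
      data.frame(sbp = sbp[taken], dbp = dbp[taken],
                 taken = rep(TRUE, sum(taken))),
      ladder_protocol(ladder, level), rule = rule)
    if (identical(ev$decision, "step-down")) level <- level - 1L
    if (identical(ev$decision, "step-up")) level <- level + 1L
    week_start <- week_start + proto$week_interval_days
  }
  do.call(rbind, weeks)
}

#' Generate a synthetic telemonitoring cohort
#'
#' Produces the user table and the full measurement log (taken and missed
#' slots). Each user walks the protocol ladder week by week: slots follow the
#' current protocol's schedule, each slot is taken with the user's adherence
#' probability (never after the dropout date), taken vitals are the user's
#' true mean plus within-user noise (rounded to integers, with diastolic
#' clipped below systolic), and an on-target week steps the user down one
#' protocol level via [evaluate_week()].
#'
#' @param config A [cohort_config()].
#' @param ladder A [protocol_ladder()] (default [build_default_ladder()]).
#' @param rule Week-evaluation rule passed to [evaluate_week()].
#' @return List with `users` (see [draw_cohort_users()]) and `measurements`:
#'   tibble `measurement_id`, `user_id`, `date`, `slot`, `sbp`, `dbp`, `hr`,
#'   `taken`, `protocol_level`, `week_start`. Fully reproducible given
#'   `config$seed`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_users = 5, seed = 1))
#' table(cohort$measurements$taken)
#' @export
generate_cohort <- function(config = cohort_config(),
                            ladder = build_default_ladder(),
                            rule = "mean") {
  users <- draw_cohort_users(config)
  logs <- lapply(seq_len(nrow(users)), function(i)
    simulate_user(as.list(users[i, ]), config, ladder, rule))
  log <- tibble::as_tibble(do.call(rbind, logs))
  log$date <- as.Date(log$date, origin = "1970-01-01")
  log$week_start <- as.Date(log$week_start, origin = "1970-01-01")
  log <- tibble::add_column(
    log, measurement_id = measurement_id(log$user_id, log$date, log$slot),
    .before = 1)
  list(users = users, measurements = log)
}

#' Realized-versus-configured cohort calibration report
#'
#' Compares realized cohort statistics with their configured targets and
#' flags relative deviations beyond `tolerance`. Quantities without a
#' configured target (total measurements) can be checked against an external
#' reference count via `target_measurements`.
#'
#' @param users,measurements Output of [generate_cohort()].
#' @param config The [cohort_config()] used.
#' @param tolerance Relative deviation that raises a flag (default 0.2).
#' @param target_measurements Optional reference count of taken measurements.
#' @return Tibble with one row per statistic: `statistic`, `realized`,
#'   `target`, `rel_deviation`, `flag`.
#' @export
calibration_report <- function(users, measurements, config,
                               tolerance = 0.2, target_measurements = NA) {
  if (nrow(users) == 0) data_error("empty cohort")
  realized <- c(
    n_users = nrow(users),
    mean_active_days = mean(users$active_days),
    n_measurements = sum(measurements$taken),
    frac_chronic_start = mean(users$start_protocol_level == 0)
  )
  target <- c(
    n_users = config$n_users,
    mean_active_days = config$mean_active_days,
    n_measurements = target_measurements,
    frac_chronic_start = config$frac_chronic_start
  )
  rel <- abs(realized - target) / ifelse(target == 0, NA, target)
  tibble::tibble(
    statistic = names(realized),
    realized = unname(realized),
    target = unname(target),
    rel_deviation = unname(rel),
    flag = !is.na(rel) & rel > tolerance
  )
}
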