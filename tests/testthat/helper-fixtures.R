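# Builders for small in-code fixtures used across the suite.

# One or more taken measurement rows with sensible defaults.
make_measurements <- function(user_id = "U0001",
                              date = as.Date("2022-06-06"),  # a Monday
                              slot = "morning-1",
                              sbp = 120, dbp = 80, hr = 70,
                              taken = TRUE, ...) {
  n <- max(lengths(list(user_id, date, slot, sbp, dbp, hr, taken)))
  m <- tibble::tibble(
    user_id = rep_len(user_id, n),
    date = rep_len(date, n),
    slot = rep_len(slot, n),
    sbp = rep_len(sbp, n), dbp = rep_len(dbp, n), hr = rep_len(hr, n),
    taken = rep_len(taken, n), ...
  )
  m$sbp[!m$taken] <- NA_real_
  m$dbp[!m$taken] <- NA_real_
  m$hr[!m$taken] <- NA_real_
  tibble::add_column(
    m, measurement_id = measurement_id(m$user_id, m$date, m$slot),
    .before = 1)
}

# A full single-protocol measurement week for one user: 7 days x 4 slots,
# constant vitals, selectable per-slot taken pattern.
make_week <- function(user_id = "U0001",
                      week_start = as.Date("2022-06-06"),
                      sbp = 120, dbp = 80, hr = 70,
                      taken = TRUE, protocol_level = 0L) {
  grid <- expand.grid(
    slot = MEASUREMENT_SLOTS,
    date = seq(week_start, week_start + 6, by = 1),
    stringsAsFactors = FALSE)
  make_measurements(
    user_id = user_id, date = grid$date, slot = grid$slot,
    sbp = sbp, dbp = dbp, hr = hr,
    taken = rep_len(taken, nrow(grid)),
    protocol_level = protocol_level, week_start = week_start)
}

# Small cohort config for fast end-to-end tests.
small_config <- function(n_users = 12, seed = 101, ...) {
  cohort_config(
    n_users = n_users,
    study_start = as.Date("2022-06-01"), study_end = as.Date("2022-11-30"),
    mean_active_days = 90, sd_active_days = 30, seed = seed, ...)
}

# A single manual alert row (for clustering/concentration fixtures).
manual_alert <- function(user_id, date, alert_type = "simple_dbp_high",
                         exceedance = 5) {
  tibble::tibble(
    alert_id = sprintf("A:%s:%s:%s:1", user_id, format(date), alert_type),
    user_id = user_id, trigger_date = as.Date(date), alert_type = alert_type,
    source_measurement_ids = "m", n_sources = 1L,
    exceedance = exceedance, routing = "manual")
}

# Independent brute-force oracle for simple alerts: scan every taken
# measurement against every bound, one record per violation.
brute_force_simple <- function(measurements, th) {
  taken <- measurements[measurements$taken, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(taken))) {
    r <- taken[i, ]
    hits <- c(
      if (r$sbp >= th$simple_sbp_high) "simple_sbp_high",
      if (r$sbp <= th$simple_sbp_low) "simple_sbp_low",
      if (r$dbp >= th$simple_dbp_high) "simple_dbp_high",
      if (r$dbp <= th$simple_dbp_low) "simple_dbp_low",
      if (r$hr >= th$simple_hr_high) "simple_hr_high",
      if (r$hr <= th$simple_hr_low) "simple_hr_low"
    )
    for (h in hits) {
      out[[length(out) + 1L]] <- data.frame(
        user_id = r$user_id, measurement_id = r$measurement_id,
        alert_type = h, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(user_id = character(), measurement_id = character(),
                      alert_type = character()))
  }
  do.call(rbind, out)
}

sort_key <- function(df, cols) do.call(order, unname(as.list(df[cols])))
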