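test_that("simple alerts use inclusive bounds, one alert per violated bound", {
  th <- alert_thresholds()
  # diastolic 106 crosses the >=105 bound
  a <- detect_simple(make_measurements(sbp = 150, dbp = 106), th)
  expect_equal(nrow(a), 1)
  expect_equal(a$alert_type, "simple_dbp_high")
  expect_equal(a$exceedance, 1)
  expect_equal(a$n_sources, 1L)

  # strictly below an inclusive bound: no alert; exactly at the bound: alert
  expect_equal(nrow(detect_simple(make_measurements(sbp = 169, dbp = 95), th)), 0)
  expect_equal(detect_simple(make_measurements(sbp = 170, dbp = 95), th)$alert_type,
               "simple_sbp_high")

  # one crisis reading can violate two bounds at once
  two <- detect_simple(make_measurements(sbp = 240, dbp = 130), th)
  expect_setequal(two$alert_type, c("simple_sbp_high", "simple_dbp_high"))
  expect_equal(unique(two$source_measurement_ids),
               make_measurements(sbp = 240, dbp = 130)$measurement_id)

  # low bounds are symmetric (<=)
  low <- detect_simple(make_measurements(sbp = 88, dbp = 52, hr = 44), th)
  expect_setequal(low$alert_type, c("simple_sbp_low", "simple_hr_low"))

  expect_error(detect_simple(make_measurements(taken = FALSE), th),
               class = "telealert_contract_error")
})

test_that("complex off-target alerts fire once per run of >= k violations", {
  chronic <- ladder_protocol(build_default_ladder(), 0)
  th <- alert_thresholds(complex_consecutive_k = 4)
  days <- as.Date("2022-06-06") + 0:6

  runlog <- function(sbp, dbp) {
    make_measurements(
      date = rep(days, each = 4)[seq_along(sbp)],
      slot = rep(MEASUREMENT_SLOTS, 7)[seq_along(sbp)],
      sbp = sbp, dbp = dbp,
      week_start = as.Date("2022-06-06"))
  }

  # exactly k consecutive off-target readings: one alert, anchored at the k-th
  four <- runlog(rep(150, 4), rep(96, 4))
  a <- detect_complex(four, chronic, th)
  off <- a[a$alert_type == "complex_off_target", ]
  expect_equal(nrow(off), 1)
  expect_equal(off$n_sources, 4L)
  expect_equal(off$trigger_date, four$date[4])

  # run shorter than k: nothing
  three <- runlog(c(150, 150, 150, 120), c(96, 96, 96, 70))
  expect_equal(sum(detect_complex(three, chronic, th)$alert_type ==
                     "complex_off_target"), 0)

  # a long run still fires once; two separated runs fire twice
  eight <- runlog(rep(150, 8), rep(96, 8))
  expect_equal(sum(detect_complex(eight, chronic, th)$alert_type ==
                     "complex_off_target"), 1)
  split2 <- runlog(c(rep(150, 4), 120, rep(150, 4)), c(rep(96, 4), 70, rep(96, 4)))
  expect_equal(sum(detect_complex(split2, chronic, th)$alert_type ==
                     "complex_off_target"), 2)

  # an on-target measurement week raises the on-target (switch/feedback) alert
  good <- make_week(sbp = 120, dbp = 75)
  on <- detect_complex(good, chronic, th)
  expect_equal(on$alert_type, "complex_on_target_switch")
  expect_equal(on$trigger_date, max(good$date))

  unsorted <- four[c(2, 1, 3, 4), ]
  expect_error(detect_complex(unsorted, chronic, th),
               class = "telealert_contract_error")
})

test_that("missed slots raise overdue alerts and silent weeks inactive alerts", {
  th <- alert_thresholds(inactivity_window_days = 7)

  # one missed slot among a taken week
  w <- make_week(taken = c(FALSE, rep(TRUE, 27)))
  a <- detect_missed(w, th)
  expect_equal(sum(a$alert_type == "overdue"), 1)
  expect_equal(sum(a$alert_type == "inactive"), 0)

  # an entirely missed 7-day week: 28 overdue + 1 inactive
  silent <- make_week(taken = FALSE)
  a2 <- detect_missed(silent, th)
  expect_equal(sum(a2$alert_type == "overdue"), 28)
  expect_equal(sum(a2$alert_type == "inactive"), 1)
  expect_equal(a2$trigger_date[a2$alert_type == "inactive"], max(silent$date))

  # full adherence: no missed-type alerts at all
  expect_equal(nrow(detect_missed(make_week(taken = TRUE), th)), 0)

  # window longer than the silent run: no inactive alert
  a3 <- detect_missed(silent, alert_thresholds(inactivity_window_days = 8))
  expect_equal(sum(a3$alert_type == "inactive"), 0)
})

test_that("routing applies the policy totally and conserves counts", {
  cohort <- generate_cohort(small_config(n_users = 6))
  alerts <- run_engine(cohort$measurements, cohort$users)
  expect_equal(sum(alerts$routing == "auto") + sum(alerts$routing == "manual"),
               nrow(alerts))
  # default policy: overdue auto, on-target auto, everything else manual
  expect_true(all(alerts$routing[alerts$alert_type == "overdue"] == "auto"))
  expect_true(all(alerts$routing[alerts$alert_type == "complex_on_target_switch"]
                  == "auto"))
  expect_true(all(alerts$routing[grepl("^simple", alerts$alert_type)] == "manual"))
  expect_true(all(alerts$routing[alerts$alert_type %in%
                                   c("complex_off_target", "inactive")] == "manual"))

  # conservation holds for arbitrary policies (property over random policies)
  set.seed(11)
  for (i in 1:10) {
    pol <- setNames(sample(c("auto", "manual"), length(ALERT_TYPES), TRUE),
                    ALERT_TYPES)
    routed <- route_alerts(alerts[, setdiff(names(alerts), "routing")], pol)
    expect_equal(sum(routed$routing == "auto") + sum(routed$routing == "manual"),
                 nrow(alerts))
  }

  expect_error(route_alerts(alerts, c(overdue = "auto")),
               class = "telealert_config_error")
  expect_equal(nrow(route_alerts(empty_alerts())), 0)
})

test_that("engine simple alerts match the brute-force oracle on small cohorts", {
  th <- alert_thresholds()
  cohort <- generate_cohort(small_config(n_users = 15, seed = 303))
  alerts <- run_engine(cohort$measurements, cohort$users, thresholds = th)
  got <- alerts[grepl("^simple", alerts$alert_type),
                c("user_id", "source_measurement_ids", "alert_type")]
  names(got)[2] <- "measurement_id"
  want <- brute_force_simple(cohort$measurements, th)
  expect_gt(nrow(want), 0)
  got <- got[sort_key(got, names(got)), ]
  want <- want[sort_key(want, names(want)), ]
  expect_equal(unname(as.list(got)), unname(as.list(want)),
               ignore_attr = TRUE)
})

test_that("raising a high threshold never increases that alert count", {
  set.seed(23)
  for (i in 1:8) {
    m <- make_measurements(
      date = as.Date("2022-06-06") + rep(0:13, each = 4),
      slot = rep(MEASUREMENT_SLOTS, 14),
      sbp = round(rnorm(56, 160, 25)), dbp = round(rnorm(56, 95, 12)),
      hr = round(rnorm(56, 80, 15)))
    counts <- vapply(c(150, 160, 170, 180, 190), function(cut) {
      a <- detect_simple(m, alert_thresholds(simple_sbp_high = cut))
      sum(a$alert_type == "simple_sbp_high")
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
    low_counts <- vapply(c(110, 100, 90), function(cut) {
      a <- detect_simple(m, alert_thresholds(simple_sbp_low = cut))
      sum(a$alert_type == "simple_sbp_low")
    }, numeric(1))
    expect_true(all(diff(low_counts) <= 0))
  }
})

test_that("every overdue alert maps to exactly one scheduled-but-missed slot", {
  cohort <- generate_cohort(small_config(n_users = 10, seed = 77))
  alerts <- run_engine(cohort$measurements, cohort$users)
  n_overdue <- sum(alerts$alert_type == "overdue")
  expect_equal(n_overdue, sum(!cohort$measurements$taken))
  expect_lte(n_overdue, nrow(cohort$measurements))
  expect_false(anyDuplicated(alerts$alert_id) > 0)
})
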