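test_that("weekend alerts consolidate into the following Monday's action", {
  # 2022-06-11 is a Saturday, 2022-06-12 a Sunday
  a <- rbind(manual_alert("U1", "2022-06-11"), manual_alert("U1", "2022-06-12"))
  a$alert_id <- c("A1", "A2")
  acts <- cluster_actions(a)
  expect_equal(nrow(acts), 1)
  expect_equal(acts$processing_date, as.Date("2022-06-13"))  # Monday
  expect_equal(acts$n_alerts, 2L)
  expect_setequal(strsplit(acts$member_alert_ids, ";")[[1]], c("A1", "A2"))
})

test_that("actions cluster per user per day and partition the manual alerts", {
  tue <- as.Date("2022-06-07")
  a <- rbind(
    manual_alert("UA", tue, "simple_dbp_high"),
    manual_alert("UA", tue, "simple_sbp_high"),
    manual_alert("UA", tue, "complex_off_target"),
    manual_alert("UB", tue, "simple_dbp_high"))
  a$alert_id <- paste0("A", 1:4)
  acts <- cluster_actions(a)
  expect_equal(nrow(acts), 2)
  expect_equal(sort(acts$n_alerts), c(1L, 3L))

  # partition over a realistic log: total conserved, no alert in two actions
  cohort <- generate_cohort(small_config(n_users = 10, seed = 9))
  alerts <- run_engine(cohort$measurements, cohort$users)
  manual <- alerts[alerts$routing == "manual", ]
  acts2 <- cluster_actions(manual)
  members <- unlist(strsplit(acts2$member_alert_ids, ";"))
  expect_equal(sum(acts2$n_alerts), nrow(manual))
  expect_setequal(members, manual$alert_id)
  expect_equal(anyDuplicated(members), 0L)
  # no weekend processing dates, ever
  expect_true(all(!format(acts2$processing_date, "%u") %in% c("6", "7")))

  auto <- alerts[alerts$routing == "auto", ][1, ]
  expect_error(cluster_actions(auto), class = "telealert_contract_error")
})

test_that("classification is seeded, degenerate at p = 1, and calibrated", {
  acts <- tibble::tibble(
    action_id = paste0("T", 1:10000), user_id = "U1",
    processing_date = as.Date("2022-06-06"),
    member_alert_ids = "x", n_alerts = 1L, max_exceedance = 0)

  all_admin <- classify_actions(acts, action_class_model(p_administrative = 1),
                                seed = 3)
  expect_true(all(all_admin$action_class == "administrative"))
  expect_true(all(all_admin$clinical_subtype == "none"))

  m <- action_class_model()
  c1 <- classify_actions(acts, m, seed = 42)
  c2 <- classify_actions(acts, m, seed = 42)
  expect_identical(c1, c2)

  share <- mean(c1$action_class == "administrative")
  expect_lt(abs(share - 0.77), 3 * sqrt(0.77 * 0.23 / 10000))
  # clinical subtypes only on clinical actions
  expect_true(all((c1$clinical_subtype == "none") ==
                    (c1$action_class == "administrative")))
})

test_that("severity covariate pushes high-exceedance actions toward clinical", {
  set.seed(8)
  acts <- tibble::tibble(
    action_id = paste0("T", 1:20000), user_id = "U1",
    processing_date = as.Date("2022-06-06"),
    member_alert_ids = "x", n_alerts = 1L,
    max_exceedance = rexp(20000, 1 / 10))
  cl <- classify_actions(acts, action_class_model(), seed = 5)
  hi <- cl$max_exceedance > stats::median(cl$max_exceedance)
  p_cli_hi <- mean(cl$action_class[hi] == "clinical")
  p_cli_lo <- mean(cl$action_class[!hi] == "clinical")
  expect_gt(p_cli_hi, p_cli_lo)
  # marginal stays calibrated at p_administrative despite the covariate
  expect_lt(abs(mean(cl$action_class == "administrative") - 0.77),
            3 * sqrt(0.77 * 0.23 / 20000))
})

test_that("workload arithmetic is linear and matches the cost model", {
  mk <- function(n_adm, n_cli) tibble::tibble(
    action_id = paste0("T", seq_len(n_adm + n_cli)),
    action_class = rep(c("administrative", "clinical"), c(n_adm, n_cli)))
  w <- compute_workload(mk(1626, 475))
  expect_equal(w$total_minutes, 1626 * 5 + 475 * 10)  # 12880
  expect_equal(w$minutes_administrative + w$minutes_clinical, w$total_minutes)
  expect_equal(compute_workload(mk(0, 0))$total_minutes, 0)
  expect_equal(compute_workload(mk(1, 1))$total_minutes, 15)
  # linearity over a disjoint split
  both <- mk(37, 13)
  expect_equal(
    compute_workload(both)$total_minutes,
    compute_workload(both[1:20, ])$total_minutes +
      compute_workload(both[21:50, ])$total_minutes)
  expect_error(compute_workload(tibble::tibble(action_id = "T1")),
               class = "telealert_contract_error")
})

test_that("proportion-mode workload reproduces the printed worked examples", {
  expect_equal(workload_from_proportions(1023, 0.71), 6598)
  expect_equal(workload_from_proportions(873, 0.71), 5631)
  expect_equal(workload_from_proportions(0, 0.5), 0)
  # differs from count-mode by less than one clinical action's minutes
  set.seed(15)
  for (i in 1:20) {
    n <- sample(1:2000, 1)
    p <- runif(1)
    n_adm <- round_half_up(n * p)
    count_mode <- 5 * n_adm + 10 * (n - n_adm)
    expect_lt(abs(workload_from_proportions(n, p) - count_mode), 10)
  }
  expect_error(workload_from_proportions(10, 1.2),
               class = "telealert_config_error")
})

test_that("invalid classification models are rejected", {
  expect_error(action_class_model(p_administrative = 1.5),
               class = "telealert_config_error")
  expect_error(
    action_class_model(clinical_subtype_probs = c(
      phone_no_adjust = 0.5, phone_adjust = 0.5,
      message_no_adjust = 0.5, message_adjust = 0.5)),
    class = "telealert_config_error")
  expect_error(workload_model(minutes_administrative = 0),
               class = "telealert_config_error")
})
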