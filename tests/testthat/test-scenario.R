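# A small labelled manual simple-alert log with known measurement values.
labelled_log <- function(sbp = c(172, 168, 185),
                         classes = c("administrative", "administrative",
                                     "clinical")) {
  m <- make_measurements(
    date = as.Date("2022-06-06") + seq_along(sbp) - 1,
    sbp = sbp, dbp = 80)
  alerts <- detect_simple(m, alert_thresholds())
  alerts$routing <- "manual"
  alerts <- tibble::add_column(
    alerts, alert_id = paste0("A", seq_len(nrow(alerts))), .before = 1)
  alerts$action_class <- classes[seq_len(nrow(alerts))]
  list(measurements = m, alerts = alerts)
}

test_that("rescoring keeps alerts whose recorded value meets the new threshold", {
  lg <- labelled_log()  # readings 172, 168, 185 against >=170: two alerts
  expect_equal(nrow(lg$alerts), 2)
  surv <- rescore_alerts(lg$alerts, lg$measurements,
                         scenario_spec("simple_sbp_high", 170, 180))
  expect_equal(nrow(surv), 1)
  expect_equal(surv$source_measurement_ids,
               lg$measurements$measurement_id[lg$measurements$sbp == 185])

  # identity scenario: the alert set is untouched
  same <- rescore_alerts(lg$alerts, lg$measurements,
                         scenario_spec("simple_sbp_high", 170, 170))
  expect_identical(same, lg$alerts)

  # other alert types pass through
  mixed <- dplyr::bind_rows(lg$alerts,
                            manual_alert("U0001", "2022-06-09",
                                         "complex_off_target"))
  mixed$action_class[is.na(mixed$action_class)] <- "clinical"
  surv2 <- rescore_alerts(mixed, lg$measurements,
                          scenario_spec("simple_sbp_high", 170, 200))
  expect_true("complex_off_target" %in% surv2$alert_type)

  broken <- lg$alerts
  broken$source_measurement_ids[1] <- "nope"
  expect_error(rescore_alerts(broken, lg$measurements,
                              scenario_spec("simple_sbp_high", 170, 180)),
               class = "telealert_data_error")
})

test_that("scenario specs validate direction and type", {
  expect_error(scenario_spec("complex_off_target", 105, 110),
               class = "telealert_config_error")
  expect_error(scenario_spec("simple_dbp_high", 105, 100),
               class = "telealert_config_error")
  expect_error(scenario_spec("simple_hr_low", 45, 50),
               class = "telealert_config_error")
  expect_silent(scenario_spec("simple_hr_low", 45, 40))
  expect_equal(length(default_scenario_specs()), 6)
})

test_that("extrapolation recomputes proportions among survivors", {
  lg <- labelled_log(sbp = c(175, 172, 185),
                     classes = c("administrative", "administrative", "clinical"))
  ext <- extrapolate_processing(lg$alerts)
  expect_equal(ext$p_administrative, 2 / 3)
  expect_equal(ext$p_clinical, 1 / 3)
  expect_equal(ext$n_administrative_projected + ext$n_clinical_projected,
               ext$n_surviving)

  all_admin <- labelled_log(sbp = c(175, 172),
                            classes = c("administrative", "administrative"))
  expect_equal(extrapolate_processing(all_admin$alerts)$p_administrative, 1)

  none <- extrapolate_processing(lg$alerts[0, ])
  expect_true(none$empty)
  expect_true(is.na(none$p_administrative))

  cf <- extrapolate_processing(lg$alerts, p_administrative_current = 0.71,
                               mode = "carry_forward")
  expect_equal(cf$p_administrative, 0.71)
  expect_equal(cf$n_administrative_projected + cf$n_clinical_projected,
               cf$n_surviving)
})

test_that("time-saving arithmetic matches the proportion-mode baselines", {
  s0 <- scenario_time_saving(873, 0.71, 873, 0.71)
  expect_equal(s0$minutes_saved, 0)
  s1 <- scenario_time_saving(1023, 0.71, 542, 0.67)
  expect_equal(s1$baseline_minutes, 6598)
  expect_equal(s1$minutes_saved, 6598 - workload_from_proportions(542, 0.67))
  expect_equal(s1$minutes_saved, 2994)
  # empty scenario costs nothing new
  s2 <- scenario_time_saving(100, 0.8, 0, NA)
  expect_equal(s2$new_minutes, 0)
})

test_that("scenario table rows are independent, deterministic and monotone", {
  cohort <- generate_cohort(small_config(n_users = 15, seed = 303))
  alerts <- run_engine(cohort$measurements, cohort$users)
  manual <- alerts[alerts$routing == "manual", ]
  actions <- classify_actions(cluster_actions(manual), seed = 7)

  tab <- scenario_table(default_scenario_specs(), alerts,
                        cohort$measurements, actions)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$n_alerts_surviving + tab$n_alerts_removed,
               tab$n_alerts_current)
  for (ty in unique(tab$alert_type)) {
    rows <- tab[tab$alert_type == ty, ]
    expect_true(all(diff(rows$pct_reduction) >= 0))
    expect_true(all(diff(rows$minutes_saved) >= 0))
    expect_true(all(rows$minutes_saved >= 0))
  }

  # duplicate spec gives an identical row (purity)
  dup <- scenario_table(list(scenario_spec("simple_dbp_high", 105, 110),
                             scenario_spec("simple_dbp_high", 105, 110)),
                        alerts, cohort$measurements, actions)
  expect_identical(dup[1, ], dup[2, ])

  # identity scenarios: zero reduction and zero saving for every simple type
  idents <- lapply(c(170, 90, 105, 50, 110, 45), function(x) x)
  types <- c("simple_sbp_high", "simple_sbp_low", "simple_dbp_high",
             "simple_dbp_low", "simple_hr_high", "simple_hr_low")
  id_specs <- Map(function(ty, cut) scenario_spec(ty, cut, cut), types, idents)
  id_tab <- scenario_table(id_specs, alerts, cohort$measurements, actions)
  expect_true(all(id_tab$minutes_saved == 0))
  expect_true(all(id_tab$n_alerts_removed == 0))
  expect_true(all(id_tab$pct_reduction[!id_tab$empty] == 0))

  # a spec with no matching alerts is flagged, not fatal
  hr_tab <- scenario_table(list(scenario_spec("simple_hr_high", 110, 120)),
                           alerts, cohort$measurements, actions)
  if (hr_tab$n_alerts_current == 0) expect_true(hr_tab$empty)
})

test_that("rescoring equals re-running the engine at the new threshold", {
  cohort <- generate_cohort(small_config(n_users = 15, seed = 41))
  base_th <- alert_thresholds()
  alerts <- run_engine(cohort$measurements, cohort$users, thresholds = base_th)

  for (new_cut in c(180, 190)) {
    spec <- scenario_spec("simple_sbp_high", 170, new_cut)
    surv <- rescore_alerts(alerts, cohort$measurements, spec)
    surv_ids <- sort(surv$source_measurement_ids[
      surv$alert_type == "simple_sbp_high"])

    re_th <- alert_thresholds(simple_sbp_high = new_cut)
    re <- run_engine(cohort$measurements, cohort$users, thresholds = re_th)
    re_ids <- sort(re$source_measurement_ids[
      re$alert_type == "simple_sbp_high"])
    expect_equal(surv_ids, re_ids)
  }
})
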