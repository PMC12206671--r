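# telealert

Alert-burden modelling and threshold scenario analysis for home
blood-pressure telemonitoring programs.

## What this is for

In care-path-embedded hypertension telemonitoring, patients measure blood
pressure at home during scheduled *measurement weeks* (four slots a day,
two morning and two evening) while sitting on a ladder of monitoring
protocols: four acute titration algorithms with targets stepping from
180/110 down to 150/95 mmHg, and a chronic maintenance algorithm at
140/90 mmHg with monthly measurement weeks. Readings raise **simple**
alerts (one reading at or past a one-off bound, e.g. DBP ≥ 105 mmHg),
**complex** alerts (a series event: ≥ k consecutive off-target readings, or
an on-target week that triggers automatic protocol step-down), and
**overdue**/**inactive** alerts for missed or abandoned schedules. Some
alert types are processed automatically by the platform; the rest are
reviewed by e-nurses, who handle all of one user's manual alerts on one day
as a single *telemonitoring action* — administrative (5 min) or clinical
(telephone or secure message, 10 min).

The package is aimed at telemonitoring teams and health-services
researchers who want to quantify alert burden and e-nurse workload and to
evaluate threshold changes before making them. It provides:

* a seeded **synthetic cohort generator** (`generate_cohort()`) with the
  statistical structure of a one-year, 174-user hypertension program —
  including the heavy-tailed subgroup in which ~15% of users produce most
  of the manual alerts;
* a rule-based **alert engine** (`run_engine()`) with auto/manual routing;
* the **e-nurse workflow model**: weekend-consolidating action clustering
  (`cluster_actions()`), stochastic administrative/clinical classification
  with a severity covariate (`classify_actions()`), and minute costing.
  The proportion-mode workload is
  `round_half_up(n·p·5 + n·(1−p)·10)` minutes for `n` alerts of which a
  proportion `p` is administrative;
* descriptive **summaries and concentration analysis**
  (`summarize_alerts()`, `summarize_actions()`, `concentration()`,
  `lorenz_curve()`);
* counterfactual **threshold scenario analysis** (`scenario_table()`):
  an alert survives a raised threshold iff the recorded value of its source
  measurement still meets it — no re-simulation — and the surviving alerts'
  empirical administrative share feeds the projected time saving.

## Worked example

```r
library(telealert)
cfg <- pipeline_config(seed = 1)          # defaults: 174 users, 1-year window
res <- run_pipeline(cfg, "out")           # writes 7 CSV/JSON artifacts
```

On the default configuration with seed 1 this prints (via the returned
summaries):

```
Users: 174 | measurements: 35093 | alerts: 23765 (68% of measurements)
Auto-processed: 14171 (60%) | manual: 9594 (40%), 55 per user
Actions: 3840 | administrative: 2932 (76%) | clinical: 908 (24%)
Top 15% of users hold 71% of manual alerts, 48% of actions
       alert_type new_threshold n_alerts_current n_alerts_surviving pct_reduction minutes_saved
1 simple_dbp_high           110             3952               1866            53         12851
2 simple_dbp_high           115             3952                719            82         20062
3 simple_dbp_high           120             3952                245            94         23120
4 simple_sbp_high           180             3943               1570            60         14834
5 simple_sbp_high           190             3943                568            86         21513
6 simple_sbp_high           200             3943                151            96         24360
```

Reading the scenario table: raising the diastolic simple-alert threshold
from ≥105 to ≥110 mmHg removes 53% of those alerts while the administrative
share among survivors drops only slightly (the severity covariate at work),
projecting 12,851 saved e-nurse minutes over the simulated year. The
deterministic worked example on the reference breakdown counts:

```r
workload_from_proportions(1023, 0.71)   # 6598 minutes (diastolic baseline)
workload_from_proportions(873, 0.71)    # 5631 minutes (systolic baseline)
```

See `vignettes/alert-burden-modelling.Rmd` for the model's assumptions,
parameter rationale, and what the synthetic cohort does and does not
emulate.

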