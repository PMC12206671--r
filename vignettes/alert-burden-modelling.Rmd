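---
title: "Modelling alert burden in home blood-pressure telemonitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling alert burden in home blood-pressure telemonitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telealert)
```

## The problem

Care-path-embedded telemonitoring programs for hypertension let patients
measure blood pressure (BP) at home on a scheduled cadence and push the
readings to a clinical dashboard, where rule-based algorithms raise alerts.
Most alerts can be handled automatically by the platform; the rest are
reviewed by specialised monitoring nurses ("e-nurses"). The clinical value of
such a program is throttled by its *alert burden*: overly strict thresholds
flood the e-nurses and breed alert fatigue, while overly lax thresholds risk
missing deterioration. `telealert` provides a complete, seeded model of this
pipeline — cohort, alerting, triage workload — so that threshold policies can
be analysed quantitatively, including counterfactual "what if we raised this
threshold" scenarios computed against recorded measurement values.

## The monitoring model

**Protocol ladder.** Users sit on one of five monitoring protocols: four
acute titration algorithms with home-BP targets stepping 180/110, 170/105,
160/100, 150/95 mmHg, and one chronic maintenance algorithm at 140/90 mmHg.
A protocol prescribes *measurement weeks* — 7 consecutive days with four
scheduled slots per day (two morning, two evening) — recurring every 7 days
(levels 4–3), 14 days (levels 2–1) or 28 days (chronic). The two published
anchors of the acute range are 180/110 and 150/95; the intermediate acute
targets are evenly interpolated and, like every ladder parameter, can be
overridden via `protocol_ladder()`.

**Automatic switching.** After each measurement week the week is evaluated
against the protocol target (`evaluate_week()`). The default rule compares
the *mean* of the week's taken readings with the target, both bounds strict:
on target means mean SBP < target and mean DBP < target. An on-target week
steps the user down one level; the chronic level is the floor. Two
alternative rules are available (`"all"`, `"majority"`) because the choice
is genuinely open; the mean rule was chosen as the least noisy single-week
summary. Escalation (stepping back toward acute after an off-target week) is
implemented but off by default: de-escalation is the only automatic movement
the modelled program performs, and re-escalation is plausibly a clinician
decision rather than an algorithmic one.

**Alert types.** The engine (`run_engine()`) emits:

* *simple* alerts — a single reading at or beyond a one-off bound
  (inclusive `>=`/`<=`; defaults SBP >= 170, DBP >= 105, plus low-BP and
  heart-rate bounds that have no published values and exist as overridable
  defaults: SBP <= 90, DBP <= 50, HR >= 110, HR <= 45). One alert per
  violated bound, so a crisis reading can raise two.
* *complex* alerts — series events: a run of at least `k = 4` consecutive
  taken readings at or above the protocol target (one alert per maximal run,
  anchored at the k-th reading — alerts are clinical events, not samples,
  so a 10-reading run is one event), and the on-target week event that
  drives protocol switching and positive feedback.
* *overdue* alerts — one per scheduled-but-missed slot.
* *inactive* alerts — one per maximal window of at least `x = 7` scheduled
  measurement-week days with zero taken readings. The window length is
  symbolic in the modelled program; 7 days (one full silent week) is the
  default.

**Routing.** A total policy maps each alert type to automatic or manual
processing (`default_routing_policy()`): overdue and on-target alerts are
automatic; simple, off-target complex and inactive alerts are manual. Auto
plus manual always equals the total — the suite asserts this conservation
for arbitrary policies.

**Workflow.** All manual alerts of one user on one day form one
*telemonitoring action* (`cluster_actions()`); Saturday and Sunday alerts
consolidate into Monday's action because alerts are reviewed during office
hours only (public holidays are ignored — only the weekend rule is
documented for the modelled program). Actions are administrative (platform/
EHR bookkeeping, 5 minutes) or clinical (telephone or secure message, with
or without a treatment adjustment, 10 minutes). Because the real label is a
human judgement, `classify_actions()` models it stochastically:
administrative with probability 0.77, clinical subtypes at 40/28/28/4%. A
severity covariate (on by default, slope 0.04 per mmHg on the logistic
scale) makes actions whose member alerts exceeded their threshold by more
lean clinical; the shift is centred — by solving for the centring constant —
so the marginal administrative share stays exactly at `p_administrative`.
This covariate is what lets threshold scenarios reproduce the observed
pattern that surviving (higher-valued) alerts need clinical action more
often.

**Rounding convention.** Every reported integer — percentages, minutes,
alerts per user — is computed from the unrounded ratio and rounded half-up
once (`round_half_up()`), never chained. This convention reproduces all ten
checkable reference percentages and both workload baselines; two published
values (an inactivity share printed as 7 where the ratio gives 7.6, and a
subtype share printed as 28 where the ratio gives 27.4) cannot be reproduced
by any single rounding rule and are treated as source rounding
inconsistencies rather than calibration targets.

## Scenario analysis

`scenario_table()` answers: *if a simple-alert threshold were raised, how
many alerts survive and how much e-nurse time is freed?* Following the
program's own method, no re-simulation happens: an alert survives if and
only if the absolute value of its recorded source measurement meets the new
threshold (`rescore_alerts()`). The administrative share among survivors is
recomputed empirically from their action labels (`extrapolate_processing()`;
a carry-forward mode applies the current share unchanged when labels are
absent). Workloads use the proportion-mode formula
`round_half_up(n·p·5 + n·(1−p)·10)` with proportions carried at two
decimals — the variant that reproduces the reference baselines 6598 and
5631 minutes exactly where raw pre-rounded counts give 6600/5630. A
re-simulation of the engine at the new threshold exists in the test suite as
the independent oracle for the rescoring path; the two must agree on small
cohorts.

Identity scenarios (new = current threshold) provably remove nothing and
save nothing; savings and reductions are monotone in the new threshold.
Derived arithmetic on the reference scenario (542 survivors at 67%
administrative from 1023 alerts at 71%) gives 2994 saved minutes; published
per-row savings of this analysis differ by 1–2 minutes from what any
consistent rounding produces, so per-row scenario outputs are covered by
sign and monotonicity properties, not exact targets.

## The synthetic cohort

No real measurement-level data are available, so `generate_cohort()`
produces a cohort with the *statistical structure* of a one-year
hypertension telemonitoring population:

* **Scale.** 174 users over a 365-day window, enrolment staggered uniformly
  so that a truncated-normal activity span (mean 207 days, sd 70, floor 14)
  fits inside the window; 45% start on the chronic algorithm, the rest on an
  acute level drawn uniformly from 1–4.
* **Blood pressure.** Per-user true means are a two-component Gaussian
  mixture: background SBP ~ N(142, 10), DBP ~ N(88, 7), HR ~ N(72, 8), and
  an elevated subgroup of 15% of users shifted +25/+15 mmHg. A single
  Gaussian cannot concentrate more than half of the manual alert burden in
  15% of users; the mixture is the minimal mechanism that can. Within-user
  noise is N(0, 10)/N(0, 6)/N(0, 5), readings rounded to integers with
  diastolic clipped below systolic.
* **Adherence.** Each scheduled slot is taken with a per-user Beta(7.2, 2.8)
  probability (mean 0.72 — the value implied by the reference program's
  ratio of taken measurements to scheduled slots); 10% of users additionally
  stop measuring entirely at a uniform dropout date, which is what creates
  inactive-alert windows.

All defaults live in `cohort_config()` and were fixed once, on the grounds
above, before the calibration suite was run. Calibration is aggregate, not
value-based: across 20 seeds of the default configuration the suite checks
that mean realized measurements fall within ±20% of the reference volume of
30,184, that the top 15% of users carry more than half of the manual alerts
in at least 90% of seeds, that the administrative share sits within its
3-sigma binomial band of 0.77, and that threshold scenarios shift surviving
alerts toward clinical processing (positive mean shift).

**What the generator does not emulate.** No circadian or treatment-response
dynamics, no demographic covariates (none exist in the modelled data
extract), no correlation between adherence and BP level, and no calibration
of absolute alert counts: under these invented distributions the manual
share of all alerts is roughly 40% versus the reference program's 21%, and
manual alerts per user are correspondingly higher. Passing calibration
therefore shows that the pipeline arithmetic and the concentration
mechanism behave correctly at realistic scale — not that the generator
reproduces the source population's alert mix.

## Numerical and degenerate-input choices

* Week evaluation with zero taken readings is *indeterminate*: no switch,
  flagged, and handled by inactivity detection rather than an error.
* Alert and action identifiers are deterministic functions of
  (user, date, type, ordinal), so equal configurations produce byte-identical
  output files; reruns of `run_pipeline()` are diffable.
* Zero denominators yield undefined (`NA`) percentages, never errors.
* Concentration ranking breaks ties by user id; the top group size is
  `ceiling(f * n_users)`.
* Generated vitals are clipped to physiological floors (SBP >= 60,
  DBP >= 30 and below SBP, HR >= 30); the clipping binds essentially never
  under the default distributions.
* All randomness flows from a single integer seed; the classifier uses
  seed + 1 so that cohort draws and labels are independent streams.

## Problem sizes

The test suite runs its property checks on cohorts of 5–20 users and its
calibration on 20 replicates of the full 174-user default cohort (roughly
35,000 measurement slots each); the acceptance script uses the same 20
replicates. These sizes give binomial standard errors comfortably inside
the asserted bands while keeping a full run in a few minutes on one CPU.

## Limitations

The model is a single-program abstraction: thresholds, cadences and the
switching rule are configurable but the *structure* (5-level ladder, 4
slots/day, weekly evaluation) is fixed. Action classification is
exchangeable given the severity covariate — real e-nurse decisions also
depend on history and context the model does not carry. Scenario analysis
deliberately holds the cohort fixed (the recorded-values method); it cannot
capture behavioural feedback such as patients measuring differently under a
new threshold regime.
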