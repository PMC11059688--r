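# emstrigger

Trigger-tool screening and validation for ambulance mission records.

Spontaneous incident reporting misses most patient-safety events in the
Emergency Medical Services (EMS): an ambulance patient has few caregivers, so
an adverse event that nobody notices is never reported. Structured
retrospective record review with a *trigger tool* — a fixed list of clues
("triggers") whose positivity criteria are checked in every record — detects
many times more incidents. `emstrigger` implements an ambulance trigger tool
as a computable pipeline for patient-safety researchers and EMS quality teams:

* **Record model** — a validated schema for prehospital mission records
  (dispatch timeline, RETTS-A triage, chief complaint, vital-sign panels,
  SX-ABCDE assessment steps, drugs, conveyance decision, documentation
  flags), read and written as CSV or JSON with a published JSON Schema.
* **Trigger engine** — every trigger encoded as a rule with per-criterion
  evidence: documentation gaps (A1), response time > 20 min at priority 1
  (A2), time on site > 10 min in life-threatening conditions (A3),
  environment/equipment/resource flags, guideline deviations (B1 with
  subtriggers B1A–B1D), deterioration during transport (B3), interpreter use
  (B4), triage inconsistency (B5), non-conveyance (B6) with 72-hour return
  linkage, alternative transport (B7), destination deviations (B8), and
  medication triggers (L1–L3). Two registry profiles (`rrr900`, `final`).
* **Two-stage review workflow** — NCC MERP severity categories (AB, C–I)
  assigned by a primary and, where routed, a secondary reviewer, mapped to
  WHO incident classes: near miss, no-harm incident, harmful incident.
* **Sampling** — monthly stratification and seeded Mersenne-Twister selection
  of a fixed number of records per month (default 25).
* **Validation statistics** — per-trigger positive predictive values
  (PPV = class count / positives × 100), item-level content validity index
  (I-CVI = share of raters scoring 3–4; ≥ 0.80 highly relevant), observed
  agreement, Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)` and the
  prevalence-adjusted bias-adjusted kappa `PABAK = 2·p_o − 1`.
* **Synthetic cohorts** — a generator that plants trigger conditions at
  configurable prevalence and emits a ground-truth manifest, plus simulated
  reviewers, so the whole pipeline is testable without confidential records.

## Worked example

```r
library(emstrigger)

# a priority-1 mission with a 25-minute response and an undocumented temperature
rec <- new_ems_record(dispatch_priority = 1L, temperature = NA_real_,
                      on_scene_arrival = as.POSIXct("2022-06-15 10:25:00", tz = "UTC"))
scr <- screen_records(rec, att_config(), link_returns(rec))
scr[scr$status == "positive", c("trigger_id", "evidence")]
#> # A tibble: 3 × 2
#>   trigger_id evidence
#>   <chr>      <chr>
#> 1 A2         response time 25 min > 20 min at priority 1
#> 2 B1         subtrigger positive: B1C
#> 3 B1C        vital sign not documented: temperature
```

Three triggers fire: the response-time rule A2, the absent-vitals rule B1C,
and B1 (guideline deviation), which aggregates its subtriggers.

Agreement between two reviewers marking the same 90 records × 22 triggers:

```r
cm <- confusion_matrix(a = 59, b = 69, c = 34, d = 1818)  # both-pos, ... , both-neg
observed_agreement(cm)   # 0.9479798
cohens_kappa(cm)         # 0.5071199  -> "moderate"
pabak(cm)                # 0.8959596  -> "almost_perfect"
```

Kappa is depressed because ~95% of the grid cells are negative (prevalence
effect); PABAK corrects for that, which is why both are reported.

A full synthetic study in one call:

```r
run_pipeline("out", seed = 42)   # generate -> sample -> screen -> classify -> report
```

writes records, the ground-truth manifest, the monthly sample, per-trigger
screening results, incident classifications and the report tables (WHO
classes, NCC MERP categories, trigger performance with PPVs, demographics)
plus a reproducibility manifest. A command-line wrapper with `simulate`,
`sample`, `screen` and `pipeline` subcommands ships in `inst/cli/att.R`.

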