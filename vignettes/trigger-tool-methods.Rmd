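---
title: "Methods: trigger-tool screening, review and validation for ambulance records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trigger-tool screening, review and validation for ambulance records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emstrigger)
```

## The screening model

A trigger tool turns retrospective record review into a two-phase procedure:
a cheap, rule-based screen that marks records carrying *clues* of a possible
patient-safety incident, followed by human review of the flagged records
only. `emstrigger` makes the first phase fully computable and models the
second as an explicit judgement input.

Every trigger rule maps one mission record to one of three statuses:

* `positive` — the trigger's criteria are met; the result carries evidence
  naming each criterion and the observed value;
* `negative` — the criteria are assessable on this record and not met;
* `not_applicable` — the record lies outside the trigger's domain (a
  priority-2 dispatch for the response-time trigger, a conveyed patient for
  the non-conveyance subtriggers, a record with a single vital-sign panel for
  the deterioration trigger).

The three-valued logic matters for performance statistics: a
`not_applicable` is not a negative, and per-trigger positive rates are always
reported against the whole cohort, as review practice does.

Two structural conventions are worth stating explicitly. First, the B1
family ("deviations from treatment guidelines") is an aggregate: B1 is
positive exactly when any of B1A (SX-ABCDE assessment steps), B1B
(condition-specific interventions), B1C (absent vital signs) or B1D (absent
complaint-relevant examination) is positive, and one record showing both B1C
and B1D counts once for B1 and once for each subtrigger. Second, the B6
non-conveyance trigger owns a subtrigger for a same-patient return contact
within 72 hours, resolved by record linkage over a pseudonymous patient key
(see below).

## Tunable parameters

All rule parameters live in a versioned YAML vocabulary
(`inst/extdata/vocabulary.yaml`), because trigger criteria reference
region-specific guidelines and documentation systems. The defaults are:

| Parameter | Default | Why |
|---|---|---|
| response-time limit (A2) | 20 min, strict `>` | the tool's stated criterion for priority-1 (lights-and-sirens) dispatches; exactly 20 min is negative |
| on-scene limit (A3) | 10 min, strict `>` | stated criterion for life-threatening conditions |
| "life-threatening" (A3) | RETTS-A red triage | the tool does not define the term; red acuity is the defensible operationalisation, and the predicate is configurable |
| return window (B6 subtrigger) | 72 h, half-open `(t0, t0 + 72 h]` | measured from the index mission's start; half-openness prevents the index contact counting as its own return |
| documentation criteria (A1) | chief complaint, complete vital-sign panel, assessment outcome, interventions/drugs with dose, conveyance rationale | the five-criterion structure of the revised tool; the exact list is configurable because it lives in the tool's manual rather than its published summary |
| core vitals (B1C) | respiratory rate, saturation, systolic pressure, pulse, temperature; glucose added for loss of consciousness / seizure | the tool's stated vital-sign set and glucose indication |
| examination map (B1D) | chest pain → ECG; abdominal pain → palpation + auscultation; dyspnoea → lung auscultation; head trauma / dizziness / seizure → neurological exam; loss of consciousness → ECG | complaint-specific examinations; complaints outside the map are not applicable |
| deterioration bounds (B3) | saturation < 90, respiratory rate < 8 or > 30, pulse < 40 or > 130, systolic < 90 | red-zone vital bounds; B3 fires on a crossing into a red zone between first and last panel, having started outside it |
| formulary (L1) | six common prehospital drugs with dose ranges and indication lists | enough to operationalise "inappropriate drug treatment"; regional formularies replace it in production |

Durations are computed in whole minutes, rounding down, from time-zone-naive
local timestamps; a trigger that needs an absent timestamp is
`not_applicable`, never positive — absent data is the business of the
documentation trigger A1, not of the time rules.

Four triggers (B1B, B3, B8, L1) encode judgements that human reviewers make
from free text. They are operationalised as declarative rules plus a
per-record manual override column, so a reviewer's reading can force either
outcome without touching the rules. The catch-all trigger A7 is a manual
annotation passthrough and is never auto-positive. The registry ships two
activation profiles: `rrr900` (the 23-entry set used during the large
review, 22 triggers plus the return subtrigger counted under B6) and `final`
(the revised set after the last consensus round). The composition of the
final set is a reconstruction — the published summary names its size but not
its members — so the profile drops the four triggers that never fired and
scored lowest on content validity (A4, B2, L2, L3).

## The two-stage review workflow

Both published versions of the workflow are implemented:

* **original**: the primary reviewer grades an incident AB, C or D on the
  NCC MERP severity index; C and D are routed to a physician, who decides
  whether harm occurred and grades E–I if so.
* **revised**: the primary reviewer decides incident presence and whether
  the patient was at risk of harm. No-risk incidents are graded AB or C by
  the primary reviewer; at-risk incidents carry no primary grade and go to
  the physician (not harmed: AB/C/D; harmed: E–I plus harm type and a
  four-point preventability grade).

Final categories map onto WHO incident classes — AB → near miss, C/D →
no-harm incident, E–I → harmful incident, no incident otherwise — and a
record with several incidents takes the class of its most severe one. The
engine validates, rather than infers, every judgement: categories outside the
workflow's allowed set, missing secondary reviews, harm/category
inconsistencies and missing preventability grades are errors.

## Sampling

The record-selection scheme stratifies included records by calendar month
and draws a fixed number (default 25) per month without replacement from a
Mersenne-Twister stream — R's own generator — with an explicit, mandatory
seed. Record ids are sorted before drawing, so the selection depends only on
the record set and the seed, never on input row order; buckets smaller than
the cap are reviewed in full.

## Validation statistics

For two raters over the identical record × trigger grid, with cells
`a` (both positive), `b`/`c` (single positives) and `d` (both negative),
`n = a+b+c+d`:

* observed agreement `p_o = (a + d)/n`;
* Cohen's kappa `κ = (p_o − p_e)/(1 − p_e)`, `p_e` from the marginal
  products; when `p_e = 1` the statistic is undefined and the function
  returns `NA` with a warning rather than a silent `NaN`;
* `PABAK = 2 p_o − 1`, reported alongside κ because trigger grids are
  dominated by negative cells, which depresses κ through its chance term;
* interpretation bands 0.21–0.40 fair, 0.41–0.60 moderate, 0.61–0.80
  substantial, 0.81–1.00 almost perfect.

Per-trigger PPV for an incident class is the class count over the trigger's
positives × 100; a trigger with zero positives has an explicitly undefined
PPV, never zero. The I-CVI of an item is the share of raters scoring it 3 or
4 on the four-point relevance scale, with 0.80 as the high-relevance
threshold; it is rater-count agnostic.

Published trigger-tool tables mix conventional rounding with truncation
(e.g. an agreement of 0.8959… shown as 0.89). Computation keeps full
precision; presentation offers both `round` (default) and `truncate` modes,
the latter used when matching printed tables. Decimal commas in printed
sources are treated as a locale artifact; all output uses decimal points.

## The synthetic-data generator

Real trigger review runs on confidential journals, so the package carries a
generator whose defaults emulate the study conditions of a 900-record,
three-organisation review: 900 candidate records over twelve months with 1%
planted inclusion violations (leaving 891 included), trigger prevalences
matching the observed frequencies (guideline deviations ≈ 30%,
non-conveyance ≈ 21%, incomplete documentation ≈ 14%, down to the
never-fired triggers at 0), a 15.1% 72-hour return rate among non-conveyed
patients, per-trigger incident-class mixes matching the observed PPVs, and
demographic margins (sex ≈ 52% female; priorities ≈ 41/54/5%; triage colours
red 9% through blue 1%; the observed chief-complaint mix; ages from a
beta(2.2, 1.3) law over 18–96 years, putting the median near 68 with
quartiles near 55 and 82).

Every record starts from a fully complete, guideline-conform template on
which all triggers are negative or not applicable. Planting is independent
per trigger except for structural couplings, which are enforced by
conditional planting so marginal rates still meet their targets: a
response-time violation is planted only on priority-1 dispatches (at rate
p/share), an on-scene violation only on red triage, condition-rule and
examination triggers only on eligible complaints, ED-handover and transport
triggers only on conveyed records, returns only on non-conveyed ones.
Planted returns are materialised as appended same-patient contact records
within the window, typed as non-primary missions so the inclusion filter
keeps them out of the analysis cohort while the linkage sees them. Field
interactions that could make one planted rule mask another (a withheld vital
that a condition rule reads, a pulse removed from a deterioration panel) are
excluded from the candidate sets, so screening recovers the manifest
*exactly*, not just in distribution — that exactness is what the
perfect-recovery tests assert.

Record-level incident classes are derived from the per-trigger draws by the
most-severe rule. Because overlapping triggers draw classes independently,
the record-level class distribution of a default cohort is more
incident-heavy than the published record-level distribution; the generator
calibrates per-trigger mixes, not the record-level marginal, and the
published cohort percentages are reproduced from the published counts, not
from synthesis. What the generator does **not** emulate: free-text
narratives, inter-trigger dependence in real data (e.g. documentation gaps
co-occurring with missing vitals), seasonal case-mix drift, and
organisation-level heterogeneity. Passing the synthetic tests therefore
shows the machinery is correct and self-consistent, not that the rules would
reproduce human reviewers' reading of real journals.

Simulated reviewers perturb the true cell grid with per-rater sensitivity
and specificity; at sensitivity 0.75 and specificity 0.985 over a grid with
roughly 5% true positives, the expected agreement statistics sit near κ 0.5
and PABAK 0.9, the regime observed in paired review sessions.

## Numerical choices and degenerate inputs

* whole-minute floors for all durations; strict inequalities at the stated
  limits (20 min, 10 min), so boundary values are negative;
* half-open return window `(t0, t0 + 72 h]`;
* undefined statistics (κ at `p_e = 1`, PPV at zero positives) are explicit
  sentinels;
* validation never coerces: rows with unknown codes, impossible vitals,
  disordered timestamps or inconsistent conveyance are dropped and reported
  with row and field;
* all randomness (generation, sampling, raters) flows from explicit seeds
  through a restored-state Mersenne-Twister helper, so library calls never
  disturb the caller's RNG.

## Problem sizes in the test suite

The suite checks the printed-table statistics exactly; the perfect-recovery
loop at the review's own scale (900 generated, 891 included); rule-engine
equivalence against a brute-force predicate oracle over a 1,536-point
enumerated record space; planting-rate recovery at n = 4,000 within 3σ
binomial bands; sampling uniformity over 1,500–2,000 seeded draws
(chi-square); and 200-case property sweeps for the agreement coefficients.
These sizes keep the full suite under a couple of minutes while leaving the
statistical checks well-powered.

## Known limitations

* The A1 criteria list, the B1B rule set, the L1 formulary and the `final`
  profile membership are reconstructions of manual content not reproduced in
  the tool's published summary; all are configuration, not code.
* Structured rules cannot read narrative text; the four judgement-dependent
  triggers will under- or over-fire on real data without reviewer overrides.
* Paediatric missions are out of scope by design (the tool's inclusion
  criteria are adult-only), as are HL7/FHIR ingestion and free-text parsing.
* Confidence intervals for κ and multi-rater generalisations (Fleiss,
  S-CVI) are not implemented; the review design they would serve reports
  point estimates only.
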