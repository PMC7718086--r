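---
title: "passmon methods: occupancy-sensor behavior indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{passmon methods: occupancy-sensor behavior indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passmon)
library(data.table)
```

## The measurement model

A smart-thermostat deployment streams, every 5 minutes, a 0/1 flag per
remote motion sensor: did the sensor fire at any point in the interval?
passmon's unit of analysis is the **activation count** — the number of
distinct sensors that fired in one interval for one house. A day is
exactly 288 intervals; timestamps are naive local clock time (time zones
and daylight-saving transitions are out of scope, so conservation
arithmetic is exact).

The behavioral interpretation rests on a spatial argument: moving from
room to room within 5 minutes trips at least two sensors, while stagnant
in-house behavior trips at most the occupied room's sensor, and an empty
(or asleep) house trips none. That yields the rule table implemented by
`classify_interval()`:

* waking window, count ≥ cutoff → `PHYSICAL_ACTIVITY`
* waking window, 1 ≤ count < cutoff → `SEDENTARY`
* waking window, count = 0 → `AWAY` (no daytime movement very likely
  means the occupant is out)
* sleep window, count = 0 → `SLEEP`
* sleep window, count ≥ 1 → `DISTURBED_SLEEP` (any movement within
  sleeping hours is an interruption; consecutive disturbed intervals are
  one interruption)

Labels are mutually exclusive and exhaustive over non-excluded intervals,
and depend only on `(activation_count, clock time, config)` — a property
the acceptance suite verifies exhaustively against a brute-force rule
table over all counts 0–30 at all 288 interval positions.

### The two published cutoffs

The source rules state the physical-activity cutoff in two places with two
values: at least **2** sensors (under the physical-activity definition
itself) and, in a three-way classification sketch, at least **3** sensors
with 1–2 indicating sedentary behavior. Which variant governed the
large-scale analysis cannot be determined from the published account, so
neither is buried: `pa_min_sensors` is a first-class knob defaulting to 2
(the definition given under the indicator's own heading), and
`three_way_mode = TRUE` reproduces the ≥3 variant. Every CLI manifest
records which was used. Raising the cutoff can only shrink the set of
physical-activity intervals — a monotonicity property under test.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `waking_start`, `waking_end` | 08:00, 22:00 | clock | the published waking period; the sleep window is its complement (no adaptive sleep detection is attempted) |
| `pa_min_sensors` | 2 | sensors | see above |
| `outlier_step_threshold` | 100 | steps / 5 min | equivalent to 156 m at a 1.56 m stride; above it an interval is stationary-exercise-like, not ambulation. Strict inequality: exactly 100 is retained |
| `noise_filter_enabled` | on | — | see the noise rule below |
| `away_min_intervals` | 1 | intervals | the published definition sets no minimum away duration, so a single 5-minute zero-activation interval may be AWAY; the knob exposes the choice |

The sleep-window complement rule means an analysis whose occupants sleep
other hours should move the waking window, not expect the classifier to
find sleep adaptively. The parameter-recovery acceptance test does exactly
this: its household sleeps 23:00–07:00 and the classifier is configured
with a 07:00–23:00 waking window.

## Data hygiene

**Missing intervals.** Gaps in a stream are materialized by
`pad_missing_intervals()` as records with a missing activation count and
labeled `EXCLUDED/MISSING` — never imputed, because no imputation rule is
published. Daily indicator components plus excluded time therefore still
partition 24 h.

**Step outliers.** With paired step data, intervals with more than
`outlier_step_threshold` steps are `EXCLUDED/STEP_OUTLIER`. The
threshold's robustness is checked by `threshold_sweep()`, recomputing the
correlation at thresholds 100–400 by 50.

**Noise.** The reference analysis removed one-off spurious activations by
inspection; a pipeline needs an operational rule, and ours is: exactly one
active sensor, both immediate temporal neighbors at zero activation, and
zero steps where step data exist → `EXCLUDED/NOISE`. Three deliberate
details: the rule is evaluated against *original* neighbor counts (so a
`0,1,0,1,0` stream drops both blips and the pass is idempotent and
single-pass); an absent neighbor at a stream edge counts as zero (an
isolated blip at the very start of a recording is still a blip); and a
nonzero step count vetoes exclusion, since steps are evidence of genuine
movement — this is what keeps true nighttime interruptions, which involve
walking, out of the noise bin.

## Indicators and summaries

`compute_daily_indicators()` multiplies label counts by 5 minutes: sleep,
disturbed sleep, sedentary and away in hours, physical activity in
minutes per day (the customary unit for that indicator), excluded time in
hours, and the nightly interruption count. The components sum to exactly
24 h per house-day — the same arithmetic structure as the published
indicator table, whose columns each sum to ≈24 h; that near-identity is
what justifies treating the five states as disjoint (disturbed sleep is
*not* a subset of sleep).

`summarize_indicators()` stratifies by occupancy: INDIVIDUAL (exactly one
occupant) vs HOUSEHOLD (more than one), mutually exclusive, plus ALL. The
published account does not state its averaging scheme, so both are
implemented: pooled house-day means (default) and per-house-first means;
the choice is recorded on the result. The PASS reference constants
(sleep 7.2 h, physical activity 24.1 min/day, sedentary 9.6 h) are baked
in for *reporting deltas only* — they never enter a computation.

## Validation statistics

`spearman_rho()` is written out rather than delegated: average-assigned
ranks in both variables, then the Pearson correlation of the ranks. The
test suite checks it against an independent exhaustive rank-enumeration
oracle for all n ≤ 8 with ties, and against the reference implementation
in `stats::cor.test`. Properties under test: invariance under strictly
monotone transforms of either variable, and hard errors (not `NA`s) when
a variable is entirely tied or fewer than 3 complete pairs remain.

The p-value defaults to the t approximation with n − 2 degrees of freedom
— the standard choice at thousands of pairs, where the published analyses
operate — with a seeded permutation alternative for auditing small
samples; the suite checks the two agree in order of magnitude at n ≥ 30.
Whether the reference correlation was computed before or after noise
removal is unstated, so `validation_report()` returns both variants
(`pooled` and `pooled_unfiltered`), the per-house correlations with their
min–max range, and the threshold sweep.

## The synthetic world

`generate_household()` is a deliberately stated world, not a tuning
surface; its defaults were fixed once, before any acceptance measurement,
and are:

* **Floorplan**: a connected room graph, 5–30 sensors total (the
  deployment range), one traversal distance (default 5 m) between
  adjacent rooms.
* **Schedule**: sleep 22:00–08:00 by default; away and activity bouts
  tile the waking window with sedentary time as filler — so ground-truth
  labels partition the day by construction.
* **Steps**: one room-to-room traversal contributes
  `room_distance / stride_m` expected steps, Poisson-jittered; the
  default stride of 1.56 m/step makes 100 steps ≡ 156 m, matching the
  outlier threshold's stated distance equivalence. Steps are indoor-only:
  away intervals have zero steps.
* **Sleep interruptions**: each sleep interval independently becomes a
  movement event with probability 0.2 — chosen so a 10-hour sleep window
  yields roughly 2 h of disturbed sleep, the magnitude reported for
  thermostat-scale data.
* **Sedentary micro-movement**: the occupied room's sensor fires and a
  Poisson(1) step count is logged — a single-room fidget, below any
  cutoff.
* **Workouts**: with probability 0.005 a sedentary interval is a
  stationary workout (one sensor, Poisson(150) steps), the phenomenon the
  100-step filter exists to remove.
* **Noise**: spurious activations are single-sensor, injected only into
  zero-activation intervals, never consecutively — matching the
  description of noise as one-off events.

Identical seeds reproduce byte-identical CSVs. What a green test on this
world establishes: the pipeline's rules, filters, aggregation arithmetic
and statistics are implemented correctly against a known ground truth.
What it does not establish: that real households behave like the
simulator. Real streams have multi-occupant interleaving, sensor
placement artifacts, schedule drift, and metadata errors the generator
does not emulate; the published field results (a pooled correlation of
0.8 against wearable steps; indicator means from hundreds of homes) were
computed on proprietary data and are structural references only.

## Numerical and design notes

* Timestamps are carried as POSIXct pinned to UTC purely as an arithmetic
  convenience for naive local time; all windows are half-open
  `[start, end)`.
* Bout boundaries in schedules must be 5-minute aligned, so parameter
  recovery is exact rather than ±1 interval; the acceptance criterion
  still allows one interval per state transition.
* `rho = ±1` short-circuits the t statistic to p = 0 rather than dividing
  by zero.
* The permutation p-value uses the add-one estimator
  `(1 + #{|ρ*| ≥ |ρ|}) / (B + 1)` and restores the caller's RNG state.
* Sleep interruptions counted per calendar day: a disturbance spanning
  midnight is attributed to both adjacent days' counts, one run each —
  acceptable at this resolution and stated here rather than hidden.
* Config files are JSON (keys mirroring `classifier_config()`); no YAML
  dependency is carried.

## Known limitations

Single-occupant semantics throughout (the simulator models one agent;
multi-occupant metadata affects stratification only). No
physical-activity intensity grading — the sensor modality cannot separate
moderate from vigorous movement. No real-vendor archive parsing. Sleep
timing is windowed, not detected, so shift-worker households require a
window override.
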