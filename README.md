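# passmon

In-home Physical Activity, Sedentary behavior and Sleep (PASS) indicators
from smart-thermostat occupancy sensors.

## The problem

Smart Wi-Fi thermostats regulate temperature using remote passive-infrared
motion sensors spread through the house (typically 5–30 per home), and they
stream each sensor's activation state in 5-minute intervals. For public
health surveillance this is a zero-effort data source: with no wearable and
no diary, the *activation count* of an interval — the number of distinct
sensors that fired — carries enough signal to quantify when a household
sleeps, sits, moves, or is out of the house.

passmon is a tested pipeline for exactly that analysis, aimed at
epidemiologists and health-surveillance engineers working with
thermostat-style occupancy exports:

1. **Classify** every 5-minute interval into one of five mutually
   exclusive behavior states. With activation count `c` at clock time `t`,
   waking window `[08:00, 22:00)` and physical-activity cutoff `k` (default
   `k = 2`; a three-way variant uses `k = 3`):

   | window          | rule        | label             |
   |-----------------|-------------|-------------------|
   | waking          | `c ≥ k`     | PHYSICAL_ACTIVITY |
   | waking          | `1 ≤ c < k` | SEDENTARY         |
   | waking          | `c = 0`     | AWAY              |
   | sleep (compl.)  | `c = 0`     | SLEEP             |
   | sleep (compl.)  | `c ≥ 1`     | DISTURBED_SLEEP   |

   Two data-hygiene filters run first: intervals with **more than 100
   steps** per 5 minutes (≈156 m; e.g. treadmill use) are excluded as
   outliers, and isolated single-sensor blips with zero steps (moving
   curtains, a bird at a window) are excluded as noise.

2. **Aggregate** the labels into per-house-day indicators — nighttime
   sleep (h), disturbed sleep (h), sedentary time (h), away period (h),
   in-house physical activity (min/day), plus a sleep-interruption count —
   which always partition the 24-hour day, and summarize them by occupancy
   stratum (INDIVIDUAL = one occupant, HOUSEHOLD = more) with deltas
   against the fixed PASS survey references (sleep 7.2 h, PA 24.1 min/day,
   sedentary 9.6 h).

3. **Validate** the sensors against wearable step counts with a
   tie-corrected Spearman rank correlation
   `ρ = cor(rank(c), rank(steps))`, pooled and per house, and a
   sensitivity sweep of the step-outlier threshold over 100–400 steps in
   increments of 50.

Because real thermostat-program exports are proprietary, the package ships
an agent-based household simulator (`generate_household()`,
`simulate_pilot()`) that emits the same CSV dialects together with
ground-truth interval labels, so every claim above is testable end to end.

## Worked example

```r
library(passmon); library(data.table)

# four synthetic households (three single-occupant), one week each
sim <- simulate_pilot(n_houses = 4, n_days = 7, seed = 2024,
                      n_occupants = c(1, 1, 1, 3))
rec <- join_steps(sim$intervals, sim$steps)
setDT(rec)
rec[, activation_count := as.integer(rowSums(.SD)),
    .SDcols = patterns("^sensor_")]

lab   <- classify_intervals(rec, classifier_config())
daily <- compute_daily_indicators(lab)
summarize_indicators(daily, sim$metadata)
```

```
Name of indicator                                  Individual    Household     PASS
-----------------------------------------------------------------------------------
Nighttime sleep, hours                                   7.89         7.90      7.2
Disturbed sleep, hours                                   2.00         1.88      N/A
Physical activity in the house, minutes per day         90.00        90.00     24.1
Sedentary time, hours                                   11.46        10.99      9.6
Away period, hours                                       0.98         1.50      N/A
Sleep interruptions, count per night                    18.76        17.43      N/A

(averaging: house_day; strata n_houses: INDIVIDUAL=3, HOUSEHOLD=1, ALL=4)
```

Reading it: the simulated single-occupant homes sleep 7.89 h per night of
which 2.00 h is disturbed, log 90 min of in-house physical activity, and
sit 11.46 h — each value is (interval count with that label) × 5 min, so
the duration rows of any one column sum to 24 h with the away and excluded
time. The PASS column holds the fixed survey reference values for the
three indicators that have one.

```r
rep <- validation_report(rec, classifier_config())
rep$pooled
#> <validation_result> scope=ALL rho=0.7301 n=8002 p=0 (t) threshold=100
round(rep$rho_range, 3)
#> [1] 0.703 0.743
rep$sweep[, .(threshold, rho = round(rho, 4), n)]
#>    threshold    rho     n
#> 1:       100 0.7244  8053
#> 2:       150 0.7242  8059
#> ...
#> 7:       400 0.7240  8064
```

Activation counts and steps correlate strongly (pooled Spearman ρ = 0.73
over 8002 paired intervals, per-house range 0.70–0.74), and the
correlation is insensitive to where the step-outlier threshold sits in
100–400 — the property that justifies the default 100-step cutoff.

## Command line

```sh
Rscript inst/cli/passmon run-all --seed 7 --out runs/demo
Rscript inst/cli/passmon classify --intervals dyd.csv --steps steps.csv \
    --out runs/c1 --three-way --outlier-threshold 150
```

Subcommands `simulate`, `classify`, `indicators`, `validate`, `run-all`;
each stage writes its CSV/JSON outputs plus a `manifest.json` (config
snapshot, seed, input digests, row and exclusion counts). Reruns with the
same manifest inputs are byte-identical.

## Scope

Single-occupant inference only (occupant disambiguation is an open
problem for this sensor class); no physical-activity intensity grading; no
parsing of real vendor export archives — the CSV dialect here is a
declared emulation. See `vignettes/passmon-methods.Rmd` for the full
methods account.
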