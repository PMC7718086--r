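Package: passmon
Title: In-Home Physical Activity, Sedentary Behavior and Sleep Indicators
    from Smart-Thermostat Occupancy Sensors
Version: 0.1.0
Authors@R:
    person("passmon", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based analysis of ambient occupancy-sensor streams from
    smart-thermostat deployments. Classifies 5-minute multi-sensor activation
    intervals into sleep, disturbed sleep, sedentary behavior, physical
    activity, and away states; aggregates them into per-day in-home
    PASS-style behavior indicators (Physical Activity, Sedentary behavior,
    Sleep) with individual versus household stratification; and validates
    sensor activation counts against wearable step counts via Spearman rank
    correlation with an outlier-threshold sensitivity sweep. Includes an
    agent-based synthetic household simulator with ground-truth interval
    labels, CSV readers and writers for the interval, step and metadata
    dialects, and a command-line pipeline with reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
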