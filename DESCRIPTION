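Package: insom
Title: Annualized Simulation of Non-Visual Physiological Responses to Light
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates ipRGC-influenced (non-visual) physiological responses to
    melanopic light exposure over annual horizons: a coupled sleep-wake
    flip-flop, circadian pacemaker and melatonin model integrated at 20-second
    steps drives predictions of subjective sleepiness (KSS), mean reaction time
    (vPVTRT), plasma melatonin concentration and circadian phase shift.
    Includes melanopic unit conversions, synthesis of annual lighting scenarios
    and hospital-style sleep schedules, seasonal and time-of-day metric
    derivation (cumulative phase shift, melatonin suppression, period
    statistics), a suite of threshold-based non-visual lighting metrics
    (N-VE/CP, nvRD, WELL EML tiers, melanopic-EDI recommendations) with
    correlation comparison, and ring-plot visualizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
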