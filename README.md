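# insom

Annualized simulation of non-visual (ipRGC-influenced) physiological
responses to light, for lighting designers and chronobiology researchers
who want to evaluate a lighting condition by the physiology it predicts
rather than by a static lux threshold.

Light absorbed by intrinsically photosensitive retinal ganglion cells
(ipRGCs) entrains the circadian pacemaker, suppresses melatonin and
acutely modulates alertness. `insom` integrates a coupled physiological
model — a Phillips–Robinson-type sleep–wake flip-flop with homeostatic
pressure *H*, a Kronauer/Jewett-lineage circadian pacemaker (*x*, *y*)
driven by melanopic irradiance, and a two-compartment melatonin model
with instantaneous light inhibition — at 20-s steps over a full year,
after a 7-day entrainment pre-run. From the simulated trajectory it
derives:

* **KSS** — predicted Karolinska Sleepiness Scale, a regression on *H*,
  the circadian drive *C* and a saturating instantaneous light term;
* **vPVTRT** — predicted mean reaction time (ms), a function of *H* and
  *C* alone;
* **melatonin suppression** — per Eq.
  `100 · (AUC_dark − AUC_day) / AUC_dark` against a matched dark
  reference, in morning (08–12) and evening (18–24) windows;
* **circadian phase shift** — nightly change in the clock time of the
  plasma-melatonin peak, cumulated per meteorological season.

It also generates annual exposure scenarios (daylight with dynamic
shades, constant electric light and screens, evening dimming/warming) and
hospital-style sleep schedules (regular and disrupted), computes the
established threshold metrics (N-VE/CP, nvRD, WELL EML tiers, melanopic-EDI
recommendations) on the same series, correlates the two metric families,
and draws seasonal ring plots.

## Worked example

Simulate a two-week unit of the electric-light scenario for a regular
sleeper starting March 1, with a dark reference for suppression:

```r
library(insom)
cfg <- scenario_config("electric")
sch <- build_sleep_schedule("scheduled")
exposure <- compose_scenario(cfg, sch, year_days = 14,
                             start_date = as.Date("2023-03-01"))
traj <- simulate_trajectory(exposure, sch, dark_reference = TRUE)
seasonal_metrics(traj)
#>   season              metric    period  value
#> 1 spring     phase_shift_min    season  -2.15
#> 2 spring mel_suppression_pct   morning  29.54
#> 3 spring mel_suppression_pct   evening  89.13
#> 4 spring                 KSS   morning   2.11
#> 5 spring                 KSS afternoon   2.08
#> 6 spring                 KSS   evening   3.49
#> 7 spring           vPVTRT_ms   morning 207.32
#> 8 spring           vPVTRT_ms afternoon 153.41
#> 9 spring           vPVTRT_ms   evening 278.31
```

Reading this: over the two simulated weeks the subject's melatonin peak
drifted 2.15 minutes earlier in total (a small phase advance); constant
bright evening light suppressed 89% of the evening melatonin AUC relative
to the dark reference; predicted sleepiness stays near "alert" (KSS ≈ 2)
through the day and rises toward "rather alert" (≈ 3.5) in the evening;
and predicted reaction times are fastest in the early afternoon when the
circadian drive to wakefulness is high. `render_ring_plot()` draws any of
these metrics as a seasonal ring (quadrants = seasons, inner band =
morning); `render_dynamics()` shows the underlying *H*, *C*, state,
irradiance, KSS, vPVTRT and melatonin traces.

The full annual study (3 scenarios × 2 sleep types × 3 view depths) runs
with `run_pipeline(system.file("extdata", "demo-config.json", package =
"insom"), "out/")`, writing `metrics.csv`, `legacy.csv`,
`correlations.csv` and a manifest. A thin command-line wrapper is
installed at `inst/cli/insom.R` (`synth`, `simulate`, `metrics`,
`legacy`, `compare`, `plot`, `run`).

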