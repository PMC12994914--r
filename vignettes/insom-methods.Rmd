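---
title: "Modelling non-visual responses to light: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling non-visual responses to light: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(insom)
```

## The problem

Light reaching the intrinsically photosensitive retinal ganglion cells
(ipRGCs) drives physiological responses that have nothing to do with image
formation: it entrains the circadian pacemaker, suppresses the nocturnal
hormone melatonin, and acutely modulates alertness. Architectural lighting
metrics have historically summarized this with static thresholds (a lux
value exceeded for so many hours). `insom` instead simulates the
physiology: given a year of melanopic irradiance at an occupant's eye and
their sleep schedule, it predicts subjective sleepiness (KSS), mean
reaction time (vPVTRT), plasma melatonin concentration and circadian phase
shift over time, and derives seasonal and time-of-day summaries from the
simulated trajectories. A suite of the threshold-based metrics (N-VE/CP,
nvRD, WELL EML tiers, the melanopic-EDI exposure recommendations) is
included so the two families can be computed on identical inputs and
correlated.

## The coupled model

The dynamic core is a coupled system integrated by fixed-step RK4 at 20-s
macro steps:

* **Sleep–wake flip-flop.** Mean voltages of mutually inhibitory
  sleep-active (VLPO, $V_v$) and wake-active (monoaminergic, $V_m$)
  neuronal populations, with sigmoidal firing rates
  $Q_i = Q_{max}/(1+e^{-(V_i-\theta)/\sigma})$. The VLPO is driven by the
  homeostatic pressure $H$ and inhibited by the circadian drive
  $C = (1+x)/2$.
* **Homeostat.** $\dot H = (\mu Q_m - H)/\chi$, with the classic
  two-process asymmetry: $\chi$ is 18.2 h during wake (slow rise) and
  4.2 h during sleep (fast dissipation). The asymmetry matters: with a
  single symmetric time constant, a disrupted sleeper's midday nap exactly
  cancels the restorative deficit of an interrupted night, and the
  robustly observed ordering — more sleep pressure at 06:00 after a
  fragmented night — cannot be produced.
* **Circadian pacemaker.** A higher-order van der Pol oscillator $(x, y)$
  of the Kronauer/Jewett lineage with intrinsic period
  $\tau_c = 24.2$ h, photic drive $B$ through a light-adapting
  photoreceptor state $n$, and a phase-gated nonphotic (behavioural)
  drive so that a repeating sleep schedule is itself a weak zeitgeber.
  The photic drive follows the published unit convention: the activation
  rate $\alpha$ enters $B$ in min$^{-1}$ while $\dot n$ runs in s$^{-1}$.
* **Melatonin.** Two compartments (pineal, plasma): synthesis is gated by
  a rotated circadian coordinate with a curved activation (so plasma has
  an interior nightly peak rather than a plateau clipped by lights-on),
  inhibited instantaneously by melanopic irradiance through a Hill
  function with half-inhibition at 0.10 W m$^{-2}$, released to plasma
  with a 30-min time constant and cleared with a 45-min half-life.
* **Alertness regressions.** KSS is a linear function of $H$ and $C$ plus
  a saturating instantaneous light term (half-saturation 0.01 W m$^{-2}$,
  nearly fully saturated by 0.075 W m$^{-2}$), clamped to $[1, 9]$.
  vPVTRT is a function of $H$ and $C$ alone — deliberately no
  instantaneous light term — so the pair separates the acute alerting
  effect of light (visible in KSS) from circadian/homeostatic state
  (visible in both).

Retinal input is gated to zero during sleep (eyes closed): light shown
during a sleep interval influences neither the pacemaker nor melatonin.
This is implemented inside the derivative, so a trajectory simulated with
arbitrary light during scheduled sleep is bit-identical to one with that
light removed.

### Coefficients

The neuronal and homeostatic constants follow the Phillips–Robinson
sleep–wake model; the pacemaker and photoreceptor constants follow the
Kronauer/Jewett/St Hilaire lineage. The remaining constants — the
melatonin gate geometry, synthesis/clearance rates, the alertness
regression weights, the dose normalization of the photic drive in
melanopic units — are package calibrations, fixed once during development
against the following anchors and not revisited: the instantaneous KSS
light term saturates near 0.075 W m$^{-2}$ while ~1 W m$^{-2}$ is needed
for a 95% evening melatonin-suppression effect; plasma melatonin is
near zero in the early afternoon for a night sleeper and peaks at
150–200 pmol L$^{-1}$ near 03:00; the coupled system free-runs in
darkness at its stated intrinsic period; and a regular 16:8 light–dark
schedule entrains melatonin phase with negligible day-to-day drift.
Every coefficient is an entry of `insom_params()` and can be substituted.

### Numerics

The voltage pair relaxes on a ~10-s timescale, which makes a bare 20-s
RK4 step unstable, so each macro step is integrated as fixed 0.5-s
substeps (`substep_s`); refining the substep further changes state
variables at the $10^{-5}$ level and below, decreasing with the fourth
order of the step. Schedule state is constant within a macro step and
light is interpolated linearly. The forced sleep schedule is imposed as a
$\pm 12$ mV drive on the VLPO population only, which flips the flip-flop
reliably without pushing wake-active firing (and with it the homeostat)
out of its physiological range. In natural-sleep mode the forcing is
removed and the sleep–wake flag follows the wake-active voltage across a
hysteretic threshold (fall asleep crossing $-2$ mV downward, wake
crossing $-1$ mV upward) so the flag cannot chatter.

Integer-second grids are used throughout; schedule boundaries are snapped
to whole seconds before comparison so that a boundary sample is assigned
to the same side of an interval on every simulated day.

## Entrainment and the dark reference

Assessed runs start from a state produced by seven days of entrainment to
the subject's own sleep schedule under the scenario's first-day exposure
(`entrain()`); results are therefore insensitive to the documented
initial condition. Melatonin suppression follows the AUC ratio
$100\,( \mathrm{AUC}_{dark} - \mathrm{AUC}_{day})/\mathrm{AUC}_{dark}$
computed by trapezoid over the morning (08:00–12:00) and evening
(18:00–24:00) windows; the afternoon is not assessed because a normally
entrained subject has almost no circulating melatonin then. The dark
reference shares the entrained initial state and the sleep schedule and
zeroes only the light. For this reference to be meaningful over a full
year, the schedule must hold the dark twin's pacemaker near 24 h — this
is exactly the role of the nonphotic drive, whose strength
($\rho = 0.08$) was chosen as the smallest value that locks the
schedule-entrained dark twin (< 0.1 min/day peak drift) while the
darkness free-run with natural sleep stays at the intrinsic period.
Seasonal suppression is reported as the mean of daily ratios across the
season's days, not the ratio of season-summed AUCs: daily values are what
the ring plots display, and the mean of daily ratios is robust to a few
low-melatonin days dominating a seasonal AUC.

## Phase shift

Daily phase shift is the signed clock-time difference of the plasma
melatonin peak between consecutive nights, wrapped to
$(-12\,\mathrm{h}, +12\,\mathrm{h}]$, with advances negative. Peaks are
located in a 24-h window centred on the subjective night (15:00 to 15:00)
so a peak that straddles midnight is never split by the civil-day
boundary, and refined below the storage grid by a parabolic fit through
the three samples around the argmax. Nights with flat melatonin are
skipped by the peak detector; requesting them from a phase-shift
operation raises an undefined-result error. Seasonal phase shift is the
sum of daily shifts over consecutive night pairs within the season, which
telescopes to the wrapped first-to-last difference whenever no single
daily shift exceeds 12 h.

## Scenario synthesis

The generator emulates the study conditions so the whole pipeline is
testable without any external irradiance data:

* **Daylight**: a raised-cosine interior daylight curve between sunrise
  and sunset, day length $12 \pm 2$ h across the year (longest near the
  June solstice), plus a brief east-facing direct-sun spike about an hour
  after sunrise. Dynamic shades clip the received irradiance wherever the
  implied photopic vertical illuminance would exceed 3000 lx. Amplitude
  attenuates linearly to 15% from the window (`view_depth` 0) to the back
  of the space (`view_depth` 1).
* **Electric**: adds a constant 6500 K electric contribution during all
  waking hours (06:00–24:00) and a 6500 K screen through the evening
  (18:00–24:00).
* **Dimming**: as electric until 18:00; the electric light switches to a
  warm 2800 K preset from 18:00 to 22:00 and is dimmed to half that power
  from 22:00 to 24:00; the screen switches to a blue-depleted 1900 K
  preset from 21:00 to 24:00.

The CCT presets are scalar melanopic irradiances (6500 K electric
0.35 W m$^{-2}$, 2800 K electric 0.10, 6500 K screen 0.12, 1900 K screen
0.02) standing in for full spectral power distributions, which belong to
an upstream multi-spectral raytracing stage that is out of scope here;
they are plain config values. The generator is deterministic: worked
examples and tests are exact.

Two sleep archetypes are built in: `scheduled` (00:00–06:00 nightly) and
`disrupted` (in bed at midnight, onset delayed to 00:24, 5.6 h of sleep
in four 84-min segments separated by three 12-min awakenings, ending
06:36, plus a 15:00–16:20 nap). The 5.6 h figure is read as sleep time
excluding the awakenings; the awakenings sit at the quartile points of
the bout. Alertness outputs are masked for 2 h after waking from any
sleep bout longer than 3 h — interruptions shorter than 30 min do not
split a bout for this purpose, and naps do not trigger the mask.

## What the generator does not emulate

The synthetic scenarios have no weather, no spectral variation, no
geometry and no behavioural noise: passing tests demonstrate that the
physiological machinery and the metric derivations behave correctly under
controlled exposure patterns, not that any real building produces these
values. Conclusions about a specific space require measured or simulated
irradiance series in the exposure CSV format. The model itself inherits
the limitations of its laboratory-derived lineage — no age or chronotype
adjustment, no rod/cone mediation of ipRGC firing, and shift-work
schedules have not been exercised.

## Legacy metrics

The threshold metrics are computed from the same exposure series:
N-VE probability ($0$ below 210 lx D55-equivalent, $100\%$ at 960 lx,
$100 E_{D55}/750 - 28$ between) and its period means (CP); daily nvRD as
a saturating per-sample dose response on a 6-min grid normalized so that
824 lx (D65) sustained 5 h yields exactly 4.2 — the interior dynamics of
the original cumulative model are not published in a reproducible form,
so the accumulator is this package's documented calibration of the
anchor, flagged in the result's `calibration` attribute; WELL EML tiers
in both readings (per-day rule with a 4-consecutive-hour block beginning
by noon, and fraction-of-daytime-timesteps, the latter used for
correlation); and the melanopic-EDI recommendations (daytime $\ge 250$
lx, $\le 10$ lx in the 3 h before bed, $\le 1$ lx during sleep, boundary
values counting as compliant per "a minimum of"). D55-equivalent
illuminance is derived from melanopic irradiance by a fixed configurable
ratio (0.89 of the D65 conversion) since the exact weighting is not
defined by the sources; N-VE unit tests therefore use D55 inputs
directly. Ferguson effect-size labels use half-open boundaries on the
left (0.2, 0.5, 0.8), a choice the quoted open intervals leave undefined.

## Problem sizes

The test suite exercises 3–30-day horizons (a few seconds each at the
default 0.5-s substep); `run_pipeline()` with the bundled demo
configuration performs the full annual study — 18 units of 365 days plus
dark references, roughly 75 s per unit on a single core. The acceptance
script evaluates closed-form quantities and runs in under a second.

## A worked unit

```{r example, eval = FALSE}
cfg <- scenario_config("electric")
sch <- build_sleep_schedule("scheduled")
exposure <- compose_scenario(cfg, sch, year_days = 365)
traj <- simulate_trajectory(exposure, sch, dark_reference = TRUE)
seasonal_metrics(traj)
render_ring_plot(seasonal_metrics(traj), "mel_suppression_pct")
```
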