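---
title: "Heat-exposure methods: UHII regression, Excess Heat Factor, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat-exposure methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urbanheat)
```

## The problem

Heat-health studies need exposure surfaces: who, where, and how strongly a
population was exposed during a heatwave. Station networks are too sparse
to resolve the urban-rural gradient, so gridded temperature fields (from a
mesoscale model or a land-data-assimilation system) are used instead. Two
quantities summarize such fields for epidemiology: the **urban heat island
intensity** (UHII), which measures how strongly temperature increases with
urbanization, and the **Excess Heat Factor** (EHF), which turns a
temperature episode into a severity index with an explicit climatological
reference. This package implements both, plus the station-based statistics
used to judge whether a gridded product is trustworthy in the first place,
and a synthetic generator that provides ground truth for all of them.

## UHII as a regression slope

Classical urban-minus-rural differences depend on an arbitrary choice of
representative sites. The regression formulation avoids that: every land
cell contributes its temperature $T$ and its urban fraction
$f \in \{0, 0.50, 0.90, 0.95\}$ (the canonical fractions of
low-intensity residential, high-intensity residential and
industrial/commercial land), and

$$T = f \cdot \mathrm{UHII} + T_\mathrm{veg}$$

is fit by ordinary least squares per date and diurnal period. Open-water
cells are excluded entirely; the zero-fraction data are vegetation cells
only, so the intercept is the vegetated-land baseline. `fit_uhii()` returns
the slope with its standard error, a two-sided $t$-test p-value, the
Pearson correlation, and a confidence interval; `daily_uhii_series()`
applies it per date.

Choices worth stating:

- **Diurnal partition.** Day is 06:00–18:00 local, night its complement. A
  night spans midnight and is labeled by the evening on which it *begins*;
  that convention is fixed and documented because no external standard
  pins it.
- **Per-date means, not pooled hours.** The daily series fits one model per
  date on the period-mean grid. Pooling all night hours of a date into one
  regression gives near-identical slopes but overstates the effective
  sample size; per-date means are the default.
- **Inference.** The p-value is the standard two-sided $t$ test on the OLS
  slope; suburban (fraction 0.5) cells enter as ordinary points.

## The Excess Heat Factor

For a 3-day event window (here pinned to explicit dates, e.g. July 4–6 for
a July 4–7 heatwave), with $T_3$ the window mean, $T_{30}$ the mean of the
previous 30 days and $T_{95}$ the 95th percentile of a multi-year daily
climatology:

$$\mathrm{EHI}_\mathrm{sig} = T_3 - T_{95}, \qquad
  \mathrm{EHI}_\mathrm{accl} = T_3 - T_{30}, \qquad
  \mathrm{EHF} = \mathrm{EHI}_\mathrm{sig} \times
  \max(1, \mathrm{EHI}_\mathrm{accl})$$

EHF is in °C²; values above 2 °C² are classed high severity, any positive
value as elevated. Three variants use daily maximum, minimum and mean
temperature, probing daytime, nighttime and overall stress.

Numerical and definitional choices:

- **Daily mean.** `Tmean` is the 24-hour arithmetic mean of the hourly
  values. Parts of the heatwave literature use (Tmax + Tmin)/2; with hourly
  input the full mean is better determined, and the daily statistics are
  computed from complete local days only (incomplete days are dropped and
  counted, never padded).
- **Percentile rule.** $T_{95}$ interpolates linearly between order
  statistics ($h = (n-1)p + 1$; for values 1..100 this gives 95.05). The
  rule is recorded in the baseline's metadata because percentile
  conventions differ by tenths of a degree.
- **Windows are strict.** $T_3$ and $T_{30}$ error out if any day of the
  window is missing, naming the absent dates — partial means would
  silently dilute the event.
- **Variant-matched baselines.** Each variant is compared against the
  percentile of *its own* statistic (Tmin against the Tmin climatology,
  etc.). Comparing Tmin or Tmax episodes against a mean-temperature
  baseline shifts EHF by the full diurnal asymmetry; if that reading is
  wanted, pass the Tmean climatology explicitly.
- **One grid.** Episode and climatology must live on the same grid; any
  regridding or cross-dataset bias correction is the caller's
  responsibility, and mixing baselines from different sources changes what
  EHI_sig means (see "What the null calibration shows" below).

## Model-evaluation statistics

Per station: $\mathrm{MB} = \overline{m - o}$,
$\mathrm{GE} = \overline{|m - o|}$,
$\mathrm{RMSE} = \sqrt{\overline{(m-o)^2}}$, after pairing on identical
timestamps. Pairing drops unpaired hours with a count — interpolation
would manufacture observations. Benchmark thresholds are configuration,
not code: the defaults (|MB| ≤ 0.5 °C, GE ≤ 2 °C) follow the commonly used
surface-meteorology benchmarks, and the aggregate row is the unweighted
station mean. Always $\mathrm{GE} \ge |\mathrm{MB}|$ and
$\mathrm{RMSE} \ge |\mathrm{MB}|$; with pure Gaussian noise of sd
$\sigma$, $\mathrm{GE} \to \sigma\sqrt{2/\pi}$ and
$\mathrm{RMSE} \to \sigma$ — both used as closed-form checks in the tests.

## The synthetic test bed

`generate_temperature_cube()` builds hourly fields as

$$T(t, c) = \mu + A\sin\!\big(2\pi(h_t - 9)/24\big)
  + \mathrm{HW}(t, c) + \mathbb{1}_\mathrm{night}(t)\, s\, f_c
  - L_c + \delta_{d(t), c} + \varepsilon_{t,c}$$

with defaults chosen once to emulate a midwestern coastal city in a hot
summer:

| term | default | rationale |
|---|---|---|
| baseline mean $\mu$ | 28.5 °C | hot-summer daily mean; night means land near 25 °C |
| diurnal amplitude $A$ | 6 °C | peak at 15:00, trough at 03:00 local |
| heatwave pulse | +4 °C rural / +2.5 °C urban, days 38–41 | rural response larger than urban, as observed for synoptically driven events |
| nighttime UHII $s$ | 2 °C per unit fraction | mid-range of reported nighttime intensities (≈1.4–2.8 °C) |
| lake cooling $L_c$ | 5 °C at the shore, e-folding 2 cells | strong but shallow lake-breeze penetration |
| synoptic anomaly $\delta$ | sd 2 °C, AR(1) ρ = 0.9 across days, iid across cells | multi-day persistence of warm/cool spells |
| hourly noise $\varepsilon$ | sd 0.3 °C | sub-grid and instrument variability |

The UHI term is a step function on the night window (the phenomenon is
observed at night; a smooth evening ramp is deliberately out of scope), and
the lake term is a static exponential cooling field, not time-resolved
advection. The heatwave pulse applies on calendar days, to urban
(fraction > 0) and vegetation cells at their respective amplitudes.
Climatology years re-run the same process without the heatwave, seeded
`seed + year`, so baseline and episode are independent but reproducible;
stations are cell-snapped samples with independent observation noise.

**Why the synoptic term exists.** Without day-to-day variability the daily
climatology collapses onto the deterministic cycle and the 95th percentile
sits a fixed offset above the mean — the null probability of a 3-day mean
exceeding it would be far below 5% (hourly noise averages down by
$\sqrt{24}$ and $\sqrt{72}$). With persistent synoptic anomalies the 3-day
mean retains most of the daily variance
($\mathrm{sd}(T_3)/\mathrm{sd}(T_1) \approx 0.96$ at ρ = 0.9), so an
episode drawn from the climatology process exceeds its own per-cell 95th
percentile on about 4–5% of cells — the calibration the percentile
definition promises, verified in the acceptance tests at 2000 land cells.

**What passing tests do and do not show.** The generator's noise is
spatially white, so per-night regression correlations are modest
(r ≈ 0.2–0.4), whereas real temperature fields are spatially smooth and
produce r > 0.7; recovery of the slope and its coverage transfer to real
data, the correlation magnitudes do not. Likewise the generator has no
humidity, wind, or time-varying lake breeze, so nothing here validates
those aspects of a real model product.

## Parameter recovery and the estimand

Two facts from the construction anchor the test suite:

- On a **lake-free** (or cooling-free) domain with no heatwave, the
  noise-free nighttime mean grid is exactly linear in urban fraction:
  `fit_uhii()` recovers slope and vegetation intercept to machine
  precision, and with 0.3 °C hourly noise, 100 replicates of a
  1008-land-cell domain recover the slope to within 0.05 °C with ≥ 90%
  CI coverage (and cover zero when the true slope is zero).
- With coastal cooling **on**, the fitted nighttime slope is attenuated
  (≈1.4–1.5 °C against an injected 2 °C on the default domain) because the
  cooling field is spatially correlated with urban fraction — the urban
  core is coastal. This is not an estimator defect: the regression
  estimates the realized urban-fraction gradient, which the lake genuinely
  reduces, mirroring the observed coastal mitigation of UHII. Recovery
  tests therefore switch the confounders off to make the injected slope
  the estimand; the default scenario keeps them on to tell the realistic
  story.

**What the null calibration shows.** Because episode and climatology come
from the same generative process, the UHI term cancels out of EHI_sig, and
with the default (rural-dominant) heatwave amplitudes, rural EHF exceeds
urban EHF. A study that takes T95 from an interpolated station product
while the episode comes from an urban-resolving model re-introduces the
UHI into EHI_sig and shifts urban EHF upward by roughly the nighttime UHI
magnitude times the clamp factor; the pipeline requires one grid precisely
so that such baseline mixing is an explicit, caller-visible decision.

## Degenerate inputs and tie-breaks

- Fits require ≥ 3 land cells and ≥ 2 distinct fractions; all-equal
  fractions raise a degenerate-design error, and a date whose fit fails is
  kept in the daily table with the failure message, never dropped
  silently.
- Stations snap to the nearest cell center; exact half-integer ties go to
  the lower (row, col) index. Coordinates are 0-based with row 0 at the
  north edge, and files carry local clock time only — time-zone conversion
  belongs to ingest, once.
- Cross-sections traverse the discrete Bresenham line (8-connected);
  urban/rural means use fraction ≥ 0.5 and fraction = 0 ∧ vegetation
  respectively, both configurable; an undefined side is reported missing,
  not imputed.
- Gridded files are a self-describing text format with fixed dimension
  order (time, y, x), mandatory units, a land-class code table, and `%.17g`
  numbers, so write→read round-trips are bit-exact and every schema
  violation is a named error.

## Problem sizes

The shipped analyses and tests run on deliberately compact domains: a
36 × 30 grid (1008 land cells) over 45 hourly days with ten 92-day
baseline summers for the main study; 100 two-day replicates for recovery
experiments; and a 50 × 42 domain (2000 land cells) with a 10-summer
baseline for the null EHF calibration. These sizes put the Monte-Carlo
standard errors well inside the tested tolerances while keeping any single
script in the tens of seconds.

## Known limitations

- The lake term is static; no time-varying breeze, no wind or humidity
  fields, and no urban-canopy physics — the generator emulates phenomena,
  not mechanisms.
- Spatially white noise understates regression correlations relative to
  real fields (see above).
- Severity classes are thresholds on EHF only; no population weighting or
  health-outcome modeling is included.
- The categorical surface has exactly four urban-fraction levels; real
  land-cover aggregation produces continuous fractions, which the
  estimators accept but the generator does not produce.
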