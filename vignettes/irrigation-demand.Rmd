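---
title: "Modelling crop irrigation demand with a threshold-triggered soil-water bucket"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crop irrigation demand with a threshold-triggered soil-water bucket}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irribucket)
library(dplyr)
```

## The model

irribucket estimates how much irrigation water field crops on light, sandy
soils will need, day by day and year by year, under observed or scenario
climate. The core is a single-layer soil-water "bucket":

```
swc[d+1] = clamp( swc[d] + P[d] - ET0[d] )          (balance, then clamp)
if swc[d+1] < trigger:  swc[d+1] += 20 mm           (one event, re-clamp)
```

where `swc` is the soil water content of the rooting zone, `P` daily
precipitation, `ET0` daily FAO-56 reference evapotranspiration, and
`clamp` pins the state between the wilting-point storage and the
field-capacity storage. Irrigation fires when the content drops strictly
below a trigger set at the wilting point plus 20% of the available water
capacity (AWC); each event applies a fixed 20 mm/m². At most one event
fires per day — applications are discrete sprinkler passes, not a
continuous top-up.

The order of operations matters and is fixed as: balance update, clamp,
threshold test on the updated value, event addition, re-clamp. The event
therefore lifts the same day's content, which is what observed
application records look like. If an extreme evaporation day leaves the
content below the trigger even after an event, the next opportunity is
the next day.

### Units: the percent bookkeeping scale

Soil survey parameters arrive as volumetric percentages. The model
bookkeeps the state in l/m³ on a 1000-l/m³ percent scale: x% ↔ 10·x
l/m³. The default soil (type 31, a brown podzolic sand common in the
Uelzen region: field capacity 24%, AWC 17%, wilting point 7%, rooting
zone 0–60 cm) becomes 240 / 170 / 70 l/m³, with the trigger at
70 + 0.20·170 = **104 l/m³** (10.4%).

In the default `paper` unit mode, daily depths in mm are added to this
state at face value (1 mm ↔ 1 l/m³), so one 20 mm event raises the
content by exactly 2 percentage points. Physically, 20 mm spread over a
0.6 m rooting zone would raise the volumetric store by 33.3 l/m³; the
`depth_scaled` mode applies that conversion (k = 1000/(10·depth_cm))
for users who want strict dimensional consistency. The two modes give
different absolute irrigation totals; `paper` is the default because it
replicates the bookkeeping convention the regional studies in this
domain actually use, and the threshold/cap constants (104, 79 mm) are
defined on that scale.

```{r}
st <- derive_storages(soil_profile(), irrigation_policy())
st
```

## The irrigation season

Irrigation is only simulated inside a crop-specific window. The window
opens on day 107 for every crop — in an average year of the reference
climate, the climatic water balance (P − ET0) turns persistently
negative around that day — with a start content of 224.9 l/m³, and
closes (exclusive) at the crop's maturation start, taken as harvest
minus three weeks: crops are not irrigated during maturation. Sugar beet
(harvest day 290) is thus simulated over [107, 269).

`determine_window_start()` re-derives start day and start content from
any long climate series: it runs the bucket continuously from field
capacity with no irrigation, averages the simulated content and the
climatic balance by day-of-year, and returns the first day whose
averaged balance is negative and stays negative in the mean over a
30-day confirmation run. The confirmation run is the package's
resolution of an ambiguity: a single early negative day (a warm week in
March) must not open the season. The shipped defaults (107, 224.9) are
the published values for the study region and are used as-is rather than
recomputed, because the original driving climate is not public.

Soil water does **not** carry over between years: every season restarts
at (day 107, 224.9 l/m³). This follows the source convention of one
start state "for all years and scenario runs"; it slightly underestimates
demand after exceptionally dry winters, a known limitation.

## Rotation, cap accounting

The regionally dominant rotation sugar beet → potato → winter rye →
winter barley is anchored so that sugar beet falls on 1991; the crop of
any year is the plan cycled modulo four. Annual totals are event count ×
20 mm. Regulatory accounting compares a **trailing 7-year moving
average** (current year plus six predecessors) of the annual totals with
the permitted 79 mm/m²·yr; a year is flagged only when the average
*strictly* exceeds the cap, because 79 is stated as a permitted maximum.
Years without six predecessors get `NA` — warm-up is never zero-filled,
the caller supplies earlier totals (e.g. start the simulation in 1985 to
report 1991 onwards).

```{r}
wx <- generate_daily_weather(scenario_preset("Tmax", seed = 42,
                                             year_range = c(1985, 2014)))
annual_irrigation_series(wx) |>
  moving_average(7) |>
  cap_exceedance(79) |>
  tail(5)
```

## The synthetic climate generator

The generator stands in for the non-public observation (1951–2010) and
RCP 8.5 scenario series (2011–2070) the study design assumes. It
emulates their published summary statistics, not their day-to-day
weather:

* **Temperature**: seasonal cosine (annual mean 8.7 °C, amplitude 8 °C,
  peak mid-July) + linear trend over the period + Gaussian daily noise
  (sd 2.5 °C).
* **Precipitation**: first-order two-state Markov occurrence chain
  (wet-after-dry 0.30, wet-after-wet 0.60) with gamma wet-day amounts
  (shape 0.8); the gamma scale is calibrated so the expected annual
  total equals the configured mean, 654.4 mm/yr for the reference
  climate. This structure reproduces the strong year-to-year variance
  that drives the irrigation series' noisiness.
* **ET0**: by default the generator draws plausible Penman-Monteith
  drivers (net radiation seasonal cosine, wind ≈ 2 m/s, relative
  humidity ≈ 0.78, vapour pressures from temperature) and computes ET0
  with the FAO-56 reference-grass equation; a `direct` mode (seasonal
  sine, mean 1.6 mm/day, amplitude 1.45) is provided for speed.
  Negative Penman-Monteith results are floored at 0: in this model ET
  only removes water. The configured ET trend is imposed as a linear
  ramp of the annual sum in both modes.

The scenario presets encode the published contrasts over 2011–2070:
Tmin (+0.9 °C, ET −8.7 mm/yr, precipitation +44.7 mm/yr), Tmed (+1.3,
+5.6, +45.0), Tmax (+1.7, +28.4, +14.1), applied as period ramps
(temperature, ET) and a shift of the annual precipitation mean.

What the generator does *not* emulate: spatial fields, multi-day
synoptic persistence beyond the first-order chain, the seasonal shift of
precipitation into winter that some scenarios project, or any
correlation between temperature and rain occurrence. Tests that pass on
synthetic climate therefore validate the *model machinery* (balance,
events, accounting, trend statistics) and the generator's calibrated
means and trends — they do not validate the published region-specific
event counts or tau values, which depend on the real series.

A fully deterministic series (for exact regression tests) is available
via `precip_mode = "climatology"` with all noise standard deviations set
to zero; the Markov-gamma rain process is irreducibly stochastic, so
determinism needs this separate uniform-drizzle mode.

## Trend statistics

Annual series are tested for monotonic trend with the Mann-Kendall test,
reported as Kendall's tau-b with tie correction for tied totals (event
granularity of 20 mm makes ties common). Years are never tied. The
two-sided p-value is exact for tie-free series with n ≤ 10 — the full
null distribution of S is built by the standard inversion-counting
recursion, equivalent to enumerating all permutations — and otherwise
uses the normal approximation with tie-adjusted variance and continuity
correction. A constant series has undefined tau and is reported as `NA`,
never as 0. Least-squares slope and R² come from `stats::lm()`; a
constant response is reported with slope 0 and R² = 0 for stable
downstream tabulation. No seasonal variant, Sen's slope or
autocorrelation correction is offered: the annual series are short and
the upstream method used none.

```{r}
ann <- annual_irrigation_series(wx)
glance(irrigation_trend(ann))
```

## Numerical and design choices

* Strict inequalities throughout: the event fires iff content < trigger;
  a cap year is flagged iff the moving average > 79.
* Day-of-year constants (107, harvest days) apply unchanged in leap
  years; day 366 simply exists and is never inside a window.
* Quantile-year selection (dry/median/wet exemplar years) uses the
  empirical type-7 quantile of annual totals and picks the nearest
  year, earliest on ties.
* The degenerate zero-AWC profile is allowed and collapses the trigger
  onto the wilting point, where it can never fire.
* Window end is exclusive: no event on the maturation start day itself.
* Monotonicity caveat: adding rain can, in edge cases, shift the event
  grid by one 20 mm event; "wetter needs less irrigation" holds within
  one event amount, and the tests assert exactly that.

## Problem sizes used in the shipped tests

The test suite validates the bucket on 10⁵ randomized days, compares 100
random seasons against an independent brute-force day loop, checks tau-b
against exhaustive pair counting for every series of length ≤ 6 over
{0, 1, 2}, runs 500-replicate power (60-year series, imposed trend
0.5 mm/yr per year, noise sd 20 mm — the year-to-year spread typical of
these annual series) and size simulations for the Mann-Kendall test, and
averages 20 seeds × 60 years per scenario preset for the Tmax ≥ Tmed ≥
Tmin ordering of mean annual irrigation. These sizes were chosen to make
sampling error small relative to the asserted margins.
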