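---
title: "Detecting post-drought legacy effects in ecosystem flux and sap-flow series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting post-drought legacy effects in ecosystem flux and sap-flow series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`droughtlegacy` asks a deceptively simple question of a multi-decade daily
record: after a severe drought, did the ecosystem's carbon and water fluxes
return to what the weather would predict, or did they stay suppressed (or
enhanced) beyond it? This vignette is the package's own account of the
method — the model and its assumptions, every consequential parameter, the
synthetic scenarios the tests run on, and the numerical choices made where
the design was genuinely open.

```{r setup, eval = FALSE}
library(droughtlegacy)
```

## The residual model of legacy effects

The core idea is counterfactual prediction. Let $y(t)$ be a daily target
(GPP, ET, tree or stand sap flow, water use efficiency, or a greenness
index) and $\mathbf{x}(t)$ the daily hydro-meteorological state: soil
water content (SWC, volumetric fraction), vapour pressure deficit (VPD,
hPa), incoming shortwave radiation (SW\_IN, W m⁻²), air temperature (TA,
°C), wind speed (WS, m s⁻¹) and precipitation (mm day⁻¹). A random-forest
regression learns $y \approx f(\mathbf{x})$ on all years *except* a
designated post-drought period (by default the two years after the drought
year). Because the training data exclude the post-drought period, the
forest cannot encode legacy behaviour: its post-drought predictions are
the no-legacy counterfactual, and the residual
$r(t) = y_\mathrm{obs}(t) - \hat f(\mathbf{x}(t))$ is the candidate legacy
signal — negative when the ecosystem underperforms the weather, positive
when it overperforms.

A residual is only meaningful relative to how well the model predicts a
year it has never seen. The null envelope is built by leave-one-year-out
cross-validation over the non-post-drought years: each year is withheld in
turn, a forest is trained on the remaining non-post-drought years, and the
withheld year is predicted. Daily residuals are averaged to weekly means
(7-day blocks from 1 January; the 52nd week absorbs the 365th day), and
for each week of year the 5th/25th/75th/95th percentiles across the
held-out years form the uncertainty band. A post-drought week is flagged
when its mean residual falls *strictly* outside the 5th–95th band. With
$n$ held-out years the band edges are order statistics of $n$ values, so
the realized false-flag rate on null data exceeds the nominal 10%
somewhat (around 15–20% for $n = 17$); the package's acceptance tests
measure this empirically over 20 seeded null scenarios, and power is
always judged against that same empirical null, never against the nominal
rate.

Assumptions worth stating explicitly:

* **Stationarity of the flux–driver relation** outside the post-drought
  window. Slow drifts (instrument degradation, greening) must be removed
  beforehand — that is exactly what the processing modules are for.
* **Drivers carry the relevant state.** Soil moisture integrates
  precipitation history, which is the main memory channel; explicit lag
  features and phenology are deliberately excluded to limit collinearity,
  with a month-of-year predictor available as a robustness variant.
* **Weekly aggregation** trades daily noise for sensitivity to sustained
  deviations; a single anomalous day never flags a legacy effect.

### Model parameters

| Parameter | Default | Why |
|---|---|---|
| `n_trees` | 500 | regression-forest convention; out-of-bag (OOB) error is stable well below this |
| `mtry` | ⌈p/3⌉ | the regression default of the conventional R implementation |
| `post_drought_years` | 2 years after the drought | legacy effects are reported up to several years post-drought; a wet first year can mask effects that only surface in the second |
| `band_stat` | weekly | flags are weekly; daily bands available |
| `band_scope` | per week of year | the envelope varies seasonally; a global band is available |
| `engine` | `"randomForest"` | the conventional implementation; `"ranger"` fits the identical Breiman forest ~2.5× faster single-threaded and is used for the package's Monte-Carlo experiments |

Two engine subtleties are contract-relevant. The tree identifier in the
pooled sap-flow model is an unordered categorical predictor:
`randomForest` orders categories by mean response, which makes its
predictions exactly invariant to relabelling; `ranger` (with
`respect.unordered.factors = "partition"`) is invariant in distribution
but not bitwise, because its RNG stream depends on level order. Both
properties are asserted in the test suite at their respective strictness.
Fits are reproducible bit-for-bit under a fixed seed for both engines.

Training-set hygiene is enforced programmatically: every forest fit
asserts that no post-drought year is present in its training mask and
aborts otherwise, so a leak is an error, not a silent bias.

A degenerate, single-valued target is refused with an error rather than
fitted: a forest that can only ever predict one value indicates an
upstream processing fault, and silently returning that constant would let
a broken pipeline "pass". (A constant-prediction reading of this edge case
is equally defensible; the package chooses the loud option.)

## Long-term sap-flow processing

Thermal-dissipation sap-flow probes lose signal amplitude over years as
tree growth detaches the probe from conducting xylem, and probes are
replaced at irregular dates, so a 20-year record mixes decaying gains with
abrupt resets. The pipeline makes the *dynamics* comparable across the
record at the declared cost that absolute values lose physical meaning.
Per sensor:

a. **Aggregate and filter.** Daytime mean per day, requiring at least 70%
   of the day's daytime half-hours (inclusive — the thresholds are "at
   least" rules); calendar years with less than 40% of daily values are
   dropped entirely; days more than 3 SD from their year's mean (mean and
   SD over that year's available days, single pass) are removed. Under
   default simulation noise this removes well under 1% of days — the
   filter targets logger spikes, not variability.
b. **Detrend.** A seasonal-trend decomposition (annual period, periodic
   seasonal, loess trend window spanning 3 years = 1095 days) estimates
   the low-frequency trend, which is subtracted. The decomposition needs a
   complete series, so gaps are linearly interpolated on a working copy
   used *only* for trend estimation; output days that were missing stay
   missing. Records with fewer than 3 years of data are refused. One
   inherent property: a within-year linear ramp is partly absorbed by the
   periodic seasonal component, so a multi-year ramp is attenuated by
   roughly 90% rather than removed exactly.
c. **Normalize variability.** For each calendar year, the SD over all
   available values in a 3-year window of neighbouring years (centred by
   default; truncated to 2 years at the record edges) divides that year's
   values. Whether the window should be centred or trailing is not
   determined by the method itself, so it is a configuration switch
   (`window_align`); centred is the default because it treats pre- and
   post-replacement years symmetrically. A window SD below `1e-8` is an
   error — the signal is effectively constant and division would be
   meaningless.
d. **Tree mean.** Daily mean over the tree's sensors with a value that
   day; the contributing count is recorded.

No step fills gaps, and steps (a)–(c) never create a value on a day that
had none. Variance homogenization is testable: for a sensor with monotone
gain decay, the spread of yearly SDs strictly contracts from stage (b) to
stage (c).

## Flux normalization, WUE and greenness

Eddy-covariance instrument eras are reconciled by z-scoring each era
separately (sample SD; segments need ≥ 30 valid days and nonzero SD, both
checked with named errors) and concatenating — the default single break at
the 2013/2014 year boundary reflects the common changeover convention when
the exact replacement day is unknown. Idempotence and within-segment rank
preservation are tested properties.

Water use efficiency is computed as GPP/ET on the *physical* scale first
and segment-normalized afterwards — a ratio of z-scores would be
meaningless. Near-zero ET days would make the ratio explode; days with ET
below a floor (default: the 1st percentile of positive ET) are set
missing and counted.

Satellite greenness carries a multi-year greening trend that would mask
drought signals; it is removed by OLS on time, returning residuals plus
the overall mean so the level is preserved, with the slope and its
significance reported.

## Direct-impact statistics

For the drought year itself, the package reports SD-scaled anomalies
$(\bar y_{2017} - \overline{\bar y_\mathrm{others}}) / \mathrm{SD}(\bar
y_\mathrm{others})$ and rank fractions (share of all years, focal
included, with a period mean ≤ the focal one — ties count towards the
rank, the conservative direction) for the whole year and for half-years
split at 1 July. Record-extreme runs mark day-of-year stretches where the
focal year is *strictly* the pointwise minimum or maximum across all
years — ties yield no extreme, days with any year missing are skipped —
and only maximal runs longer than one week (≥ 8 days) are reported.
Presentation smoothing (centred moving average) is a separate function
that no statistic consumes.

## The synthetic scenarios

The generator produces records with the statistical structure the
detector assumes, with defaults emulating a Mediterranean evergreen-oak
flux site: a 2003–2021 record, a severe 2017 drought whose July–September
precipitation is 11% of the climatological mean (`deficit = 0.89`), a
record-wet first post-drought year (`surplus = 0.56`), five instrumented
trees with two thermal-dissipation sensors each and one mid-record sensor
replacement.

* **Drivers.** SW\_IN, TA, VPD, WS: annual harmonic + AR(1) anomaly
  (innovation SDs chosen so day-to-day weather variability is comparable
  to the seasonal amplitude scale); precipitation: seasonal wet-day
  occurrence × gamma amounts tuned to ~950 mm yr⁻¹ with dry summers; SWC:
  a bucket balance with storage capacity 250 mm and a demand term
  proportional to VPD, temperature and the current store. The bucket
  integrates precipitation history, which gives SWC the memory the
  detector relies on, and produces the record-minimum soil moisture in
  the drought year's autumn.
* **Fluxes.** $y = A\,g_1(\mathrm{SW})\,g_2(\mathrm{TA})\,
  g_3(\mathrm{SWC})\,g_4(\mathrm{VPD}) + \varepsilon$ with saturating
  light response, unimodal temperature response, soil-moisture limitation
  below a stress threshold and a decreasing VPD factor; noise SDs default
  to 5–9% of signal variance. The true flux–driver map of a real site is
  unknown and learned, not prescribed; any form of comparable
  predictability would do, and the acceptance tests require OOB
  pseudo-R² > 0.7 so that the experiments always exercise a skilful
  forest.
* **Legacy injection.** All fluxes are multiplied by
  $1 - \lambda e^{-(t-\mathrm{onset})/\tau}$ from the onset (default
  1 January of the first post-drought year, $\tau$ = 180 days).
  Suppression is multiplicative because drought impacts on fluxes are
  naturally fractional. Noise is drawn independently of $\lambda$, so
  scenarios sharing a seed are *coupled*: identical before onset. The
  Monte-Carlo experiments exploit this — training years never see the
  suppression, so one forest and one leave-one-out envelope per seed
  serve the whole $\lambda$ grid.
* **Sensors.** value = gain × tree-level truth × (1 + noise), gain
  decaying exponentially (defaults 0.1 and 0.2 yr⁻¹ alternating between a
  tree's two sensors) and resetting at replacement; isolated daily gaps
  (1%), occasional multi-week gap blocks, and rare spikes placed 5 annual
  SDs from the annual mean so the 3-SD filter's target is unambiguous.
  Half-hourly resolution expands each day into a half-sine daytime course
  whose daytime mean equals the daily value.

What the generator does **not** emulate — and therefore what passing
tests cannot certify about real data: correlated driver errors and sensor
drift that co-varies with weather, partitioning artefacts in GPP,
advection and energy-balance problems in ET, phenological carry-over that
is not soil-moisture-mediated, and real calendars (the generator uses
365-day years throughout; week-of-year alignment is exact by
construction, at the cost of ignoring leap days — acceptable because no
statistic here resolves single-day offsets).

## Problem sizes and numerical choices

The package's simulation experiments use 19-year scenarios, forests of
100 trees and the `ranger` engine (the null-calibration and power
experiment alone fits ~380 forests); the package default of 500 trees is
used where a single fit's skill is assessed. Percentiles are type-7
sample quantiles. Band comparisons use strict inequalities, so a residual
exactly on a band edge is not flagged. All randomness flows from
explicit integer seeds: scenario generation from the scenario seed (with
fixed offsets separating the driver, flux and sensor streams so that
changing $\lambda$ never shifts the noise), forest fits from the model
seed.

## Limitations

* The null envelope reflects model uncertainty and interannual
  variability, not measurement bias; a systematic observation error in
  the post-drought period is indistinguishable from a legacy effect.
* With two post-drought years there are at most 104 flagged/unflagged
  weeks; the method detects sustained suppression (months), not
  short-lived dips.
* The empirical false-flag rate of percentile bands from ~17 held-out
  years is above the nominal 10%; interpret isolated flags accordingly
  and look for runs of consecutive flagged weeks of one sign.
* Processed sap flow is dimensionless; only temporal dynamics, never
  absolute magnitudes, are interpretable downstream.
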