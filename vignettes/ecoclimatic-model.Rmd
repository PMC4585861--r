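---
title: "The ecoclimex model: growth indices, stress accumulation and the Ecoclimatic Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ecoclimex model: growth indices, stress accumulation and the Ecoclimatic Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

## The model

`ecoclimex` implements a process-oriented climatic niche model in the
CLIMEX tradition. The premise is that a perennial species experiences, at
every location, a favourable season in which the population can grow and an
unfavourable season in which survival stresses accumulate. Both sides are
evaluated on a weekly time step from monthly climatologies, then combined
into one annual score, the Ecoclimatic Index (EI), scaled 0–100.

For each of 52 model weeks the growth side is

* a **temperature index** `TI_w`, a trapezoid that is 0 at or below the
  limiting low temperature `DV0` and at or above the limiting high
  temperature `DV3`, 1 on the optimal plateau `[DV1, DV2]`, and linear on
  the ramps;
* a **moisture index** `MI_w`, the analogous trapezoid on soil moisture
  (as a fraction of the bucket's water-holding capacity) over
  `[SM0, SM1, SM2, SM3]`;
* the weekly **growth index** `GI_w = TI_w · MI_w`, averaged into the
  annual growth index `GIA = 100 · Σ GI_w / 52`.

The survival side consists of four annual stress accumulators, each a
rate-scaled sum of weekly threshold exceedances clamped to [0, 100]:

* **cold stress**, the maximum of two mechanisms: weekly minimum
  temperature below `TTCS` accumulated at `|THCS|` per week, and weekly
  degree-days below `DTCS` accumulated at `|DHCS|` per week. The two
  mechanisms bound the same limiting process from two sides (night-time
  minima and overall warmth), so they are combined by maximum rather than
  by sum, which would double-count;
* **heat stress**: weekly maximum temperature above `TTHS` at rate `THHS`;
* **dry stress**: soil moisture below `SMDS` at rate `|HDS|`;
* **wet stress**: soil moisture above `SMWS` at rate `HWS`.

These combine multiplicatively,

```
EI = GIA · (1 − CS/100)(1 − HS/100)(1 − DS/100)(1 − WS/100),
```

with one additional hard gate: if the annual degree-day sum above `DV0`
falls short of `PDD`, the growing season is too short for establishment and
EI is set to 0. EI maps onto four suitability classes: below 1 unsuitable,
1–10 marginal, 10–20 suitable (able to carry substantial populations), and
above 20 highly suitable. Class boundaries follow the published interval
convention; because the printed intervals "1–10" and "10–20" overlap at
their ends, the package fixes the boundary policy as `EI < 1`, `[1, 10)`,
`[10, 20]`, `> 20` — "highly" is strictly above 20, so suitable is closed
at 20. Classification always uses the unrounded double-precision EI.

The bundled oil-palm parameter set (`oil_palm_params()`, also shipped as a
plain-text config) encodes a wet-tropical perennial: growth between 19 and
36 °C with the optimum at 24–28 °C, a soil-moisture optimum at 0.6–1.6 of
bucket capacity, cold stress from 15 °C / 20 degree-days down, heat stress
above 36 °C, dry stress below 0.4, wet stress above 2, and a 1500
degree-day annual establishment requirement. Accumulation rates are stored
signed exactly as printed (cold and dry rates negative); the kernels use
magnitudes, so a published table can be transcribed verbatim.

## From monthly climatologies to weekly series

Inputs are monthly climatologies of five variables: average minimum and
maximum temperature, precipitation total, and relative humidity at 09:00
and 15:00. The model year has 365.25 days cut into 52 weeks (51 of 7 days
and one of 8.25), which tiles the year exactly without a stub 53rd week.

Temperatures and humidity are interpolated linearly and periodically
between month midpoints and sampled at week midpoints; linear interpolation
is monotone between knots, overshoot-free and reproducible (a spline would
buy little at monthly resolution and can overshoot). Monthly precipitation
totals are apportioned to weeks proportionally to the day overlap between
week and month, which conserves every cell's annual total to rounding
error — a property the test suite asserts for arbitrary inputs. Weekly mean
temperature is `(t_min + t_max)/2`; weekly humidity is the mean of the
morning and afternoon fields.

## The soil-moisture bucket

Soil moisture is tracked with a single-bucket weekly water balance,

```
sm_w = clamp( sm_{w−1} + (precip_w − pet_w) / soil_capacity, 0, sm_cap ),
```

with potential evapotranspiration modelled as a bulk temperature–humidity
demand `pet_w = k_et · max(0, t_avg_w) · (1 − rh_w/100) · days_w` (mm per
week). The choices that matter:

* **`soil_capacity` = 100 mm**, the conventional single-bucket capacity in
  this model family; configurable per parameter file.
* **`sm_cap` = 2.5.** Soil moisture above 1 is meaningful in this scale
  (the oil-palm optimum extends to 1.6 and wet stress starts at 2), so the
  bucket must be allowed to exceed nominal capacity under sustained
  surplus; the cap at 2.5 keeps the state bounded while leaving room above
  the wet-stress threshold for stress to accumulate.
* **`k_et` ≈ 1.1846 mm · °C⁻¹ · day⁻¹** per unit saturation-deficit
  fraction. This is calibrated once, analytically, so that the reference
  "ideal tropical" cell — 26 °C mean temperature, 80 % relative humidity,
  and 2250 mm rain per year (the middle of the crop's ideal 2000–2500 mm
  band) spread evenly — is in exact water balance:
  `k_et = 2250 / (365.25 · 26 · 0.2)`. Under that calibration the ideal
  cell's soil moisture holds at its spin-up value `SM1 = 0.6`, inside the
  optimal band, and the cell scores EI = 100. `k_et` is exposed in the
  parameter file for recalibration.
* **PET uses each week's actual day count** (7 or 8.25 days), consistent
  with the precipitation apportionment; a fixed 7-day PET week would make
  every constant climate drift systematically in the long week.

The annual cycle is iterated from `sm = SM1` until the series is periodic
(maximum weekly change between successive cycles below 1e-6) or 100 cycles
are spent; non-convergence is flagged per cell but not fatal. Whenever the
bucket clamps at either bound during the year the converged orbit is unique,
so the spin-up forgets its initial value; the tests check invariance across
starts at 0, `SM1` and the cap. The one situation without a unique orbit is
a cell whose supply exactly balances demand every week and never clamps —
then the orbit is the start value itself, which is why the spin-up starts
at the lower edge of the optimal band rather than at an arbitrary point.

## Numerical choices and degenerate inputs

All computation is in double precision with no rounding before
classification. Stress accumulation is linear in exceedance and
week-additive; each mechanism is clamped at 100 before combining. The
degree-day gate is hard (EI exactly 0 below `PDD`) rather than tapered,
matching its role as a range limiter. Zero-length masks, cells with any
missing variable, and out-of-range humidity are rejected or masked at
container construction, so the kernels only ever see valid input.
Vectorized accumulators are verified against an independent literal-loop
reference on 1000 random weekly series to 1e-12 relative — agreement at the
last bit is not attainable because R's `rowSums` accumulates in extended
precision while a scalar loop does not.

## The synthetic generator and what passing tests show

No climate rasters ship with the package; every test input is generated.
`synthetic_spec()` / `make_climatology()` produce an idealised
tropical field: temperature declining linearly with absolute latitude,
a sinusoidal seasonal cycle that flips phase across the equator, a
von-Mises-shaped monsoon rainfall profile normalised to a prescribed annual
total, constant humidity baselines, and optional seeded Gaussian noise. The
defaults emulate a wet equatorial region: equatorial means of 31/22 °C
(maximum/minimum), 2250 mm yr⁻¹, morning/afternoon humidity 90/70 %, and a
monsoon concentration of 0.3, i.e. a wettest/driest month ratio near 1.8,
typical of the weakly seasonal equatorial tropics the oil-palm preset
targets. Scenario perturbations (`apply_scenario_delta()`) shift
temperatures, scale precipitation and shift humidity — magnitudes of
interest are the 1.5–2 °C warming projected for mid-century and
precipitation changes of a few tens of percent.

`make_gradient_testbed()` is an engineered fixture: a 1°-resolution strip
from the equator to 35.5° S whose suitability declines monotonically
poleward under the oil-palm preset. Its design isolates the thermal
response: rainfall in the humid columns tracks the local evapotranspiration
demand so soil moisture stays near the optimum, the seasonal amplitude
peaks mid-strip (so cold stress builds gradually with latitude), and the
poleward end is cold year-round (zero degree-days). One arid column gets
200 mm yr⁻¹ and is dry-stress limited instead. The testbed yields all four
classes in order — highly suitable within ~5° of the equator, then
suitable, marginal, and unsuitable from ~8° — and its contract is asserted
in the tests.

What passing tests do **not** show: synthetic fields are smooth, have no
orography, coastlines, interannual variability or observational error, and
the generator's monsoon is a single-harmonic idealisation. Agreement with
the real gridded-climatology analysis is therefore qualitative (class
patterns and scenario directions), not cell-for-cell; the upstream
commercial implementation's exact interpolation and hydrology are
unpublished, so bit-level agreement with it is not a design goal.

## Problem sizes

The default testbeds are deliberately small: the standard synthetic grid is
36 × 36 cells at 0.5° and the gradient strip 36 × 4 at 1°, which keep a
full multi-scenario run in seconds while exercising every code path;
resolution is a spec field, and 10-arcmin grids run through the same code.
Pipeline-level fuzzing uses 10,000 random weekly series.

## Limitations

* Interaction stresses (hot–dry, cold–wet, etc.) are not implemented; the
  oil-palm parameterisation does not assign them values.
* Irradiance, diapause/vernalisation, biotic interactions, irrigation and
  other management inputs are out of scope.
* The hydrology is a one-layer bucket: no runoff routing, soil texture
  classes or capillary rise.
* Automated parameter fitting is not provided; parameter sets are inputs.
* Gridded I/O uses plain-text formats (per-variable CSV and ESRI ASCII
  grid) plus CSV/GeoJSON for points; these are GIS-interoperable and keep
  the package dependency-light.
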