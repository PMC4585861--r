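# ecoclimex

Mechanistic climate-suitability modelling for perennial tropical crops, in
the CLIMEX tradition, with a complete, tested oil palm (*Elaeis
guineensis*) parameterisation.

Correlative niche models ask where a species' climate envelope occurs;
process-oriented models like this one ask where the climate lets a
population grow faster than it is knocked back. `ecoclimex` answers that
question on gridded or station monthly climatologies and compares the
answer across climate-change scenarios — which is how questions like *"will
the core palm-oil producing regions still be climatically suitable at the
end of the century?"* get quantitative answers.

## The model

For each grid cell, monthly climatologies of five variables (minimum and
maximum temperature, precipitation, 09:00 and 15:00 relative humidity) are
interpolated to 52 weeks and passed through:

* a single-bucket weekly soil-moisture balance
  `sm_w = clamp(sm_{w-1} + (P_w − PET_w)/C, 0, 2.5)` with bulk
  evapotranspiration demand `PET_w = k_et · max(0, T̄_w) · (1 − RH_w/100) ·
  days_w`, iterated to a periodic steady state;
* trapezoidal weekly growth indices — temperature `TI_w` on
  `DV0 ≤ DV1 ≤ DV2 ≤ DV3`, moisture `MI_w` on `SM0 ≤ SM1 ≤ SM2 ≤ SM3` —
  combined as `GI_w = TI_w · MI_w` and averaged into the annual growth
  index `GIA = 100 · Σ GI_w / 52`;
* four annual stress accumulators (cold by two mechanisms — night minima
  below `TTCS` and weekly degree-days below `DTCS`, combined by maximum —
  heat above `TTHS`, dry below `SMDS`, wet above `SMWS`), each a
  rate-scaled sum of weekly exceedances clamped to [0, 100];
* the annual **Ecoclimatic Index**

  ```
  EI = GIA · (1−CS/100)(1−HS/100)(1−DS/100)(1−WS/100),   EI := 0 if annual degree-days < PDD
  ```

  classified as unsuitable (EI < 1), marginal (1–10), suitable (10–20) or
  highly suitable (> 20).

On top of the per-cell model the package does suitability classification,
spherical per-class area accounting (km²), scenario perturbation and
comparison (stress-change maps, class-transition matrices), occurrence
overlay validation, and ships a seeded synthetic-climatology generator so
the whole pipeline is testable offline. See the vignette
(`vignettes/ecoclimatic-model.Rmd`) for the full model description and the
reasoning behind the numerical choices.

## Worked example

```r
library(ecoclimex)
p <- oil_palm_params()          # the published oil-palm parameter set

# a reference wet-tropics cell: 26 degC mean, RH 80%, 2250 mm/yr
run_cell(ideal_tropical_cell(), p)[, 1:8]
#>   GIA CS HS DS WS annual_dd  EI           class
#> 1 100  0  0  0  0   2556.75 100 highly_suitable
```

An ideal tropical cell accumulates no stress, clears the 1500 degree-day
establishment gate with 2557 degree-days, and scores the maximum EI of 100.

```r
# a synthetic wet-equatorial grid and two warming scenarios
clim  <- make_climatology(synthetic_spec())
base  <- run_grid(clim, p)
warm2 <- run_grid(apply_scenario_delta(clim, dT = 2), p)
warm4 <- run_grid(apply_scenario_delta(clim, dT = 4, P_scale = 0.9), p)

rbind(area_table(base,  "current"),
      area_table(warm2, "2070_plus2C"),
      area_table(warm4, "2100_plus4C_dry"))
#>          scenario unsuitable marginal suitable highly_suitable   total
#> 1         current          0        0        0         3989594 3989594
#> 2     2070_plus2C          0        0        0         3989594 3989594
#> 3 2100_plus4C_dry    1779020   443739   553679         1213157 3989594
```

The baseline tropics are uniformly highly suitable (mean EI 41); +2 °C
erodes EI but not yet the classes; +4 °C with 10 % less rain collapses
most of the region to lower classes — the area table's row total is
invariant, so area only moves *between* classes. Occurrence points sampled
from highly suitable cells validate 23/23 as highly suitable via
`overlay_occurrences()`.

End-to-end runs with raster/CSV/log outputs are driven by a YAML config:

```r
run_scenarios("run.yaml")   # or: Rscript inst/cli/ecoclimex.R run --config run.yaml
```

writing per scenario an EI raster (`ei_<label>.asc`), a class raster, an
area CSV, a combined scenarios-by-classes table (`areas.csv`) and a JSON
run log; `compare_runs()` adds stress-change rasters and the
class-transition matrix.

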