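# monomict

One-dimensional simulation of thermal stratification, winter turnover, and
bottom-water hypoxia in deep monomictic lakes, with the cross-year analyses
used to attribute turnover timing to climatic drivers and to link hypoxia
to phosphorus.

## Who this is for

Limnologists and aquatic-ecosystem modellers studying lakes that mix
top-to-bottom once per year (in winter) and stratify the rest of the time —
the regime of large temperate lakes such as Lake Biwa, Lake Zurich, or Lake
Washington.  In these systems the winter turnover is the annual oxygen
delivery to the deep water; its timing is climate-sensitive, and late or
failed turnovers deepen hypolimnetic oxygen deficits and promote release of
legacy phosphorus from the sediment.  `monomict` provides a desk-scale,
fully testable pipeline for studying that chain of mechanisms without any
external data: a synthetic forcing generator defines the study conditions,
a coupled physical–biogeochemical column model produces the lake's
response, and analysis functions reproduce the standard downstream
statistics.

## The model

Every state variable `C` (temperature, phytoplankton, zooplankton, DIN,
DIP, DO, POC) obeys a vertical advection–diffusion–reaction balance on a
layered column (default 37 × 2.5 m):

    ∂C/∂t = ∂/∂z ( K(z) ∂C/∂z ) − ∂(w_s C)/∂z + q_C + R_C

* `K(z)` — wind-driven eddy diffusivity: scales with the friction velocity
  of the over-lake wind (station wind × 1.2), decays over a mixing length,
  and is damped by `(1 + N²/N₀²)^−p` where the column is stably stratified.
  Convective adjustment homogenizes any statically unstable layers
  (volume-weighted, tracers together with heat), which is what produces
  winter turnover as the surface cools.
* Surface heat budget: absorbed shortwave, Berliand net longwave with
  cloud correction, bulk sensible and latent fluxes.
* `q_C` — NPZD-style kinetics at Redfield stoichiometry: Monod
  nutrient/light limitation under Liebig's minimum, Ivlev grazing, linear
  mortality, first-order decomposition, constant-piston-velocity
  reaeration, and a sediment pool whose decay consumes bottom oxygen and
  releases nutrients — phosphorus preferentially under low DO
  (`1 + a·K/(K + DO)`).
* `R_C` — river sources at the surface layer with matching outflow; daily
  flows follow smoothed precipitation and annual nutrient masses equal the
  prescribed loading exactly.

Turnover timing is detected as the first day (December–April window) on
which surface–bottom differences in temperature and DO are simultaneously
below 0.5 °C and 0.1 mg/L, reported as days past January 1.  Cross-year
analyses: random-forest variable importance (%IncMSE and node purity) of
cold-season vs annual climatic predictors for turnover timing, and OLS
regressions (with a pre/post-1980 split) between annual minimum bottom DO,
DIP, and timing.

Heat, carbon, nitrogen, phosphorus, and oxygen ledgers are accumulated by
the core and close to round-off; the test suite checks every kernel against
independent brute-force oracles.  See the methods vignette
(`vignettes/monomict-methods.Rmd`) for the full model description,
parameter rationale, and limitations.

## Worked example

```r
library(monomict)

# 6 years of synthetic forcing and loading for a Biwa-like basin
cfg   <- scenario_config(n_years = 6, start_year = 2000, seed = 7)
meteo <- generate_meteo(cfg)
river <- generate_river_inputs(meteo, generate_loading(cfg))

sim <- run_lake(meteo, river, grid = column_grid(), dt = 600)
sim
#> <lake_sim> 2000-01-01 to 2005-12-31  (2192 archived days, 37 layers, 92.5 m)
#>   surface T   8.3.. 26.8 degC   bottom T   8.3..  9.5 degC
#>   bottom DO  7.30..11.69 mg/L   config hash 424db3b210197e74

detect_turnover(surface_bottom(sim))
#>   year timing failed delta_t    delta_do
#> 1 2001     25  FALSE       0 0.004063261
#> 2 2002     -1  FALSE       0 0.006361402
#> 3 2003    -15  FALSE       0 0.006864545
#> 4 2004     30  FALSE       0 0.007206557
#> 5 2005      2  FALSE       0 0.010047494

annual_hypoxia_index(sim)[3:6, ]
#>   year   min_do day
#> 3 2002 8.878482 349
#> 4 2003 8.494603 365
#> 5 2004 7.469195 366
#> 6 2005 7.299763 363
```

The lake stratifies each summer (surface near 27 °C over bottom water near
8 °C), and mixes each winter between mid-December and late January in this
scenario (`timing` is days past January 1 of the labelled year; negative
values are December detections).  The annual minimum of bottom DO is
reached in December, at the end of the stratified season just before
turnover restores it, and drifts downward from year to year as sediment
oxygen demand builds up under the eutrophic nutrient loading.
`delta_t`/`delta_do` are the surface–bottom differences on the detection
day, both below the 0.5 °C / 0.1 mg/L thresholds.

On a longer run the same objects feed the cross-year analyses — a
predictor table of cold-season climate aggregates, the random-forest
importance of those drivers for turnover timing, and the hypoxia
regressions (`scripts/acceptance.R` runs all of them end to end):

```r
tv  <- detect_turnover(surface_bottom(sim))
tab <- aggregate_predictors(sim, meteo, tv, mode = "cold_season")
fi  <- forest_importance(tab, n_trees = 500, seed = 1)  # needs >= 8 years
```

A thin command-line surface wraps the same functions:

```sh
Rscript inst/cli/monomict.R synth-forcing --years 5 --seed 42 -o forcing.csv
Rscript inst/cli/monomict.R simulate --years 3 --seed 1 -o out/
Rscript inst/cli/monomict.R detect-turnover -i monitoring.csv -o turnover.csv
```

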