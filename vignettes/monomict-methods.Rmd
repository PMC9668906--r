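---
title: "Modelling winter turnover and hypoxia in a deep monomictic lake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling winter turnover and hypoxia in a deep monomictic lake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Deep monomictic lakes stratify for most of the year and mix from top to
bottom once, in winter.  That single mixing event -- the turnover -- is the
main annual delivery of oxygen to the deep water.  When turnover comes late
or fails, bottom-water dissolved oxygen (DO) keeps falling through the
extended stratified season, and low oxygen at the sediment surface
accelerates the release of legacy phosphorus stored during past
eutrophication.  The timing of turnover is therefore a climate-sensitive
control on both hypoxia and nutrient cycling.

`monomict` puts this chain of mechanisms into a single testable pipeline:

1. a **synthetic forcing generator** producing multi-decadal daily
   meteorology and an annual nutrient-loading history with the statistical
   structure of a temperate monomictic basin;
2. a **one-dimensional physical submodel** of the water column
   (surface heat budget, wind-driven vertical diffusion, convective
   adjustment);
3. a **pelagic ecosystem submodel** with six state variables
   (phytoplankton, zooplankton, DIN, DIP, DO, POC), particle sinking, and
   a sediment pool;
4. **turnover detection and validation metrics** on the daily
   surface/bottom series;
5. **cross-year statistics**: random-forest variable importance of
   turnover drivers and linear regressions linking annual minimum bottom
   DO, DIP, and turnover timing.

## The one-dimensional reduction

The full problem is three-dimensional, but stratification and turnover are
vertical phenomena: the quantities that define them (surface-bottom
temperature and DO differences) live on a single column.  `monomict`
therefore solves, for every state variable $C$,

$$\frac{\partial C}{\partial t}
  = \frac{\partial}{\partial z}\!\left(K(z)\,\frac{\partial C}{\partial z}\right)
  - \frac{\partial (w_s C)}{\partial z} + q_C + R_C,$$

on a uniform grid (default 37 layers of 2.5 m, a 92.5 m column), where
$K(z)$ is a wind- and stratification-dependent eddy diffusivity, $w_s$ a
sinking speed (phytoplankton and POC only), $q_C$ the biochemical source
term and $R_C$ the river input.  The horizontal circulation of the real
lake is not solved; its vertical mixing effect is parameterized by two
operators:

* **wind-driven diffusion** -- $K$ at each layer interface scales with the
  friction velocity of the over-lake wind (station wind times a
  land-to-lake factor of 1.2), decays with depth over a mixing length
  `l_mix` (default 22 m), and is damped where the column is stably
  stratified by $(1 + N^2/N_0^2)^{-p}$ with $N_0^2 = 10^{-6}\,\mathrm{s^{-2}}$
  and $p = 1.7$.  A background diffusivity of $2\times10^{-6}$ m²/s acts
  everywhere.
* **convective adjustment** -- wherever density decreases with depth, the
  offending contiguous layers are homogenized (volume-weighted, tracers
  together with heat), re-checking upward after every merge.  This is the
  1-D surrogate for penetrative cooling-driven overturn, and it is the
  mechanism that produces the winter turnover: as the surface cools below
  the deep-water temperature, convection reaches progressively deeper until
  the whole column mixes.

Heat diffusion is implicit (backward Euler, tridiagonal solve), so it is
unconditionally stable; sinking is explicit first-order upwind under a CFL
guard ($w_s \Delta t \le \Delta z$, checked by `stability_check()`).

The surface heat budget is the standard four-component bulk formulation:
absorbed shortwave (albedo 0.07; 45 % absorbed in the top layer, the rest
attenuated downward with extinction 0.3 m⁻¹), Berliand-type net longwave
with a cloud correction, and bulk sensible and latent fluxes linear in the
over-lake wind.  Humidity is not part of the forcing; a constant relative
humidity (default 0.70) enters the vapour-pressure terms.  A fixed-point
test verifies that the equilibrium surface temperature under constant
forcing equals the root of the flux function.

### Why these mixing constants

The paper trail for the original 3-D model's coefficients is unpublished,
so the mixing parameterization is this package's own, set by requiring the
*emergent regime* to be that of a large temperate monomictic lake:

* hypolimnetic diffusivities of order $10^{-6}$–$10^{-5}$ m²/s under summer
  stratification (bottom water warms by well under 1 °C per stratified
  season);
* at least 60 contiguous summer days with a surface-bottom temperature
  difference above 2 °C;
* winter turnover in most years, at dates from late December to early
  March, with occasional failed winters in warm, calm years -- matching the
  observed behaviour of such lakes (turnover typically late January to
  mid-March, with rare failures).

These constants were fixed from this climatological reasoning and are all
exposed in `physics_params()`.

## The ecosystem submodel

Six pelagic pools are tracked per layer: phytoplankton (PHY) and
zooplankton (ZOO) in mgC/m³, POC in mgC/m³, DIN in µgN/L, DIP in µgP/L and
DO in mg/L.  Process kinetics are deliberately standard:

* **growth**: $\mu_{\max} f_T f_I \min(f_N, f_P)$ -- Michaelis-Menten
  nutrient limitation under Liebig's minimum, a saturating light response
  $I/(K_I + I)$ on the penetrating shortwave, and a Q10 temperature factor
  ($Q_{10} = 2$, reference 20 °C);
* **grazing**: Ivlev form $g_{\max} f_T (1 - e^{-\lambda \mathrm{PHY}})$,
  with assimilation efficiency 0.7 and the egested remainder routed to POC;
* **mortality** linear; **decomposition** of POC first-order
  (bacteria are implicit);
* **stoichiometry** fixed at Redfield (C:N:P = 106:16:1 molar;
  O₂:C = 32/12 by mass), which makes elemental closure a structural
  property: every flux appears with opposite signs in exactly two budgets
  or at a named boundary (atmosphere, sediment, river).  Closed-column
  conservation of C, N and P to 10⁻⁸ relative over 10⁴ steps is a standing
  test.
* **reaeration**: a constant piston velocity (default 1 m/day) relaxing
  surface DO toward Benson-Krause saturation; supersaturation above 1.2 ×
  saturation is vented (bubble escape), and the vented mass is ledgered.
* **sediment**: sinking PHY/POC accumulate in areal C, N, P pools; the
  carbon pool decays at a temperature-dependent first-order rate consuming
  bottom-layer oxygen (aerobic decay -- the rate stalls when bottom DO is
  exhausted), while phosphorus is released from its own pool with a low-DO
  enhancement factor $1 + a\,K/(K + \mathrm{DO})$ (default $a = 2$,
  $K = 2$ mg/L) that does not require oxygen: this is the redox-controlled
  legacy-phosphorus pathway.

Positivity is enforced by a capped-sink scheme rather than clipping: within
each step, all sinks drawing on a pool are scaled down together so the pool
cannot go negative, and because each process is scaled identically in every
budget it touches, conservation remains exact.  An open question in the
source literature is whether zooplankton excrete directly to the dissolved
pools or via detritus; both are implemented (`excrete_direct`), with direct
excretion the default since it is the simpler closure.

## Operator splitting and archiving

Each time step (default 600 s) applies, in order: physics (surface fluxes,
heat diffusion, convective adjustment, river exchange at the surface layer
with matching outflow) -> tracer diffusion with the same $K$ as heat ->
sinking -> biochemical tendencies (forward Euler with capped sinks) ->
reaeration and sediment exchange.  The archive stores daily means, which is
what the turnover detector consumes.  Whole-run heat, C, N, P and O₂
ledgers (including boundary fluxes and venting) are accumulated in the core
and closed by `budget_residuals()`; residuals are at round-off in every
configuration tested.

## The synthetic forcing generator

The generator is the package's definition of the study conditions, not a
fixture: every variable is a climatological seasonal cycle plus AR(1) daily
anomalies, with air temperature carrying an optional centred linear trend.
Defaults emulate a temperate basin: annual mean air temperature 14 °C
(seasonal half-amplitude 11.5 °C, minimum in late January), annual
precipitation 1700 mm (summer-weighted), mean station wind 3 m/s (winter
maximum), cloud cover 0.65, and shortwave from a clear-sky seasonal curve
attenuated by $(1 - 0.65\,\mathrm{CC})$.  The AR(1) coefficients (0.90 for
air temperature, 0.85 for wind) are set high enough that seasonal means
vary realistically between years -- daily-noise-only anomalies would make
every cold season statistically identical, which would leave the
cross-year driver analysis with nothing to explain.  A seed fully
determines the output.

The nutrient-loading history (`biwa-history` preset) is a unimodal
eutrophication-oligotrophication trajectory: a rise to a 2 200 t/year TP
peak in 1975, a strict decline from 1980 to 2000, a further halving by
2010, and a plateau thereafter; TN is ten times TP.  River flow is
baseflow plus smoothed precipitation scaled by the catchment-to-lake area
ratio with a runoff coefficient of 0.7; river temperature equals the
same-day air temperature (floored at 0 °C); 60 % of each nutrient load
enters as dissolved inorganic nutrient and the non-bioavailable phosphorus
arrives bound to POC at Redfield ratio.  Concentrations are normalized per
year so the annual delivered mass equals the prescribed load exactly.

What the generator does **not** emulate: instrument-era inhomogeneity of
early records, spatial structure of the forcing, typhoon-scale extremes,
and interannual teleconnection regimes beyond AR(1) persistence.  Tests
passing under this generator therefore demonstrate the mechanisms and the
pipeline, not predictive skill for any specific lake.

## Turnover detection and its conventions

The detector declares turnover on the first day in the search window
(December 1 of the previous calendar year through April 30) on which the
surface-bottom differences in temperature *and* DO are simultaneously below
0.5 °C and 0.1 mg/L.  Timing is reported as integer days past January 1 of
the labelled year, so December detections are negative -- the label-year
convention is the package's decision, as is the window, chosen to bracket
generously the late-January-to-mid-March dates at which such detections
are observed.  The criterion must hold for a single archived day (daily
means); no multi-day persistence is required.  Gaps up to 7 days are
linearly interpolated; larger gaps are a data error, not a guess.

A secondary diagnostic, `curve_shape()`, classifies the bottom-water
temperature-DO trajectory: a turnover appears as a turning point where,
within 10 days, bottom temperature falls by at least 0.1 °C while bottom DO
rises by at least 0.5 mg/L.  The magnitudes are package-defined; in a 1-D
column the deep-water renewal signature is predominantly a sharp oxygen
jump with modest simultaneous cooling, which is why the temperature
threshold is small.  An observation-style criterion
(`observed_turnover_criterion()`: both surface and bottom DO within
10-11 mg/L) is provided for validating against monitoring-style series.

Validation metrics are RMSE and NRMSE (RMSE divided by the observed range),
with observation-model pairs matched by nearest timestamp within 3 days.

## Cross-year statistics

`aggregate_predictors()` builds one row per detection year with the six
candidate drivers -- cold-season (November-April) or annual means of air
temperature, precipitation, cloud cover and station wind speed, plus two
model outputs: the bottom-minus-surface density difference and the surface
POC concentration.  Station (pre-correction) wind is used in the predictor
table; the land-to-lake factor is a constant rescaling and cannot change
importance ranks.  Failed-turnover years keep their predictor rows but are
excluded from the response (an optional censored mode -- timing set to the
window end -- exists but is off by default).

`forest_importance()` fits a bagged regression-tree ensemble
(`randomForest`) and reports out-of-bag permutation importance (% increase
in MSE), total node-purity decrease, and out-of-bag variance explained --
out-of-bag was chosen for the variance-explained figure since the
alternative (in-bag fit) is not comparable across predictor sets.
`linear_fit()` and `period_split_fit()` are ordinary least squares with
t-based confidence intervals; the split year (default 1980, assigned to the
"before" period) separates the loading-driven era from the climate-driven
era.  No multiple-testing correction is applied -- raw R² values are
reported, as is conventional for these single-relationship analyses.

## Numerical choices and degenerate inputs

* Implicit diffusion conserves tracer mass to round-off by construction
  (flux form); boundary fluxes enter the budget exactly.
* Convective adjustment terminates in O(n) merges; on a monotone branch of
  the equation of state its fixed point is the unique
  pool-adjacent-violators solution, which is what the brute-force oracle in
  the test-suite computes.  Near the 4 °C density maximum the merge order
  is fixed (top-down with upward re-check), making results deterministic.
* The equation of state is the standard freshwater polynomial (density
  maximum 3.98 °C); cooling below 4 °C produces reverse stratification and
  convection correctly stops -- the model lake, like its archetype, does
  not rely on ice cover.
* Ecology uses forward Euler at the model step; the capped-sink scheme
  guarantees non-negativity at any step size, and `stability_check()`
  additionally bounds the fastest Q10-scaled rate at the warmest plausible
  temperature.
* The daily archive is the mean over that day's steps, not a midnight
  snapshot, because the turnover criterion operates on daily values.
* River inflow enters the surface layer and an equal outflow leaves it
  (surface outlets), conserving volume; a dense cold river parcel is
  immediately subject to convective adjustment.

## Problem sizes used in the tests

The test-suite runs the full 37-layer column at the 600 s default step for
the multi-year emergence test (six simulated years), and at 1 800 s for the
20-seed driver-sensitivity ensembles (four-year runs) -- diffusion is
implicit and the ecology rates are far from the positivity bound at either
step, so the coarser step changes nothing qualitative while keeping the
ensembles desk-scale.  Oracle-equivalence tests use randomized columns of
3-24 layers, 100 instances per kernel.

## Known limitations

* One column cannot represent basin-scale asymmetries (two-basin exchange,
  seiches, differential deepening) or horizontal nutrient transport; river
  water enters the surface layer regardless of its density-determined
  intrusion depth.
* The ecosystem has a single phytoplankton pool and fixed stoichiometry;
  no nitrogen fixation, denitrification, silica, or carbonate chemistry.
  Regression magnitudes involving DIP therefore depend on these
  reconstructed kinetics and should be read as directional, not absolute.
* The sediment is a single well-mixed pool per element with first-order
  kinetics -- a deliberate simplification of early diagenesis; the low-DO
  phosphorus-release enhancement is the one redox effect retained.
* The forcing generator's interannual variability is AR(1) persistence
  only; regime-scale climate variability (e.g. monsoon strength epochs)
  is not represented, which limits how much of the turnover-timing
  variance the cross-year driver analysis can explain.
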