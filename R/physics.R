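#' Freshwater density from temperature
#'
#' Standard freshwater polynomial equation of state (salinity zero), with a
#' density maximum at 3.98 degC where `water_density(4)` is 999.972 kg/m3.
#'
#' @param temp temperature in degC, between -0.5 and 40
#' @return density in kg/m3, same length as `temp`
#' @export
#' @examples
#' water_density(c(0, 4, 10, 25))
water_density <- function(temp) {
  if (any(!is.finite(temp)) || any(temp < -0.5) || any(temp > 40))
    stop("domain error: temperature must be finite and within [-0.5, 40] degC")
  water_density_cpp(as.numeric(temp))
}

#' Surface heat-flux breakdown
#'
#' Bulk surface heat budget: absorbed shortwave, net longwave
#' (Berliand-type clear-sky formula with cloud correction), and sensible and
#' latent fluxes from bulk-transfer formulas driven by the over-lake wind
#' (station wind times the land-to-lake factor).  Sign convention: positive
#' into the lake.  `total` is the sum of the four components;
#' `sw_penetrating` is the part of `shortwave_abs` that penetrates below the
#' surface layer.
#'
#' @param air_temp air temperature (degC)
#' @param wind station (land) wind speed (m/s)
#' @param cloud cloud-cover fraction in [0, 1]
#' @param shortwave incident shortwave (W/m2)
#' @param t_surface lake surface temperature (degC)
#' @param params a [physics_params()]
#' @return named vector: shortwave_abs, longwave_net, sensible, latent,
#'   total, sw_penetrating (W/m2)
#' @export
surface_heat_flux <- function(air_temp, wind, cloud, shortwave, t_surface,
                              params = physics_params()) {
  stopifnot(wind >= 0, cloud >= 0, cloud <= 1, shortwave >= 0)
  surface_heat_flux_cpp(air_temp, wind, cloud, shortwave, t_surface, params)
}

#' Exponential light profile at layer mid-depths
#'
#' I(z) = I0 exp(-k z) evaluated at the layer mid-depths, with an optional
#' POC-dependent extinction term (self-shading by particles).
#'
#' @param i0 penetrating irradiance just below the surface (W/m2)
#' @param grid a [column_grid()]
#' @param extinction background extinction coefficient (1/m), > 0
#' @param poc optional per-layer POC (mgC/m3)
#' @param kext_poc extinction per unit POC (m2/mgC)
#' @return irradiance per layer (W/m2), strictly decreasing with depth
#' @export
#' @examples
#' light_profile(100, column_grid(n_layers = 4), 0.4)
light_profile <- function(i0, grid, extinction, poc = NULL,
                          kext_poc = 0) {
  if (extinction <= 0) stop("extinction must be positive")
  n <- grid$n_layers
  kx <- rep(extinction, n)
  if (!is.null(poc)) kx <- kx + kext_poc * poc
  # cumulative attenuation to the top of each layer, then half a layer more
  atten_top <- c(0, cumsum(kx * grid$dz))[seq_len(n)]
  i0 * exp(-(atten_top + kx * grid$dz / 2))
}

#' Wind-driven vertical diffusivity profile
#'
#' Eddy diffusivity on the interior layer interfaces: the surface value
#' scales with the friction velocity of the over-lake wind (station wind
#' times the land-to-lake factor), decays exponentially over the mixing
#' length, and is damped where the density profile is stably stratified.
#' Never falls below the background diffusivity.
#'
#' @param wind station (land) wind speed (m/s)
#' @param density per-layer density (kg/m3)
#' @param grid a [column_grid()]
#' @param params a [physics_params()]
#' @return diffusivity K (m2/s) on the `n_layers - 1` interior interfaces
#' @export
wind_diffusivity <- function(wind, density, grid, params = physics_params()) {
  stopifnot(wind >= 0, length(density) == grid$n_layers)
  wind_diffusivity_cpp(wind, as.numeric(density), grid$dz, params)
}

#' Convective adjustment of an unstable column
#'
#' Wherever density decreases with depth, the offending contiguous layers
#' are homogenized to their volume-weighted mean -- temperature and all
#' passive tracers together -- re-checking upward after every merge until
#' the density profile is non-decreasing with depth (mixed-region
#' algorithm).  Heat and tracer mass are conserved exactly.
#'
#' @param temp per-layer temperature (degC)
#' @param tracers optional matrix (layers x tracers) mixed along with heat
#' @param grid a [column_grid()] (used only for a length check)
#' @return list with `temp` and `tracers` after adjustment
#' @export
convective_adjustment <- function(temp, tracers = NULL, grid = NULL) {
  if (!is.null(grid) && length(temp) != grid$n_layers)
    stop("temp must have one value per layer")
  if (is.null(tracers))
    tracers <- matrix(numeric(0), nrow = length(temp), ncol = 0)
  tracers <- as.matrix(tracers)
  out <- convective_adjustment_cpp(as.numeric(temp), tracers)
  colnames(out$tracers) <- colnames(tracers)
  out
}

#' Implicit vertical diffusion of a tracer
#'
#' Backward-Euler (unconditionally stable) solve of the vertical diffusion
#' equation on the layered grid, in flux form via a tridiagonal system.
#' With zero boundary fluxes the column integral of the tracer is conserved
#' to round-off, and no new extrema are created.
#'
#' @param conc per-layer concentration
#' @param K diffusivity (m2/s) on the `n_layers - 1` interior interfaces
#' @param dt time step (s)
#' @param grid a [column_grid()]
#' @param flux_top,flux_bottom boundary fluxes in concentration units * m/s,
#'   positive into the column
#' @return the concentration profile after one step
#' @export
diffuse <- function(conc, K, dt, grid, flux_top = 0, flux_bottom = 0) {
  stopifnot(length(conc) == grid$n_layers, all(K >= 0))
  diffuse_cpp(as.numeric(conc), as.numeric(K), dt, grid$dz,
              flux_top, flux_bottom)
}

#' Advance the physical state by one time step
#'
#' Applies, in order: the surface heat flux to the top layer with
#' penetrating shortwave absorbed down the column; implicit vertical heat
#' diffusion with the wind-driven diffusivity; convective adjustment of
#' temperature and tracers; river inflow into the surface layer with a
#' matching surface outflow (volume conserved); density update.
#'
#' @param temp per-layer temperature (degC)
#' @param meteo_day a one-row data.frame (or list) with `air_temp_c`,
#'   `wind_ms`, `cloud_frac`, `shortwave_wm2`
#' @param dt time step (s)
#' @param grid a [column_grid()]
#' @param params a [physics_params()]
#' @param tracers optional matrix (layers x tracers), mixed by convection
#'   and exchanged with river water when 6 columns (PHY, ZOO, DIN, DIP, DO,
#'   POC) are supplied
#' @param river optional list/one-row data.frame with `flow_m_day`,
#'   `temp_c`, `din_ugl`, `dip_ugl`, `do_mgl`, `poc_mgcm3`
#' @return list: `temp`, `tracers`, `density`, `K`, `flux` (the heat-flux
#'   breakdown) and the step's heat-ledger terms in J/m2
#' @export
advance_physics <- function(temp, meteo_day, dt, grid,
                            params = physics_params(), tracers = NULL,
                            river = NULL) {
  if (is.null(tracers))
    tracers <- matrix(numeric(0), nrow = length(temp), ncol = 0)
  tracers <- as.matrix(tracers)
  rv <- if (is.null(river)) rep(0, 6) else
    c(river$flow_m_day, river$temp_c, river$din_ugl, river$dip_ugl,
      river$do_mgl, river$poc_mgcm3)
  out <- advance_physics_cpp(as.numeric(temp), tracers,
                             meteo_day$air_temp_c, meteo_day$wind_ms,
                             meteo_day$cloud_frac, meteo_day$shortwave_wm2,
                             as.numeric(rv), dt, grid$dz, params)
  colnames(out$tracers) <- colnames(tracers)
  out
}
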