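#' Vertical column grid
#'
#' Uniform layered grid for the water column, depth positive downward.
#' The default (37 layers of 2.5 m) resolves a deep monomictic basin of
#' 92.5 m.
#'
#' @param n_layers number of layers (>= 3)
#' @param dz layer thickness in metres
#' @return an object of class `column_grid` with fields `n_layers`, `dz`,
#'   `z_mid` (layer mid-depths, m), `z_int` (interior interface depths, m)
#'   and `depth` (total column depth, m)
#' @export
#' @examples
#' g <- column_grid()
#' g$depth # 92.5
column_grid <- function(n_layers = 37, dz = 2.5) {
  if (n_layers < 3) stop("n_layers must be >= 3")
  if (dz <= 0) stop("dz must be positive")
  structure(list(
    n_layers = as.integer(n_layers), dz = dz,
    z_mid = (seq_len(n_layers) - 0.5) * dz,
    z_int = seq_len(n_layers - 1) * dz,
    depth = n_layers * dz
  ), class = "column_grid")
}

#' Physical submodel parameters
#'
#' Every coefficient of the physical submodel, named with units.  Defaults
#' are standard bulk-formula values for a temperate lake.
#'
#' @param albedo water surface shortwave albedo (-)
#' @param sw_surface_frac fraction of absorbed shortwave deposited in the
#'   surface layer (near-infrared); the remainder penetrates and is absorbed
#'   down the column following Beer-Lambert with `kext_heat`
#' @param kext_heat extinction coefficient for penetrating shortwave (1/m)
#' @param emissivity water longwave emissivity (-)
#' @param rel_humidity relative humidity assumed for the vapour-pressure
#'   terms (-); the forcing series carries no humidity variable
#' @param cloud_lw_coef cloud correction coefficient on net clear-sky
#'   longwave, applied as (1 - c * cloud^2)
#' @param c_sensible bulk transfer coefficient for sensible heat (-)
#' @param c_latent bulk transfer coefficient for latent heat (-)
#' @param rho_air air density (kg/m3)
#' @param cp_air air specific heat (J/kg/K)
#' @param latent_heat_vap latent heat of vaporisation (J/kg)
#' @param wind_factor land-to-lake wind-speed correction factor; over-lake
#'   wind = factor * station wind (default 1.2)
#' @param c_drag momentum drag coefficient (-)
#' @param rho0 reference water density (kg/m3)
#' @param cp_water water specific heat (J/kg/K)
#' @param k_background background (minimum) vertical diffusivity (m2/s)
#' @param c_k dimensionless scale for the wind-driven surface diffusivity,
#'   K0 = c_k * u_star * l_mix
#' @param l_mix e-folding depth of wind-driven diffusivity (m)
#' @param n0_sq buoyancy-frequency-squared scale for stability damping
#'   (1/s2); K is divided by (1 + N^2/n0_sq)^ri_exp where stratified
#' @param ri_exp exponent of the stability damping (-)
#' @param dt_max maximum admissible model time step (s)
#' @return a named list of class `physics_params`
#' @export
physics_params <- function(albedo = 0.07, sw_surface_frac = 0.45,
                           kext_heat = 0.30, emissivity = 0.97,
                           rel_humidity = 0.70, cloud_lw_coef = 0.65,
                           c_sensible = 1.3e-3, c_latent = 1.4e-3,
                           rho_air = 1.2, cp_air = 1005,
                           latent_heat_vap = 2.5e6, wind_factor = 1.2,
                           c_drag = 1.3e-3, rho0 = 1000, cp_water = 4186,
                           k_background = 2e-6, c_k = 0.35, l_mix = 24,
                           n0_sq = 1e-6, ri_exp = 1.7, dt_max = 3600) {
  p <- as.list(environment())
  stopifnot(albedo >= 0, albedo <= 1, sw_surface_frac >= 0,
            sw_surface_frac <= 1, k_background > 0, l_mix > 0, dt_max > 0)
  structure(p, class = "physics_params")
}

#' Ecosystem submodel parameters
#'
#' Rates are first-order per day at the reference temperature `t_ref` and
#' scale with a Q10 temperature factor.  Stoichiometry is Redfield
#' (C:N:P = 106:16:1 molar) with an O2:C mass ratio of 32/12.
#'
#' @param mu_max maximum phytoplankton growth rate (1/day at `t_ref`)
#' @param q10 Q10 temperature coefficient for biological rates (-)
#' @param t_ref reference temperature (degC)
#' @param k_light light half-saturation for photosynthesis (W/m2)
#' @param k_din DIN half-saturation (ugN/L)
#' @param k_dip DIP half-saturation (ugP/L)
#' @param r_phy phytoplankton respiration rate (1/day)
#' @param m_phy phytoplankton mortality rate (1/day)
#' @param g_max maximum zooplankton grazing rate (1/day)
#' @param ivlev Ivlev grazing coefficient (m3/mgC)
#' @param assim_eff zooplankton assimilation efficiency (0-1)
#' @param r_zoo zooplankton respiration/excretion rate (1/day)
#' @param m_zoo zooplankton mortality rate (1/day)
#' @param k_dec POC decomposition rate in the water column (1/day)
#' @param w_phy phytoplankton sinking speed (m/day)
#' @param w_poc POC sinking speed (m/day)
#' @param k_rea surface reaeration piston velocity (m/day)
#' @param k_sed sediment organic-carbon decay rate (1/day at `t_ref`)
#' @param sed_q10 Q10 for sediment decay (-)
#' @param p_enh_a low-oxygen enhancement amplitude of sediment phosphorus
#'   release; release is multiplied by 1 + a * K / (K + DO_bottom)
#' @param k_do_sed half-saturation DO of the enhancement (mg/L)
#' @param ratio_nc N:C mass ratio of organic matter (gN/gC, Redfield)
#' @param ratio_pc P:C mass ratio of organic matter (gP/gC, Redfield)
#' @param ratio_oc O2:C mass ratio of photosynthesis/respiration (gO2/gC)
#' @param do_cap supersaturation cap on DO as a multiple of saturation;
#'   excess is vented (bubble escape)
#' @param kext_w background light extinction of water (1/m)
#' @param kext_poc additional extinction per unit POC (m2/mgC)
#' @param excrete_direct if TRUE (default) zooplankton respiration releases
#'   nutrients directly to DIN/DIP; if FALSE the same carbon flux is routed
#'   to POC as fecal material (no oxygen consumed) and remineralises later
#' @return a named list of class `eco_params`
#' @export
eco_params <- function(mu_max = 2.0, q10 = 2.0, t_ref = 20, k_light = 25,
                       k_din = 10, k_dip = 1, r_phy = 0.08, m_phy = 0.05,
                       g_max = 0.3, ivlev = 0.01, assim_eff = 0.7,
                       r_zoo = 0.08, m_zoo = 0.04, k_dec = 0.05,
                       w_phy = 0.2, w_poc = 1.0, k_rea = 1.0,
                       k_sed = 0.002, sed_q10 = 2.0, p_enh_a = 2.0,
                       k_do_sed = 2.0,
                       ratio_nc = 16 * 14 / (106 * 12),
                       ratio_pc = 31 / (106 * 12),
                       ratio_oc = 32 / 12, do_cap = 1.2,
                       kext_w = 0.30, kext_poc = 5e-4,
                       excrete_direct = TRUE) {
  p <- as.list(environment())
  rates <- c(mu_max, r_phy, m_phy, g_max, r_zoo, m_zoo, k_dec, k_sed,
             k_rea, w_phy, w_poc)
  if (any(rates < 0)) stop("ecosystem rates must be non-negative")
  if (assim_eff < 0 || assim_eff > 1)
    stop("assim_eff must be in [0, 1]")
  structure(p, class = "eco_params")
}

#' List every ecosystem and physics parameter with its default
#'
#' @param physics,ecology parameter sets to dump
#' @return a data.frame (block, name, value)
#' @export
list_params <- function(physics = physics_params(), ecology = eco_params()) {
  pv <- vapply(physics, function(x) as.numeric(x)[1], numeric(1))
  ev <- vapply(ecology, function(x) as.numeric(x)[1], numeric(1))
  data.frame(
    block = c(rep("physics", length(pv)), rep("ecology", length(ev))),
    name = c(names(pv), names(ev)),
    value = unname(c(pv, ev)),
    stringsAsFactors = FALSE
  )
}

#' Initial column state
#'
#' A winter-like or user-specified starting state.  DO defaults to
#' saturation at the initial temperature.
#'
#' @param grid a [column_grid()]
#' @param temp initial temperature (degC), scalar or per-layer vector
#' @param phy,zoo,din,dip,poc initial concentrations (mgC/m3 for the biology
#'   and POC, ug/L for nutrients), scalar or per-layer
#' @param do initial DO (mg/L); `NULL` means saturation at `temp`
#' @param sed_c,sed_n,sed_p initial sediment pools (g/m2)
#' @return list with `temp` (vector), `eco` (matrix layers x 6, columns
#'   PHY, ZOO, DIN, DIP, DO, POC) and `sed` (length-3 vector C, N, P)
#' @export
init_state <- function(grid = column_grid(), temp = 8.5, phy = 10, zoo = 2,
                       din = 150, dip = 3, do = NULL, poc = 20,
                       sed_c = 50, sed_n = sed_c * 16 * 14 / (106 * 12),
                       sed_p = sed_c * 31 / (106 * 12)) {
  n <- grid$n_layers
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else
    if (length(x) == n) as.numeric(x) else
      stop("state fields must be scalar or one value per layer")
  temp <- rep_n(temp)
  if (is.null(do)) do <- do_saturation(temp)
  eco <- cbind(PHY = rep_n(phy), ZOO = rep_n(zoo), DIN = rep_n(din),
               DIP = rep_n(dip), DO = rep_n(do), POC = rep_n(poc))
  if (any(eco < 0)) stop("initial concentrations must be non-negative")
  list(temp = temp, eco = eco, sed = c(C = sed_c, N = sed_n, P = sed_p))
}

#' Check time-step admissibility before a run
#'
#' Verifies the sinking CFL condition (w * dt <= dz), the configured maximum
#' time step, and a positivity bound on the fastest ecosystem rate.  A
#' reporting operation: it never throws, it lists violated constraints.
#'
#' @param dt model time step (s)
#' @param grid a [column_grid()]
#' @param physics a [physics_params()]
#' @param ecology an [eco_params()]
#' @param t_max warmest temperature assumed when bounding Q10-scaled rates
#'   (degC)
#' @return list with `ok` (logical) and `violations` (character vector)
#' @export
stability_check <- function(dt, grid = column_grid(),
                            physics = physics_params(),
                            ecology = eco_params(), t_max = 32) {
  v <- character(0)
  dtd <- dt / 86400
  wmax <- max(ecology$w_phy, ecology$w_poc)
  if (wmax * dtd > grid$dz * (1 + 1e-12))
    v <- c(v, sprintf(
      "sinking CFL violated: w_sink * dt = %.3g m exceeds dz = %.3g m",
      wmax * dtd, grid$dz))
  if (dt > physics$dt_max)
    v <- c(v, sprintf("dt = %g s exceeds configured maximum %g s",
                      dt, physics$dt_max))
  ft <- ecology$q10^((t_max - ecology$t_ref) / 10)
  rmax <- ft * max(ecology$mu_max, ecology$g_max, ecology$k_dec,
                   ecology$r_phy + ecology$m_phy + ecology$g_max)
  if (rmax * dtd > 0.5)
    v <- c(v, sprintf(
      "ecology sub-step bound violated: max rate * dt = %.3g > 0.5",
      rmax * dtd))
  list(ok = length(v) == 0, violations = v)
}
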