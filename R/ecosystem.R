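#' Phytoplankton growth limitation factors
#'
#' Michaelis-Menten nutrient limitation, saturating light response, and a
#' Q10 temperature factor.  Nutrient limitation follows Liebig's minimum:
#' the total factor is f_light * min(f_N, f_P) * f_T.  All factors are in
#' [0, 1] except f_T, which may exceed 1 above the reference temperature by
#' the Q10 convention.
#'
#' @param light irradiance (W/m2)
#' @param din dissolved inorganic nitrogen (ugN/L)
#' @param dip dissolved inorganic phosphorus (ugP/L)
#' @param temp temperature (degC)
#' @param params an [eco_params()]
#' @return a data.frame with columns f_light, f_n, f_p, f_t, f_total
#' @export
#' @examples
#' growth_limitation(100, 10, 2, 20) # f_n = f_p = 0.5 at half-saturation
growth_limitation <- function(light, din, dip, temp,
                              params = eco_params()) {
  if (any(light < 0) || any(din < 0) || any(dip < 0))
    stop("light and nutrient concentrations must be non-negative")
  f_light <- light / (params$k_light + light)
  f_n <- din / (params$k_din + din)
  f_p <- dip / (params$k_dip + dip)
  f_t <- params$q10^((temp - params$t_ref) / 10)
  data.frame(f_light = f_light, f_n = f_n, f_p = f_p, f_t = f_t,
             f_total = f_light * pmin(f_n, f_p) * f_t)
}

#' Instantaneous biochemical tendencies
#'
#' Source-minus-sink rates (per day) for the six pelagic state variables in
#' each layer: photosynthesis grows phytoplankton; respiration, mortality,
#' and grazing reduce it; zooplankton assimilate part of their grazing and
#' egest the rest to POC; POC decomposes back to nutrients; every carbon,
#' nitrogen, phosphorus, and oxygen flux appears with equal magnitude and
#' opposite sign in exactly two budgets (or at a boundary), so elemental
#' totals close exactly when sinking and reaeration are off.
#'
#' @param state matrix (layers x 6), columns PHY, ZOO, DIN, DIP, DO, POC
#'   (mgC/m3, mgC/m3, ugN/L, ugP/L, mg/L, mgC/m3)
#' @param light per-layer irradiance (W/m2)
#' @param temp per-layer temperature (degC)
#' @param params an [eco_params()]
#' @return matrix of tendencies dC/dt (per day), same shape and units as
#'   `state`
#' @export
ecosystem_tendencies <- function(state, light, temp, params = eco_params()) {
  state <- as.matrix(state)
  if (ncol(state) != 6) stop("state must have 6 columns")
  if (any(state < 0)) stop("domain error: negative state variable")
  d <- eco_tendencies_cpp(state, as.numeric(light), as.numeric(temp), params)
  colnames(d) <- c("PHY", "ZOO", "DIN", "DIP", "DO", "POC")
  d
}

#' Dissolved-oxygen saturation concentration
#'
#' Standard freshwater solubility at 1 atm (Benson-Krause), strictly
#' decreasing in temperature; about 14.6 mg/L at 0 degC and in the
#' 10-11 mg/L band across the 8-12 degC winter-mixing range.
#'
#' @param temp temperature (degC) in [0, 40]
#' @return saturation DO (mg/L)
#' @export
#' @examples
#' do_saturation(c(0, 10, 25))
do_saturation <- function(temp) {
  if (any(!is.finite(temp)) || any(temp < 0) || any(temp > 40))
    stop("domain error: temperature must be within [0, 40] degC")
  do_saturation_cpp(as.numeric(temp))
}

#' Surface reaeration flux
#'
#' Linear relaxation of surface DO toward saturation with a constant piston
#' velocity: flux = k_rea (DOsat(T) - DO) / dz, in mg/L per day applied to
#' the surface layer.  Sign-symmetric about saturation (degassing when
#' supersaturated); an abiotic surface layer relaxes to saturation with
#' e-folding time dz / k_rea.
#'
#' @param do_surface surface DO (mg/L)
#' @param t_surface surface temperature (degC)
#' @param k_rea reaeration piston velocity (m/day), >= 0
#' @param dz surface-layer thickness (m)
#' @return tendency of surface DO (mg/L/day)
#' @export
reaeration_flux <- function(do_surface, t_surface, k_rea, dz) {
  if (k_rea < 0) stop("k_rea must be non-negative")
  k_rea * (do_saturation(t_surface) - do_surface) / dz
}

#' Particle sinking with sediment capture
#'
#' First-order upwind downward transport of a sinking tracer (phytoplankton
#' or POC).  Mass leaving the bottom layer accrues to the sediment; total
#' mass (water column + sediment flux) is conserved exactly.  Requires the
#' CFL condition w * dt <= dz.
#'
#' @param conc per-layer concentration
#' @param w_sink sinking speed (m/day), >= 0
#' @param dt time step (s)
#' @param grid a [column_grid()]
#' @return list with `conc` (profile after the step) and
#'   `flux_to_sediment` (concentration units * m delivered to the sediment)
#' @export
sinking <- function(conc, w_sink, dt, grid) {
  if (w_sink < 0) stop("w_sink must be non-negative")
  dtd <- dt / 86400
  if (w_sink * dtd > grid$dz * (1 + 1e-12))
    stop("step-size error: sinking CFL violated (w_sink * dt > dz)")
  sinking_cpp(as.numeric(conc), w_sink, dtd, grid$dz)
}

#' Sediment-water exchange fluxes
#'
#' The sediment organic-carbon pool decays at a temperature-dependent
#' first-order rate, consuming bottom-water oxygen (aerobic decay: the
#' oxygen demand is capped by the available bottom DO, and the carbon decay
#' and nitrogen release stall with it).  Phosphorus is released from its own
#' pool at the same base rate, multiplied by a low-oxygen enhancement factor
#' 1 + a K / (K + DO_bottom), and is not oxygen-limited (redox-driven
#' release continues in anoxia).
#'
#' @param sed_c,sed_n,sed_p sediment pools (gC/m2, gN/m2, gP/m2)
#' @param do_bottom bottom-layer DO (mg/L)
#' @param t_bottom bottom-layer temperature (degC)
#' @param params an [eco_params()]
#' @param dt time step (s) used for the oxygen-availability cap
#' @param dz bottom-layer thickness (m)
#' @return list of daily rates: `o2_demand` (mg/L/day drawn from the bottom
#'   layer), `din_release`, `dip_release` (ug/L/day added to the bottom
#'   layer), and `sed_decay` (gC/m2/day, gN/m2/day, gP/m2/day pool losses)
#' @export
sediment_exchange <- function(sed_c, sed_n, sed_p, do_bottom, t_bottom,
                              params = eco_params(), dt = 600, dz = 2.5) {
  stopifnot(sed_c >= 0, sed_n >= 0, sed_p >= 0)
  e <- params
  dtd <- dt / 86400
  ft <- e$sed_q10^((t_bottom - e$t_ref) / 10)
  decay_c <- e$k_sed * ft * sed_c
  o2_need <- decay_c * e$ratio_oc / dz * dtd
  fa <- if (o2_need > do_bottom && o2_need > 0) do_bottom / o2_need else 1
  decay_c <- decay_c * fa
  rel_n <- e$k_sed * ft * sed_n * fa
  enh <- 1 + e$p_enh_a * e$k_do_sed / (e$k_do_sed + do_bottom)
  rel_p <- min(e$k_sed * ft * sed_p * enh, if (dtd > 0) sed_p / dtd else Inf)
  list(o2_demand = decay_c * e$ratio_oc / dz,
       din_release = rel_n * 1000 / dz,
       dip_release = rel_p * 1000 / dz,
       sed_decay = c(C = decay_c, N = rel_n, P = rel_p))
}
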