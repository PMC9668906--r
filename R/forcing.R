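#' Scenario configuration for the synthetic forcing generator
#'
#' Defines the statistical structure of a multi-decadal daily forcing
#' scenario: climatological means and seasonal amplitudes of each
#' meteorological variable, a linear air-temperature trend, AR(1) daily
#' anomalies, and the nutrient-loading preset.  The defaults emulate the
#' climate of a temperate monomictic lake basin (annual mean air
#' temperature 14 degC, annual precipitation about 1700 mm) and a loading
#' history that rises to a mid-1970s peak, declines through 1980-2000, and
#' then plateaus.
#'
#' The seed fully determines the generated series.
#'
#' @param n_years number of simulated years (>= 1)
#' @param start_year first calendar year
#' @param seed integer random seed
#' @param mean_air_temp annual mean air temperature (degC)
#' @param amp_air_temp seasonal half-amplitude of air temperature (degC)
#' @param phase_air_temp day-of-year of the air-temperature minimum
#' @param trend_air_temp linear warming trend (degC per decade), applied
#'   centred on the middle of the series so the configured mean is preserved
#' @param mean_wind annual mean station wind speed (m/s)
#' @param amp_wind seasonal half-amplitude of wind (m/s), maximum in winter
#' @param mean_cloud annual mean cloud-cover fraction
#' @param amp_cloud seasonal half-amplitude of cloud cover, maximum in winter
#' @param annual_precip mean annual precipitation (mm)
#' @param amp_precip relative seasonal modulation of precipitation
#'   (0 = uniform; peak in summer)
#' @param sw_clear_mean annual mean clear-sky shortwave (W/m2)
#' @param sw_clear_amp seasonal half-amplitude of clear-sky shortwave (W/m2)
#' @param sw_cloud_atten shortwave attenuation per unit cloud cover;
#'   shortwave = clear-sky * (1 - atten * cloud)
#' @param ar1_coef AR(1) coefficient of the daily anomalies (per variable,
#'   named vector at, wind, cloud, precip)
#' @param noise_sd innovation standard deviations of the AR(1) anomalies
#'   (same names; precip noise is log-scale)
#' @param loading_preset one of "biwa-history", "constant", "custom"
#' @param loading_level constant-preset TP load (t/year); TN is
#'   `loading_tn_ratio` times TP
#' @param loading_tn_ratio TN:TP ratio of the external load (mass)
#' @param loading_custom for preset "custom", a data.frame
#'   (year, tn_load, tp_load)
#' @return an object of class `scenario_config`
#' @export
scenario_config <- function(n_years = 10, start_year = 2000, seed = 1,
                            mean_air_temp = 14, amp_air_temp = 11.5,
                            phase_air_temp = 25, trend_air_temp = 0,
                            mean_wind = 3.0, amp_wind = 0.8,
                            mean_cloud = 0.65, amp_cloud = 0.08,
                            annual_precip = 1700, amp_precip = 0.3,
                            sw_clear_mean = 230, sw_clear_amp = 115,
                            sw_cloud_atten = 0.65,
                            ar1_coef = c(at = 0.90, wind = 0.85,
                                         cloud = 0.50, precip = 0.40),
                            noise_sd = c(at = 1.2, wind = 0.8,
                                         cloud = 0.15, precip = 1.0),
                            loading_preset = "biwa-history",
                            loading_level = 1000,
                            loading_tn_ratio = 10,
                            loading_custom = NULL) {
  cfg <- as.list(environment())
  if (n_years < 1) stop("n_years must be >= 1")
  if (any(noise_sd < 0)) stop("configuration error: negative noise s.d.")
  if (any(c(amp_air_temp, amp_wind, amp_cloud, sw_clear_amp) < 0))
    stop("configuration error: seasonal amplitudes must be non-negative")
  if (any(abs(ar1_coef) >= 1)) stop("AR(1) coefficients must be in (-1, 1)")
  if (!loading_preset %in% c("biwa-history", "constant", "custom"))
    stop("configuration error: unknown loading preset '", loading_preset, "'")
  structure(cfg, class = "scenario_config")
}

# stationary AR(1) series of length n: z_t = phi z_{t-1} + N(0, sd)
ar1_series <- function(n, phi, sd) {
  if (sd == 0) return(rep(0, n))
  z <- numeric(n)
  stat_sd <- sd / sqrt(1 - phi^2)
  z[1] <- rnorm(1, 0, stat_sd)
  eps <- rnorm(n - 1, 0, sd)
  for (t in seq_len(n - 1)) z[t + 1] <- phi * z[t] + eps[t]
  z
}

# seasonal cosine keyed to each calendar year's own length, so the mean
# over any complete year is exactly the configured mean
seasonal_cos <- function(doy, year_len, peak_doy) {
  cos(2 * pi * (doy - peak_doy) / year_len)
}

#' Generate a daily synthetic meteorological series
#'
#' Each variable is a climatological seasonal cycle plus (for air
#' temperature) a centred linear trend plus AR(1) daily noise, clipped to
#' its physical domain.  Shortwave is derived from the clear-sky seasonal
#' curve attenuated by cloud cover.  Leap days are included; with zero noise
#' and zero trend every year of a variable is identical and the annual mean
#' of air temperature equals the configured mean exactly.
#'
#' @param config a [scenario_config()]
#' @return a data.frame with columns `date`, `air_temp_c`, `wind_ms`,
#'   `cloud_frac`, `precip_mm`, `shortwave_wm2`, one row per day
#' @export
#' @examples
#' m <- generate_meteo(scenario_config(n_years = 2, seed = 42))
#' round(mean(m$air_temp_c), 1)
generate_meteo <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  y0 <- config$start_year
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y0 + config$n_years - 1)),
               by = "day")
  n <- length(dates)
  yr <- as.integer(format(dates, "%Y"))
  doy <- as.integer(format(dates, "%j"))
  ylen <- ifelse(yr %% 4 == 0 & (yr %% 100 != 0 | yr %% 400 == 0), 366, 365)

  # years elapsed since mid-series, for the centred trend
  t_mid <- (as.numeric(dates) - mean(range(as.numeric(dates)))) / 365.25

  phi <- config$ar1_coef
  sdv <- config$noise_sd

  # air temperature: minimum at phase_air_temp (late January)
  at_season <- config$mean_air_temp -
    config$amp_air_temp * seasonal_cos(doy, ylen, config$phase_air_temp)
  at <- at_season + (config$trend_air_temp / 10) * t_mid +
    ar1_series(n, phi[["at"]], sdv[["at"]])

  # wind: seasonal maximum in winter (same phase as the cold minimum)
  ws <- config$mean_wind +
    config$amp_wind * seasonal_cos(doy, ylen, config$phase_air_temp) +
    ar1_series(n, phi[["wind"]], sdv[["wind"]])
  ws <- pmax(ws, 0.1)

  # cloud cover: winter maximum, clipped to [0, 1]
  cc <- config$mean_cloud +
    config$amp_cloud * seasonal_cos(doy, ylen, config$phase_air_temp) +
    ar1_series(n, phi[["cloud"]], sdv[["cloud"]])
  cc <- pmin(pmax(cc, 0), 1)

  # precipitation: seasonal intensity envelope (summer peak) times a
  # lognormal AR(1) factor with unit expectation
  env <- (config$annual_precip / 365.25) *
    (1 - config$amp_precip * seasonal_cos(doy, ylen, config$phase_air_temp))
  zp <- ar1_series(n, phi[["precip"]], sdv[["precip"]])
  if (sdv[["precip"]] > 0) {
    vstat <- sdv[["precip"]]^2 / (1 - phi[["precip"]]^2)
    pr <- env * exp(zp - vstat / 2)
  } else pr <- env

  # shortwave: clear-sky curve (summer maximum, i.e. opposite phase to the
  # cold-season peak) attenuated by cloud
  sw_clear <- config$sw_clear_mean -
    config$sw_clear_amp * seasonal_cos(doy, ylen, config$phase_air_temp + 183)
  sw <- pmax(sw_clear * (1 - config$sw_cloud_atten * cc), 0)

  data.frame(date = dates, air_temp_c = at, wind_ms = ws, cloud_frac = cc,
             precip_mm = pr, shortwave_wm2 = sw)
}

#' Generate an annual external nutrient-loading series
#'
#' The `"biwa-history"` preset is a unimodal eutrophication-oligotrophication
#' trajectory: loads rise to a 1975 peak, decline strictly from 1980 to
#' 2000, halve again by 2010, and plateau thereafter.  The `"constant"`
#' preset holds `loading_level` every year; `"custom"` passes
#' `loading_custom` through.
#'
#' @param config a [scenario_config()]
#' @return a data.frame (year, tn_load, tp_load), loads in t/year
#' @export
generate_loading <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- seq(config$start_year, config$start_year + config$n_years - 1)
  if (config$loading_preset == "constant") {
    tp <- rep(config$loading_level, length(years))
  } else if (config$loading_preset == "custom") {
    lc <- config$loading_custom
    if (is.null(lc) || !all(c("year", "tn_load", "tp_load") %in% names(lc)))
      stop("custom preset requires loading_custom with year, tn_load, tp_load")
    lc <- lc[lc$year %in% years, , drop = FALSE]
    return(lc[order(lc$year), c("year", "tn_load", "tp_load")])
  } else {
    tp <- vapply(years, biwa_history_tp, numeric(1))
  }
  data.frame(year = years, tn_load = config$loading_tn_ratio * tp,
             tp_load = tp)
}

# TP load trajectory (t/year): Gaussian rise to a 2200 t peak in 1975,
# linear easing to 2000 t by 1980, exponential halving 1980 -> 2000
# (2000 -> 1000 t) and 2000 -> 2010 (1000 -> 500 t), flat afterwards.
biwa_history_tp <- function(y) {
  if (y <= 1975) {
    400 + 1800 * exp(-((y - 1975) / 8)^2)
  } else if (y <= 1980) {
    2200 + (2000 - 2200) * (y - 1975) / 5
  } else if (y <= 2000) {
    2000 * 0.5^((y - 1980) / 20)
  } else if (y <= 2010) {
    1000 * 0.5^((y - 2000) / 10)
  } else {
    500
  }
}

#' Aggregate river configuration
#'
#' The many inflowing rivers of a real basin are collapsed to a configurable
#' set of aggregate sources (default three, weighted by catchment share);
#' in a one-dimensional column only their sum matters.
#'
#' @param catchment_area_km2 total catchment area draining to the lake
#' @param lake_area_km2 lake surface area
#' @param runoff_coef fraction of catchment precipitation that reaches the
#'   lake as river flow
#' @param baseflow_frac fraction of the annual flow delivered as constant
#'   baseflow (the configured minimum); the rest follows smoothed
#'   precipitation
#' @param smooth_days width of the moving-average smoothing applied to
#'   precipitation before converting it to flow
#' @param min_flow_m_day minimum daily inflow (m/day over the lake area);
#'   the baseflow floor that remains when precipitation vanishes
#' @param bioavail_n,bioavail_p fractions of the TN/TP load delivered as
#'   dissolved inorganic nutrient; the non-bioavailable phosphorus is
#'   delivered bound to POC at Redfield ratio
#' @param weights relative catchment-area weights of the aggregate rivers
#' @return a list of class `river_config`
#' @export
river_config <- function(catchment_area_km2 = 3174, lake_area_km2 = 670,
                         runoff_coef = 0.7, baseflow_frac = 0.3,
                         smooth_days = 7, min_flow_m_day = 1e-3,
                         bioavail_n = 0.6, bioavail_p = 0.6,
                         weights = c(0.5, 0.3, 0.2)) {
  stopifnot(runoff_coef > 0, runoff_coef <= 1,
            baseflow_frac >= 0, baseflow_frac <= 1,
            bioavail_n >= 0, bioavail_n <= 1,
            bioavail_p >= 0, bioavail_p <= 1)
  structure(as.list(environment()), class = "river_config")
}

#' Generate daily river inputs from meteorology and annual loads
#'
#' River flow is baseflow plus a component proportional to smoothed
#' precipitation, scaled so the annual flow equals the catchment water
#' balance; river temperature equals the same-day air temperature (floored
#' at 0 degC); nutrient concentrations are set per year so that the annual
#' mass flux equals that year's load times the bioavailable fraction
#' exactly.  River DO enters at saturation for the river temperature.
#'
#' @param meteo a daily forcing series from [generate_meteo()]
#' @param loading an annual series from [generate_loading()]
#' @param river a [river_config()]
#' @return a data.frame with columns `date`, `flow_m_day` (m/day of water
#'   over the lake area), `temp_c`, `din_ugl`, `dip_ugl`, `do_mgl`,
#'   `poc_mgcm3`
#' @export
generate_river_inputs <- function(meteo, loading, river = river_config()) {
  stopifnot(inherits(river, "river_config"))
  yr <- as.integer(format(meteo$date, "%Y"))
  if (!all(unique(yr) %in% loading$year))
    stop("alignment error: loading series does not cover the forcing years")
  rpc <- 31 / (106 * 12)

  # moving-average smoothing of precipitation (mm/day)
  k <- river$smooth_days
  pr <- meteo$precip_mm
  sm <- stats::filter(pr, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- pr[is.na(sm)]
  sm <- as.numeric(sm)

  area_ratio <- river$catchment_area_km2 / river$lake_area_km2
  flow <- numeric(length(pr))
  din <- dip <- poc <- numeric(length(pr))
  for (y in unique(yr)) {
    i <- which(yr == y)
    nd <- length(i)
    # annual inflow volume, expressed as metres of water over the lake area
    vol_y <- sum(pr[i]) / 1000 * area_ratio * river$runoff_coef
    base <- river$baseflow_frac * vol_y / nd
    s <- sum(sm[i])
    event <- if (s > 0) (1 - river$baseflow_frac) * vol_y * sm[i] / s else 0
    flow[i] <- pmax(base + event, river$min_flow_m_day)

    ld <- loading[loading$year == y, ]
    # concentrations constant within the year, scaled by the realised annual
    # volume so that sum(flow * conc) equals the annual load exactly;
    # load t/year = 1e9 mg; conc in mg/m3 over (vol m * area m2)
    vol_m3 <- sum(flow[i]) * river$lake_area_km2 * 1e6
    din[i] <- ld$tn_load * 1e9 * river$bioavail_n / vol_m3
    dip[i] <- ld$tp_load * 1e9 * river$bioavail_p / vol_m3
    poc[i] <- ld$tp_load * 1e9 * (1 - river$bioavail_p) / vol_m3 / rpc
  }
  rtemp <- pmax(meteo$air_temp_c, 0)
  data.frame(date = meteo$date, flow_m_day = flow, temp_c = rtemp,
             din_ugl = din, dip_ugl = dip,
             do_mgl = do_saturation(rtemp), poc_mgcm3 = poc)
}
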