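# Independent brute-force oracles used to cross-check the numerical kernels.
# These are written naively (loops, repeat-until-stable) and never call the
# package's own kernel for the quantity they check.

# freshwater density, re-stated independently for the oracle
oracle_density <- function(t) {
  999.842594 + 6.793952e-2 * t - 9.095290e-3 * t^2 + 1.001685e-4 * t^3 -
    1.120083e-6 * t^4 + 6.536332e-9 * t^5
}

# convective adjustment: repeatedly find the first adjacent pair of blocks
# with density decreasing downward and pool them (volume-weighted), starting
# from one block per layer, until the block densities are non-decreasing.
# For temperatures on a monotone branch of the equation of state this is
# pool-adjacent-violators, whose fixed point is unique, so any merge order
# gives the same answer.
oracle_convect <- function(temp, tracers = NULL) {
  n <- length(temp)
  if (is.null(tracers)) tracers <- matrix(numeric(0), n, 0)
  blocks <- lapply(seq_len(n), function(i)
    list(w = 1, t = temp[i], tr = tracers[i, , drop = TRUE]))
  repeat {
    rho <- vapply(blocks, function(b) oracle_density(b$t), numeric(1))
    bad <- which(diff(rho) < -1e-12)
    if (length(bad) == 0) break
    i <- bad[1]
    a <- blocks[[i]]; b <- blocks[[i + 1]]
    w <- a$w + b$w
    blocks[[i]] <- list(w = w, t = (a$w * a$t + b$w * b$t) / w,
                        tr = (a$w * a$tr + b$w * b$tr) / w)
    blocks[[i + 1]] <- NULL
  }
  t_out <- numeric(0); tr_out <- NULL
  for (b in blocks) {
    t_out <- c(t_out, rep(b$t, b$w))
    tr_out <- rbind(tr_out, matrix(rep(b$tr, b$w), nrow = b$w, byrow = TRUE))
  }
  if (ncol(tracers) == 0) tr_out <- matrix(numeric(0), n, 0)
  list(temp = t_out, tracers = tr_out)
}

# explicit forward-Euler diffusion with zero-flux boundaries, sub-stepped
oracle_diffuse_explicit <- function(conc, K, total_t, dz, n_sub) {
  dt <- total_t / n_sub
  n <- length(conc)
  for (s in seq_len(n_sub)) {
    flux <- K * diff(conc) / dz          # interface fluxes, downward gradient
    div <- c(flux, 0) - c(0, flux)       # into each layer
    conc <- conc + dt * div / dz
  }
  conc
}

# fine-stepped upwind sinking, returning profile and sediment gain
oracle_sink <- function(conc, w_mday, total_days, dz, n_sub) {
  dt <- total_days / n_sub
  sed <- 0
  n <- length(conc)
  for (s in seq_len(n_sub)) {
    cr <- w_mday * dt / dz
    sed <- sed + conc[n] * w_mday * dt
    conc <- conc * (1 - cr) + c(0, conc[-n]) * cr
  }
  list(conc = conc, sed = sed)
}

# exhaustive day-by-day turnover scan over an explicit window
oracle_detect <- function(dates, ts, tb, os, ob, year, t_thresh = 0.5,
                          do_thresh = 0.1) {
  w0 <- as.Date(sprintf("%d-12-01", year - 1))
  w1 <- as.Date(sprintf("%d-04-30", year))
  best <- NULL
  for (i in seq_along(dates)) {
    if (dates[i] < w0 || dates[i] > w1) next
    if (abs(ts[i] - tb[i]) < t_thresh && abs(os[i] - ob[i]) < do_thresh) {
      best <- as.integer(dates[i] - as.Date(sprintf("%d-01-01", year)))
      break
    }
  }
  best
}

# brute-force annual minimum scan
oracle_min_by_year <- function(dates, values) {
  yr <- as.integer(format(dates, "%Y"))
  out <- NULL
  for (y in sort(unique(yr))) {
    i <- which(yr == y)
    j <- i[which.min(values[i])]
    out <- rbind(out, data.frame(year = y, min = values[j],
                                 day = as.integer(format(dates[j], "%j"))))
  }
  out
}

# small biwa-like run shared by several test files (cheap: coarse dt)
biwa_run <- function(n_years = 3, seed = 5, dt = 1800, ...) {
  cfg <- scenario_config(n_years = n_years, start_year = 2000, seed = seed)
  meteo <- generate_meteo(cfg)
  river <- generate_river_inputs(meteo, generate_loading(cfg))
  run_lake(meteo, river, dt = dt, ...)
}

# cold-season (Nov-Apr) scenario perturbation of a forcing series
perturb_cold_season <- function(meteo, d_air = 0, wind_mult = 1) {
  cold <- as.integer(format(meteo$date, "%m")) %in% c(11, 12, 1:4)
  meteo$air_temp_c[cold] <- meteo$air_temp_c[cold] + d_air
  meteo$wind_ms[cold] <- meteo$wind_ms[cold] * wind_mult
  meteo
}

# physics with all surface heat exchange disabled (closed thermal column)
flux_off_physics <- function(...) {
  physics_params(albedo = 1, emissivity = 0, c_sensible = 0, c_latent = 0,
                 ...)
}
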