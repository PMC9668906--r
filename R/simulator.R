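# polynomial rolling hash of a serialized R object; used to stamp outputs
# so that a hash-identical configuration provably reproduces hash-identical
# data.  Arithmetic kept below 2^53 so it is exact in doubles.
config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h1 <- 0; h2 <- 0
  for (v in b) {
    h1 <- (h1 * 131 + v) %% 2147483647
    h2 <- (h2 * 137 + v) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' Run the coupled physics-ecosystem simulation
#'
#' Marches the one-dimensional column through the forcing period with the
#' operator-splitting order: physics (surface fluxes, heat diffusion,
#' convective adjustment, river exchange) -> tracer diffusion with the same
#' diffusivity as heat -> particle sinking -> biochemical tendencies
#' (forward integration with capped sinks so no state goes negative) ->
#' reaeration and sediment exchange.  The archive holds daily means of every
#' state variable; the run is deterministic given its inputs.
#'
#' @param meteo daily forcing from [generate_meteo()] (or
#'   [read_forcing_csv()]); one row per day, no gaps
#' @param river daily river inputs from [generate_river_inputs()], or
#'   `NULL` for a closed column
#' @param grid a [column_grid()]
#' @param physics a [physics_params()]
#' @param ecology an [eco_params()]
#' @param init initial state from [init_state()]
#' @param dt model time step in seconds; must divide 86400
#' @param archive_every archive thinning in days (1 = daily); thinning only
#'   subsets the archive, it never changes the dynamics
#' @param check if TRUE (default) run [stability_check()] first and stop on
#'   violations
#' @return an object of class `lake_sim`: `date`, `z_mid`, the time x depth
#'   matrices `temp`, `density`, `phy`, `zoo`, `din`, `dip`, `do`, `poc`,
#'   the `sediment` pool series, `surface`/`bottom` extracts, whole-run
#'   `budget` accumulators, the final state, and `meta` (configs, hash)
#' @export
#' @examples
#' \donttest{
#' m <- generate_meteo(scenario_config(n_years = 1, seed = 1))
#' sim <- run_lake(m, dt = 3600, grid = column_grid(n_layers = 10, dz = 5))
#' }
run_lake <- function(meteo, river = NULL, grid = column_grid(),
                     physics = physics_params(), ecology = eco_params(),
                     init = init_state(grid), dt = 600, archive_every = 1,
                     check = TRUE) {
  need <- c("date", "air_temp_c", "wind_ms", "cloud_frac", "shortwave_wm2")
  if (!all(need %in% names(meteo)))
    stop("meteo is missing columns: ",
         paste(setdiff(need, names(meteo)), collapse = ", "))
  if (any(diff(as.numeric(meteo$date)) != 1))
    stop("meteo must cover consecutive days without gaps")
  if (86400 %% dt != 0) stop("dt must divide 86400 s")
  if (check) {
    sc <- stability_check(dt, grid, physics, ecology)
    if (!sc$ok) stop("stability check failed:\n  ",
                     paste(sc$violations, collapse = "\n  "))
  }
  nd <- nrow(meteo)
  if (is.null(river)) {
    river_l <- list(flow = numeric(nd), temp = numeric(nd),
                    din = numeric(nd), dip = numeric(nd),
                    do = numeric(nd), poc = numeric(nd))
  } else {
    if (!all(river$date == meteo$date))
      stop("alignment error: river and meteo dates differ")
    river_l <- list(flow = river$flow_m_day, temp = river$temp_c,
                    din = river$din_ugl, dip = river$dip_ugl,
                    do = river$do_mgl, poc = river$poc_mgcm3)
  }
  forcing_l <- list(air_temp = meteo$air_temp_c, wind = meteo$wind_ms,
                    cloud = meteo$cloud_frac, shortwave = meteo$shortwave_wm2)
  steps_per_day <- as.integer(86400 / dt)

  out <- run_core_cpp(forcing_l, river_l, init$temp, init$eco, init$sed,
                      steps_per_day, grid$dz, physics, ecology)

  keep <- seq(1, nd, by = archive_every)
  n <- grid$n_layers
  arr <- function(m) {
    m <- m[keep, , drop = FALSE]
    dimnames(m) <- list(NULL, NULL)
    m
  }
  date <- meteo$date[keep]
  sim <- list(
    date = date, z_mid = grid$z_mid,
    temp = arr(out$temp), density = arr(out$density),
    phy = arr(out$phy), zoo = arr(out$zoo), din = arr(out$din),
    dip = arr(out$dip), do = arr(out$do), poc = arr(out$poc),
    sediment = {
      s <- out$sediment[keep, , drop = FALSE]
      colnames(s) <- c("sed_c", "sed_n", "sed_p"); s
    },
    surface = data.frame(date = date, temp = out$temp[keep, 1],
                         do = out$do[keep, 1], dip = out$dip[keep, 1],
                         poc = out$poc[keep, 1]),
    bottom = data.frame(date = date, temp = out$temp[keep, n],
                        do = out$do[keep, n], dip = out$dip[keep, n]),
    budget = out$budget,
    final = list(temp = out$final_temp, eco = out$final_eco,
                 sed = out$final_sed),
    init = init,
    meta = list(grid = unclass(grid), physics = unclass(physics),
                ecology = unclass(ecology), dt = dt,
                archive_every = archive_every,
                version = as.character(utils::packageVersion("monomict")))
  )
  sim$meta$hash <- config_hash(list(sim$meta, init, forcing_l, river_l))
  class(sim) <- "lake_sim"
  sim
}

#' @export
print.lake_sim <- function(x, ...) {
  cat("<lake_sim> ", format(x$date[1]), " to ", format(x$date[length(x$date)]),
      "  (", length(x$date), " archived days, ", length(x$z_mid),
      " layers, ", max(x$z_mid) + diff(x$z_mid[1:2]) / 2, " m)\n", sep = "")
  cat(sprintf("  surface T %5.1f..%5.1f degC   bottom T %5.1f..%5.1f degC\n",
              min(x$surface$temp), max(x$surface$temp),
              min(x$bottom$temp), max(x$bottom$temp)))
  cat(sprintf("  bottom DO %5.2f..%5.2f mg/L   config hash %s\n",
              min(x$bottom$do), max(x$bottom$do), x$meta$hash))
  invisible(x)
}

#' Surface and bottom daily series from a simulation
#'
#' @param sim a `lake_sim`
#' @return data.frame (date, t_surface, t_bottom, do_surface, do_bottom),
#'   the input expected by [detect_turnover()]
#' @export
surface_bottom <- function(sim) {
  stopifnot(inherits(sim, "lake_sim"))
  data.frame(date = sim$date,
             t_surface = sim$surface$temp, t_bottom = sim$bottom$temp,
             do_surface = sim$surface$do, do_bottom = sim$bottom$do)
}

#' Whole-run conservation residuals
#'
#' Closes the heat, carbon, nitrogen, phosphorus, and oxygen ledgers of a
#' run: change in storage (water column + sediment pools) minus the
#' accumulated boundary and biochemical source terms.  Residuals are
#' returned both absolutely and relative to the gross flux magnitude; both
#' should be at round-off level for any run.
#'
#' @param sim a `lake_sim`
#' @return data.frame (quantity, residual, scale, relative)
#' @export
budget_residuals <- function(sim) {
  stopifnot(inherits(sim, "lake_sim"))
  b <- sim$budget
  g <- sim$meta$grid
  p <- sim$meta$physics
  e <- sim$meta$ecology
  dz <- g$dz
  hc <- p$rho0 * p$cp_water * dz

  heat0 <- sum(sim$init$temp) * hc
  heat1 <- sum(sim$final$temp) * hc
  r_heat <- (heat1 - heat0) -
    (b$heat_surface_j + b$heat_river_in_j - b$heat_river_out_j)
  s_heat <- abs(b$heat_surface_j) + abs(b$heat_river_in_j) +
    abs(heat0) + abs(heat1)

  orgc <- function(eco, sed) sum(eco[, c(1, 2, 6)]) * dz + sed[1] * 1000
  c0 <- orgc(sim$init$eco, sim$init$sed)
  c1 <- orgc(sim$final$eco, sim$final$sed)
  r_c <- (c1 - c0) - (b$c_fixed_mg - b$c_respired_mg - b$c_sed_decay_mg +
                        b$c_river_in_mg - b$c_outflow_mg)
  s_c <- abs(c0) + abs(c1) + b$c_fixed_mg + b$c_respired_mg

  totn <- function(eco, sed)
    (sum(eco[, c(1, 2, 6)]) * e$ratio_nc + sum(eco[, 3])) * dz +
      sed[2] * 1000
  n0 <- totn(sim$init$eco, sim$init$sed)
  n1 <- totn(sim$final$eco, sim$final$sed)
  r_n <- (n1 - n0) - (b$n_river_in_mg - b$n_outflow_mg)
  s_n <- abs(n0) + abs(n1) + abs(b$n_river_in_mg)

  totp <- function(eco, sed)
    (sum(eco[, c(1, 2, 6)]) * e$ratio_pc + sum(eco[, 4])) * dz +
      sed[3] * 1000
  p0 <- totp(sim$init$eco, sim$init$sed)
  p1 <- totp(sim$final$eco, sim$final$sed)
  r_p <- (p1 - p0) - (b$p_river_in_mg - b$p_outflow_mg)
  s_p <- abs(p0) + abs(p1) + abs(b$p_river_in_mg)

  o0 <- sum(sim$init$eco[, 5]) * dz
  o1 <- sum(sim$final$eco[, 5]) * dz
  r_o <- (o1 - o0) - (b$o2_bio_g - b$o2_sed_g + b$o2_air_g - b$o2_vented_g +
                        b$o2_river_in_g - b$o2_outflow_g)
  s_o <- abs(o0) + abs(o1) + abs(b$o2_air_g) + abs(b$o2_bio_g) + b$o2_sed_g

  data.frame(
    quantity = c("heat", "carbon", "nitrogen", "phosphorus", "oxygen"),
    residual = c(r_heat, r_c, r_n, r_p, r_o),
    scale = c(s_heat, s_c, s_n, s_p, s_o),
    relative = abs(c(r_heat, r_c, r_n, r_p, r_o)) /
      pmax(c(s_heat, s_c, s_n, s_p, s_o), .Machine$double.eps)
  )
}
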