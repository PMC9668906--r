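test_that("equation of state has the freshwater density maximum near 4 degC", {
  expect_gt(water_density(4), water_density(0))
  expect_gt(water_density(4), water_density(10))
  expect_equal(water_density(4), 999.972, tolerance = 0.01)
  # independent polynomial evaluation over the range
  tt <- seq(-0.5, 40, by = 0.25)
  expect_equal(water_density(tt), oracle_density(tt), tolerance = 1e-12)
  # monotone decreasing on [4, 40]
  expect_true(all(diff(water_density(seq(4, 40, by = 0.1))) < 0))
  expect_error(water_density(45), "domain")
})

test_that("bulk transfer fluxes vanish without a gradient and wind", {
  f <- surface_heat_flux(air_temp = 10, wind = 0, cloud = 0, shortwave = 0,
                         t_surface = 10)
  expect_equal(unname(f["sensible"]), 0)
  expect_equal(unname(f["latent"]), 0)
  expect_lt(unname(f["longwave_net"]), 0)
  expect_equal(unname(f["total"]), unname(f["longwave_net"]))
})

test_that("sensible and latent fluxes are linear in wind speed", {
  f1 <- surface_heat_flux(5, wind = 3, cloud = 0.5, shortwave = 100,
                          t_surface = 12)
  f2 <- surface_heat_flux(5, wind = 6, cloud = 0.5, shortwave = 100,
                          t_surface = 12)
  expect_equal(unname(f2["sensible"]), 2 * unname(f1["sensible"]))
  expect_equal(unname(f2["latent"]), 2 * unname(f1["latent"]))
  # flux breakdown sums to the total
  expect_equal(unname(f1["total"]),
               sum(f1[c("shortwave_abs", "longwave_net", "sensible",
                        "latent")]))
})

test_that("equilibrium surface temperature matches an independent root-finder", {
  # constant forcing; evolve a single well-mixed layer to steady state
  p <- physics_params()
  meteo <- list(air_temp_c = 12, wind_ms = 4, cloud_frac = 0.5,
                shortwave_wm2 = 180)
  g <- column_grid(n_layers = 3, dz = 2)
  temp <- rep(15, 3)
  for (i in 1:4000) {
    temp <- advance_physics(temp, meteo, dt = 3600, grid = g,
                            params = p)$temp
  }
  root <- uniroot(function(ts)
    surface_heat_flux(12, 4, 0.5, 180, ts, p)[["total"]],
    c(0, 40))$root
  expect_equal(mean(temp), root, tolerance = 1e-3)
})

test_that("light profile follows Beer-Lambert at layer mid-depths", {
  g <- column_grid(n_layers = 4, dz = 5)
  li <- light_profile(100, g, extinction = 0.4)
  expect_equal(li[1], 100 * exp(-1.0))   # first mid-depth is 2.5 m
  expect_equal(li[2], 100 * exp(-0.4 * 7.5))
  expect_true(all(diff(li) < 0))
  # extinction -> 0+ limit: all layers approach I0
  expect_equal(light_profile(100, g, extinction = 1e-9),
               rep(100, 4), tolerance = 1e-6)
  expect_error(light_profile(100, g, extinction = 0), "positive")
})

test_that("wind diffusivity is non-decreasing in wind and floors at background", {
  g <- column_grid(n_layers = 10, dz = 2.5)
  p <- physics_params()
  rho <- water_density(seq(20, 8, length.out = 10))  # stable profile
  k0 <- wind_diffusivity(0, rho, g, p)
  expect_equal(k0, rep(p$k_background, 9))
  winds <- seq(0, 12, by = 0.5)
  kk <- sapply(winds, function(w) wind_diffusivity(w, rho, g, p))
  expect_true(all(apply(kk, 1, function(x) all(diff(x) >= 0))))
})

test_that("the land-to-lake wind factor rescales the station wind exactly", {
  g <- column_grid(n_layers = 8, dz = 2.5)
  rho <- water_density(seq(18, 9, length.out = 8))
  k_a <- wind_diffusivity(5, rho, g, physics_params(wind_factor = 1.2))
  k_b <- wind_diffusivity(6, rho, g, physics_params(wind_factor = 1.0))
  expect_equal(k_a, k_b)
})

test_that("convective adjustment matches the brute-force pooling oracle", {
  set.seed(42)
  for (case in 1:120) {
    n <- sample(3:20, 1)
    temp <- runif(n, 5, 28)              # monotone branch of the EOS
    tracers <- matrix(runif(n * 3, 0, 50), n, 3)
    got <- convective_adjustment(temp, tracers)
    want <- oracle_convect(temp, tracers)
    expect_equal(got$temp, want$temp, tolerance = 1e-12)
    expect_equal(unname(got$tracers), unname(want$tracers),
                 tolerance = 1e-12)
    # conservation and stability
    expect_lt(abs(sum(got$temp) - sum(temp)), 1e-10 * max(1, sum(temp)))
    expect_true(all(diff(water_density(got$temp)) > -1e-9))
  }
})

test_that("a stable profile passes through convective adjustment unchanged", {
  temp <- seq(24, 8, length.out = 12)
  out <- convective_adjustment(temp)
  expect_identical(out$temp, temp)
  # two-layer unstable column mixes to the volume-weighted mean
  out2 <- convective_adjustment(c(5, 10))
  expect_equal(out2$temp, c(7.5, 7.5))
})

test_that("implicit diffusion conserves mass and has the right limits", {
  g <- column_grid(n_layers = 12, dz = 2)
  K <- rep(1e-4, 11)
  u <- rep(3.7, 12)
  expect_equal(diffuse(u, K, 600, g), u)  # uniform is an equilibrium
  step <- c(rep(10, 6), rep(0, 6))
  # long-time limit: uniform at the conserved mean
  x <- step
  for (i in 1:200) x <- diffuse(x, K, 86400, g)
  expect_equal(x, rep(5, 12), tolerance = 1e-6)
  # conservation over randomized K
  set.seed(1)
  for (case in 1:20) {
    K2 <- runif(11, 0, 5e-3)
    x0 <- runif(12, 0, 10)
    y <- diffuse(x0, K2, 3600, g)
    expect_lt(abs(sum(y) - sum(x0)), 1e-10 * sum(x0))
  }
})

test_that("implicit diffusion converges to the fine-step explicit oracle", {
  g <- column_grid(n_layers = 8, dz = 1)
  set.seed(3)
  K <- runif(7, 1e-5, 1e-4)
  x0 <- runif(8, 1, 10)
  total_t <- 500
  # both integrations resolved enough that each is within ~1e-7 of the
  # continuum solution, so they agree to 1e-6
  x <- x0
  for (i in 1:1000) x <- diffuse(x, K, total_t / 1000, g)
  want <- oracle_diffuse_explicit(x0, K, total_t, g$dz, n_sub = 5e4)
  expect_equal(x, want, tolerance = 1e-6)
})

test_that("boundary fluxes enter the diffusion budget exactly", {
  g <- column_grid(n_layers = 6, dz = 2)
  K <- rep(1e-4, 5)
  x0 <- rep(4, 6)
  ft <- 1e-3  # conc * m / s into the top
  x <- diffuse(x0, K, 500, g, flux_top = ft)
  expect_equal(sum(x) * g$dz, sum(x0) * g$dz + ft * 500, tolerance = 1e-10)
})

test_that("a closed, windless, uniform column does not drift", {
  g <- column_grid(n_layers = 10, dz = 2.5)
  p <- flux_off_physics()
  meteo <- list(air_temp_c = 10, wind_ms = 0, cloud_frac = 0.5,
                shortwave_wm2 = 200)
  temp <- rep(9.3, 10)
  out <- advance_physics(temp, meteo, dt = 600, grid = g, params = p)
  expect_equal(out$temp, temp, tolerance = 1e-12)
})

test_that("persistent strong cooling drives the column isothermal", {
  g <- column_grid(n_layers = 10, dz = 2.5)
  # cooling toward an equilibrium above the 4 degC density maximum, so
  # convection keeps reaching the bottom (the turnover analogue)
  meteo <- list(air_temp_c = 8, wind_ms = 6, cloud_frac = 0,
                shortwave_wm2 = 0)
  temp <- seq(20, 8, length.out = 10)  # summer-like stratification
  for (i in 1:(60 * 24)) {
    temp <- advance_physics(temp, meteo, dt = 3600,
                            grid = g, params = physics_params())$temp
  }
  expect_lt(max(temp) - min(temp), 0.1)
})

test_that("each physics step closes its heat budget", {
  g <- column_grid(n_layers = 10, dz = 2.5)
  p <- physics_params()
  hc <- p$rho0 * p$cp_water * g$dz
  set.seed(8)
  temp <- seq(18, 8, length.out = 10)
  riv <- list(flow_m_day = 0.02, temp_c = 11, din_ugl = 100, dip_ugl = 10,
              do_mgl = 10, poc_mgcm3 = 50)
  tracers <- matrix(runif(60, 0, 20), 10, 6)
  for (i in 1:50) {
    meteo <- list(air_temp_c = runif(1, -5, 30), wind_ms = runif(1, 0, 10),
                  cloud_frac = runif(1), shortwave_wm2 = runif(1, 0, 300))
    out <- advance_physics(temp, meteo, dt = 600, grid = g, params = p,
                           tracers = tracers, river = riv)
    gain <- sum(out$temp) * hc - sum(temp) * hc
    ledger <- out$heat_surface_j + out$heat_river_in_j - out$heat_river_out_j
    expect_equal(gain, ledger, tolerance = 1e-6 * max(1, abs(ledger)))
    temp <- out$temp; tracers <- out$tracers
  }
})
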