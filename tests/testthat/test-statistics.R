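# minimal synthetic predictor table: timing driven by chosen columns
make_table <- function(n = 30, seed = 1, driver = "WS", beta = -8,
                       noise = 1) {
  set.seed(seed)
  tab <- data.frame(year = seq_len(n) + 1980,
                    AT = rnorm(n, 5, 1), pptn = rnorm(n, 4, 0.5),
                    CC = runif(n, 0.5, 0.8), DD = rnorm(n, 0.3, 0.1),
                    POC = rnorm(n, 40, 8), WS = rnorm(n, 3.5, 0.6))
  tab$timing <- 40 + beta * (tab[[driver]] - mean(tab[[driver]])) +
    rnorm(n, 0, noise)
  tab$failed <- FALSE
  tab
}

test_that("predictor aggregation reduces to the constant on constant input", {
  dates <- seq(as.Date("2001-06-01"), as.Date("2004-08-31"), by = "day")
  nd <- length(dates)
  meteo <- data.frame(date = dates, air_temp_c = 6, wind_ms = 3.2,
                      cloud_frac = 0.7, precip_mm = 4.4,
                      shortwave_wm2 = 100)
  # hand-built archive: isothermal column (DD = 0), constant surface POC
  sim <- structure(list(
    date = dates, z_mid = c(1.25, 3.75),
    density = matrix(water_density(8), nd, 2),
    poc = matrix(55, nd, 2)), class = "lake_sim")
  tv <- data.frame(year = 2003, timing = 35L, failed = FALSE)
  tab <- aggregate_predictors(sim, meteo, tv, mode = "cold_season")
  expect_equal(tab$AT, 6)
  expect_equal(tab$WS, 3.2)
  expect_equal(tab$CC, 0.7)
  expect_equal(tab$pptn, 4.4)
  expect_equal(tab$DD, 0)
  expect_equal(tab$POC, 55)
  expect_equal(tab$timing, 35L)
  tab_a <- aggregate_predictors(sim, meteo, tv, mode = "annual")
  expect_equal(tab_a$AT, 6)
  # a partially covered season is dropped with a warning (calendar 2001 is
  # only covered from June onward)
  expect_warning(
    none <- aggregate_predictors(sim, meteo,
                                 data.frame(year = 2001, timing = 1L,
                                            failed = FALSE),
                                 mode = "annual"),
    "incomplete")
  expect_null(none)
})

test_that("cold-season aggregation matches independent subset arithmetic", {
  cfg <- scenario_config(n_years = 3, start_year = 2000, seed = 15)
  meteo <- generate_meteo(cfg)
  from <- as.Date("2001-11-01"); to <- as.Date("2002-04-30")
  i <- meteo$date >= from & meteo$date <= to
  sim <- structure(list(
    date = meteo$date, z_mid = c(1, 3),
    density = cbind(water_density(pmax(meteo$air_temp_c, 4)),
                    water_density(rep(8, nrow(meteo)))),
    poc = matrix(seq_len(nrow(meteo)) / 10, nrow(meteo), 2)),
    class = "lake_sim")
  tv <- data.frame(year = 2002, timing = 20L, failed = FALSE)
  tab <- aggregate_predictors(sim, meteo, tv)
  expect_equal(tab$AT, mean(meteo$air_temp_c[i]))
  expect_equal(tab$DD, mean(sim$density[i, 2] - sim$density[i, 1]))
  expect_equal(tab$POC, mean(sim$poc[i, 1]))
})

test_that("ordinary least squares recovers exact and null relationships", {
  # exact data make summary.lm warn about a perfect fit; that is the point
  f <- suppressWarnings(linear_fit(1:10, 2 * (1:10) + 1))
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_equal(f$n, 10)
  set.seed(5)
  g <- linear_fit(rnorm(2000), rnorm(2000))
  expect_lt(g$r2, 0.01)
  expect_error(linear_fit(rep(3, 5), 1:5), "zero variance")
  expect_error(linear_fit(1:2, 1:2), "n >= 3")
})

test_that("period split equals two independent fits with the boundary before", {
  set.seed(3)
  years <- 1960:2010
  x <- runif(length(years), 1, 9)
  y <- 5 - 0.8 * x + rnorm(length(years), 0, 0.4)
  ps <- period_split_fit(x, y, years, split_year = 1980)
  i <- years <= 1980
  expect_equal(ps$before, linear_fit(x[i], y[i]))
  expect_equal(ps$after, linear_fit(x[!i], y[!i]))
  # piecewise construction: tight before, noisy after
  y2 <- ifelse(i, 10 - x, rnorm(length(years), 5, 3))
  ps2 <- suppressWarnings(period_split_fit(x, y2, years)) # exact "before"
  expect_gt(ps2$before$r2, ps2$after$r2)
  expect_error(period_split_fit(x[1:5], y[1:5], c(1970, 1971, 1972, 1990,
                                                  1991)),
               "at least 3")
})

test_that("forest importance is reproducible and needs enough rows", {
  tab <- make_table(n = 20, seed = 2)
  f1 <- forest_importance(tab, n_trees = 100, seed = 9)
  f2 <- forest_importance(tab, n_trees = 100, seed = 9)
  expect_identical(f1$importance, f2$importance)
  expect_identical(f1$var_explained, f2$var_explained)
  expect_setequal(f1$importance$predictor,
                  c("AT", "pptn", "CC", "DD", "POC", "WS"))
  expect_lte(f1$var_explained, 100)
  expect_error(forest_importance(make_table(n = 5), n_trees = 50),
               "at least 8")
  expect_error(forest_importance(make_table(20)[, c("AT", "timing")],
                                 n_trees = 50),
               "2 predictors")
})

test_that("a planted dominant driver ranks first on both importance measures", {
  hits <- 0
  for (seed in 1:5) {
    tab <- make_table(n = 30, seed = seed, driver = "WS", beta = -8,
                      noise = 1)
    fi <- forest_importance(tab, n_trees = 300, seed = seed)
    imp <- fi$importance
    first_mse <- imp$predictor[which.max(imp$pct_inc_mse)]
    first_np <- imp$predictor[which.max(imp$node_purity)]
    if (first_mse == "WS" && first_np == "WS") hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("failed-turnover years are excluded from the forest response", {
  tab <- make_table(n = 20, seed = 4)
  tab$timing[3] <- NA; tab$failed[3] <- TRUE
  fi <- forest_importance(tab, n_trees = 100, seed = 1)
  expect_equal(fi$n, 19)
})

test_that("shuffling a predictor does not raise its importance", {
  tab <- make_table(n = 40, seed = 6, driver = "WS", beta = -8, noise = 0.5)
  fi <- forest_importance(tab, n_trees = 400, seed = 11)
  shuffled <- tab
  set.seed(100)
  shuffled$WS <- sample(shuffled$WS)
  fs <- forest_importance(shuffled, n_trees = 400, seed = 11)
  ws  <- fi$importance$pct_inc_mse[fi$importance$predictor == "WS"]
  ws2 <- fs$importance$pct_inc_mse[fs$importance$predictor == "WS"]
  expect_lt(ws2, ws)
})
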