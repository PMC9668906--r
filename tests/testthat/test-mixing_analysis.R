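# construct a winter series in which the turnover criterion first co-holds
# on a chosen date
make_winter_series <- function(year, hit_date = NULL, dt_base = 3,
                               ddo_base = 2) {
  dates <- seq(as.Date(sprintf("%d-10-01", year - 1)),
               as.Date(sprintf("%d-05-31", year)), by = "day")
  n <- length(dates)
  dts <- rep(dt_base, n)   # surface-bottom temperature difference
  dos <- rep(ddo_base, n)
  if (!is.null(hit_date)) {
    i <- which(dates >= hit_date)
    dts[i] <- 0.2; dos[i] <- 0.05
  }
  data.frame(date = dates, t_surface = 8 + dts, t_bottom = 8,
             do_surface = 9 + dos, do_bottom = 9)
}

test_that("turnover timing is days past January 1 of the labelled year", {
  s <- make_winter_series(2008, as.Date("2008-02-11"))
  tv <- detect_turnover(s)
  expect_equal(tv$year, 2008)
  expect_false(tv$failed)
  expect_equal(tv$timing, 41)      # Feb 11 is 41 days past Jan 1
  expect_equal(timing_to_date(2008, tv$timing), as.Date("2008-02-11"))
  expect_lt(tv$delta_t, 0.5)
  expect_lt(tv$delta_do, 0.1)
})

test_that("December detections get negative day numbers", {
  s <- make_winter_series(2011, as.Date("2010-12-20"))
  tv <- detect_turnover(s)
  expect_equal(tv$timing, -12)
  expect_equal(timing_to_date(2011, -12), as.Date("2010-12-20"))
})

test_that("a permanently stratified winter is a failed turnover", {
  s <- make_winter_series(2009, hit_date = NULL, dt_base = 1.2)
  tv <- detect_turnover(s)
  expect_true(tv$failed)
  expect_true(is.na(tv$timing))
})

test_that("both criteria must hold simultaneously", {
  s <- make_winter_series(2010, as.Date("2010-02-01"))
  s$do_surface <- s$do_bottom + 2      # DO never equalizes
  tv <- detect_turnover(s)
  expect_true(tv$failed)
})

test_that("detector equals an exhaustive day-by-day scan on random series", {
  set.seed(77)
  for (case in 1:100) {
    year <- sample(2000:2016, 1)
    dates <- seq(as.Date(sprintf("%d-11-15", year - 1)),
                 as.Date(sprintf("%d-05-15", year)), by = "day")
    n <- length(dates)
    ts <- 8 + abs(cumsum(rnorm(n, 0, 0.3)))
    tb <- rep(8, n)
    os <- 9 + abs(cumsum(rnorm(n, 0, 0.1)))
    ob <- rep(9, n)
    s <- data.frame(date = dates, t_surface = ts, t_bottom = tb,
                    do_surface = os, do_bottom = ob)
    got <- detect_turnover(s, years = year)
    want <- oracle_detect(dates, ts, tb, os, ob, year)
    if (is.null(want)) {
      expect_true(got$failed)
    } else {
      expect_equal(got$timing, want)
    }
  }
})

test_that("timing / calendar round-trip is lossless across leap years", {
  for (year in c(2007, 2008, 2016)) {       # 2008 and 2016 are leap years
    for (timing in c(-31, -1, 0, 41, 59, 60, 120)) {
      d <- timing_to_date(year, timing)
      expect_equal(date_to_timing(d, year), timing)
    }
  }
  expect_equal(timing_to_date(2008, 59), as.Date("2008-02-29"))
  expect_equal(timing_to_date(2009, 59), as.Date("2009-03-01"))
})

test_that("gaps up to 7 days are interpolated and larger ones rejected", {
  s <- make_winter_series(2012, as.Date("2012-02-05"))
  drop <- seq(40, 44)                       # a 5-day hole
  tv <- detect_turnover(s[-drop, ])
  expect_false(tv$failed)
  s2 <- s[-seq(40, 60), ]                   # a 21-day hole
  expect_error(detect_turnover(s2, years = 2012), "gap")
})

test_that("curve shape classifies turning points versus straight lines", {
  dates <- seq(as.Date("2007-12-01"), as.Date("2008-04-30"), by = "day")
  n <- length(dates)
  # sharp bottom cooling with simultaneous DO jump mid-February
  tb <- c(rep(8.5, 75), seq(8.5, 7.2, length.out = 10), rep(7.2, n - 85))
  ob <- c(rep(6, 75), seq(6, 9.5, length.out = 10), rep(9.5, n - 85))
  s <- data.frame(date = dates, t_bottom = tb, do_bottom = ob)
  cs <- curve_shape(s, years = 2008)
  expect_equal(cs$shape, "turnover-like")
  expect_false(is.na(cs$turning_timing))
  # monotone co-rising temperature and DO: no turning point
  s2 <- data.frame(date = dates,
                   t_bottom = seq(7.8, 8.8, length.out = n),
                   do_bottom = seq(6, 8, length.out = n))
  expect_equal(curve_shape(s2, years = 2008)$shape, "straight-line")
})

test_that("curve shape agrees with the threshold detector on simulated winters", {
  sim <- biwa_run(n_years = 4, seed = 31, dt = 1800)
  sb <- surface_bottom(sim)
  tv <- detect_turnover(sb)
  cs <- curve_shape(sb)
  agree <- (tv$failed & cs$shape == "straight-line") |
    (!tv$failed & cs$shape == "turnover-like")
  expect_gte(mean(agree), 2 / 3)
})

test_that("validation metrics reproduce hand-computed values", {
  m <- rmse_nrmse(c(1, 2, 3), c(2, 3, 4))
  expect_equal(m$rmse, 1)
  expect_equal(m$nrmse, 0.5)
  expect_equal(rmse_nrmse(c(4, 7), c(4, 7))$rmse, 0)
  # date-matched pairing within the tolerance
  obs <- data.frame(date = as.Date("2001-06-01") + c(0, 10, 40),
                    value = c(10, 12, 20))
  mod <- data.frame(date = as.Date("2001-06-01") + 0:45,
                    value = seq(10, 19, length.out = 46))
  m2 <- rmse_nrmse(obs, mod)
  expect_equal(m2$n, 3)
  want <- sqrt(mean((obs$value - mod$value[c(1, 11, 41)])^2))
  expect_equal(m2$rmse, want)
  expect_equal(m2$nrmse, want / 10)
  # zero observed range flags NRMSE as undefined
  expect_warning(z <- rmse_nrmse(c(5, 5, 5), c(4, 5, 6)), "range")
  expect_true(is.na(z$nrmse))
  expect_error(rmse_nrmse(1, 1), "pairs")
})

test_that("annual hypoxia index scans complete years only", {
  dates <- seq(as.Date("2001-01-01"), as.Date("2002-12-31"), by = "day")
  dox <- rep(8, length(dates))
  x <- data.frame(date = dates, do_bottom = dox)
  h <- annual_hypoxia_index(x)
  expect_equal(h$min_do, c(8, 8))
  expect_equal(h$day, c(1, 1))             # first occurrence on ties
  # a single dip on Sep 10 of a non-leap year is day 253
  dox2 <- dox
  dox2[dates == as.Date("2001-09-10")] <- 2
  h2 <- annual_hypoxia_index(data.frame(date = dates, do_bottom = dox2))
  expect_equal(h2$min_do[1], 2)
  expect_equal(h2$day[1], 253)
  # random series match the brute-force scan
  set.seed(12)
  dox3 <- 6 + cumsum(rnorm(length(dates), 0, 0.1))
  h3 <- annual_hypoxia_index(data.frame(date = dates, do_bottom = dox3))
  want <- oracle_min_by_year(dates, dox3)
  expect_equal(h3$min_do, want$min)
  expect_equal(h3$day, want$day)
  # partial years are excluded with a warning
  expect_warning(
    h4 <- annual_hypoxia_index(data.frame(date = dates, do_bottom = dox3)[
      -(1:100), ]), "partial")
  expect_equal(h4$year, 2002)
})

test_that("the DO-band observation criterion finds the first qualifying day", {
  dates <- seq(as.Date("2005-10-01"), as.Date("2006-05-31"), by = "day")
  n <- length(dates)
  s <- data.frame(date = dates, do_surface = rep(10.5, n),
                  do_bottom = rep(10.5, n))
  oc <- observed_turnover_criterion(s)
  expect_true(oc$detected)
  expect_equal(oc$date, as.Date("2005-12-01"))  # first window day
  # bottom never reaching the band means no detection
  s$do_bottom <- 9.5
  expect_false(observed_turnover_criterion(s)$detected)
  # brute-force equivalence on a crossing series
  s$do_bottom <- seq(8, 11, length.out = n)
  oc2 <- observed_turnover_criterion(s)
  first <- dates[which(s$do_surface >= 10 & s$do_surface <= 11 &
                         s$do_bottom >= 10 & s$do_bottom <= 11 &
                         dates >= as.Date("2005-12-01"))[1]]
  expect_equal(oc2$date, first)
})
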