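# window of candidate turnover days for detection year `year`:
# window_start (in the preceding December) through window_end of `year`
turnover_window <- function(year, window_start = "12-01",
                            window_end = "04-30") {
  seq(as.Date(sprintf("%d-%s", year - 1, window_start)),
      as.Date(sprintf("%d-%s", year, window_end)), by = "day")
}

# reindex a series to consecutive days, filling gaps of at most `max_gap`
# days by linear interpolation; longer gaps are a data error
fill_series <- function(dates, values, target_dates, max_gap = 7) {
  have <- !is.na(values)
  dates <- dates[have]; values <- values[have]
  if (length(dates) < 2) stop("insufficient coverage for interpolation")
  dn <- as.numeric(dates)
  gaps <- diff(sort(dn))
  if (any(gaps > max_gap))
    stop("data error: series has a gap of ", max(gaps),
         " days (> ", max_gap, " allowed)")
  tn <- as.numeric(target_dates)
  if (min(tn) < min(dn) || max(tn) > max(dn))
    stop("data error: series does not cover the requested window")
  approx(dn, values, xout = tn)$y
}

#' Convert a turnover timing to a calendar date and back
#'
#' Timing is integer days past January 1 of the labelled year: January 1 is
#' 0, February 11 is 41, and December days of the preceding calendar year
#' are negative.  The conversion uses the real calendar, so it is lossless
#' across leap years.
#'
#' @param year labelled detection year
#' @param timing days past January 1 (may be negative)
#' @param date a `Date`
#' @return `timing_to_date`: a `Date`; `date_to_timing`: an integer
#' @export
timing_to_date <- function(year, timing) {
  as.Date(sprintf("%d-01-01", year)) + timing
}

#' @rdname timing_to_date
#' @export
date_to_timing <- function(date, year) {
  as.integer(as.Date(date) - as.Date(sprintf("%d-01-01", year)))
}

#' Detect winter turnover timing from surface and bottom series
#'
#' The turnover date of a year is the first day in the search window
#' (default December 1 of the previous year through April 30) on which the
#' surface-bottom differences in water temperature and dissolved oxygen are
#' simultaneously below the thresholds (defaults 0.5 degC and 0.1 mg/L).
#' Timing is reported as days past January 1 of the labelled year (December
#' detections are negative).  A year with no qualifying day is flagged as a
#' failed turnover.  Gaps of up to 7 days are filled by linear
#' interpolation.
#'
#' @param series data.frame with columns `date`, `t_surface`, `t_bottom`,
#'   `do_surface`, `do_bottom` (daily or near-daily); see
#'   [surface_bottom()] for extracting it from a simulation
#' @param years detection years to evaluate; default all years whose window
#'   the series covers
#' @param t_thresh temperature-difference threshold (degC)
#' @param do_thresh DO-difference threshold (mg/L)
#' @param window_start,window_end month-day strings delimiting the search
#'   window (start is in the preceding December)
#' @return data.frame (year, timing, failed, delta_t, delta_do); `timing`
#'   is NA when `failed`
#' @export
detect_turnover <- function(series, years = NULL, t_thresh = 0.5,
                            do_thresh = 0.1, window_start = "12-01",
                            window_end = "04-30") {
  need <- c("date", "t_surface", "t_bottom", "do_surface", "do_bottom")
  if (!all(need %in% names(series)))
    stop("series is missing columns: ",
         paste(setdiff(need, names(series)), collapse = ", "))
  series$date <- as.Date(series$date)
  if (is.null(years)) {
    yr_all <- as.integer(format(series$date, "%Y"))
    cand <- seq(min(yr_all), max(yr_all) + 1)
    years <- Filter(function(y) {
      w <- turnover_window(y, window_start, window_end)
      min(w) >= min(series$date) && max(w) <= max(series$date)
    }, cand)
    if (length(years) == 0)
      stop("data error: series covers no complete detection window")
  }
  out <- lapply(years, function(y) {
    w <- turnover_window(y, window_start, window_end)
    ts <- fill_series(series$date, series$t_surface, w)
    tb <- fill_series(series$date, series$t_bottom, w)
    os <- fill_series(series$date, series$do_surface, w)
    ob <- fill_series(series$date, series$do_bottom, w)
    dts <- abs(ts - tb); dos <- abs(os - ob)
    hit <- which(dts < t_thresh & dos < do_thresh)
    if (length(hit) == 0) {
      data.frame(year = y, timing = NA_integer_, failed = TRUE,
                 delta_t = NA_real_, delta_do = NA_real_)
    } else {
      i <- hit[1]
      data.frame(year = y, timing = date_to_timing(w[i], y), failed = FALSE,
                 delta_t = dts[i], delta_do = dos[i])
    }
  })
  res <- do.call(rbind, out)
  attr(res, "thresholds") <- c(t = t_thresh, do = do_thresh)
  attr(res, "window") <- c(start = window_start, end = window_end)
  res
}

#' Classify the bottom temperature-oxygen trajectory of a winter
#'
#' Secondary turnover diagnostic based on the shape of the bottom-water
#' temperature versus DO trajectory: a turnover shows as a turning point --
#' a day from which, within `span` days, bottom temperature drops by at
#' least `t_drop` while bottom DO rises by at least `do_rise` (cold,
#' oxygen-rich surface water arriving at depth); otherwise the trajectory is
#' a relatively straight line and the winter is classified as a failed
#' turnover.  The default magnitudes reflect the deep-water renewal
#' signature of a gradually eroding one-dimensional column: a sharp oxygen
#' replenishment accompanied by a modest simultaneous cooling.
#'
#' @param series data.frame with `date`, `t_bottom`, `do_bottom`
#' @param years detection years; default as in [detect_turnover()]
#' @param t_drop minimum bottom-temperature drop (degC)
#' @param do_rise minimum bottom-DO rise (mg/L)
#' @param span number of days within which both changes must occur
#' @param window_start,window_end search window as in [detect_turnover()]
#' @return data.frame (year, shape, turning_timing); shape is
#'   "turnover-like" or "straight-line"
#' @export
curve_shape <- function(series, years = NULL, t_drop = 0.1, do_rise = 0.5,
                        span = 10, window_start = "12-01",
                        window_end = "04-30") {
  need <- c("date", "t_bottom", "do_bottom")
  if (!all(need %in% names(series)))
    stop("series is missing columns: ",
         paste(setdiff(need, names(series)), collapse = ", "))
  series$date <- as.Date(series$date)
  if (is.null(years)) {
    yr_all <- as.integer(format(series$date, "%Y"))
    cand <- seq(min(yr_all), max(yr_all) + 1)
    years <- Filter(function(y) {
      w <- turnover_window(y, window_start, window_end)
      min(w) >= min(series$date) && max(w) <= max(series$date)
    }, cand)
  }
  out <- lapply(years, function(y) {
    w <- turnover_window(y, window_start, window_end)
    tb <- fill_series(series$date, series$t_bottom, w)
    ob <- fill_series(series$date, series$do_bottom, w)
    nd <- length(w)
    turn <- NA_integer_
    for (d in seq_len(nd - 1)) {
      ks <- seq(d + 1, min(d + span, nd))
      if (any(tb[ks] - tb[d] <= -t_drop & ob[ks] - ob[d] >= do_rise)) {
        turn <- date_to_timing(w[d], y)
        break
      }
    }
    data.frame(year = y,
               shape = if (is.na(turn)) "straight-line" else "turnover-like",
               turning_timing = turn)
  })
  do.call(rbind, out)
}

#' Root-mean-square error and normalized RMSE
#'
#' Validation metrics between an observed and a modelled series: RMSE in
#' the units of the variable and NRMSE = RMSE divided by the observed range.
#' Series may be plain numeric vectors of equal length, or data.frames with
#' `date` and `value` columns, in which case pairs are matched by nearest
#' timestamp within `tolerance_days`.
#'
#' @param obs,model numeric vectors or data.frames (date, value)
#' @param variable label stored in the result
#' @param tolerance_days maximum date distance for a matched pair
#' @return data.frame (variable, n, rmse, nrmse); `nrmse` is NA with a
#'   warning when the observed range is zero
#' @export
#' @examples
#' rmse_nrmse(c(1, 2, 3), c(2, 3, 4)) # rmse 1, nrmse 0.5
rmse_nrmse <- function(obs, model, variable = "value",
                       tolerance_days = 3) {
  if (is.data.frame(obs)) {
    stopifnot(is.data.frame(model),
              all(c("date", "value") %in% names(obs)),
              all(c("date", "value") %in% names(model)))
    od <- as.numeric(as.Date(obs$date)); md <- as.numeric(as.Date(model$date))
    idx <- vapply(od, function(d) {
      j <- which.min(abs(md - d))
      if (abs(md[j] - d) <= tolerance_days) j else NA_integer_
    }, integer(1))
    keep <- !is.na(idx) & !is.na(obs$value)
    o <- obs$value[keep]; m <- model$value[idx[keep]]
  } else {
    stopifnot(length(obs) == length(model))
    keep <- !is.na(obs) & !is.na(model)
    o <- obs[keep]; m <- model[keep]
  }
  if (length(o) < 2) stop("need at least 2 matched pairs")
  rmse <- sqrt(mean((o - m)^2))
  rng <- max(o) - min(o)
  if (rng == 0) {
    warning("observed range is zero; NRMSE undefined")
    nrmse <- NA_real_
  } else nrmse <- rmse / rng
  data.frame(variable = variable, n = length(o), rmse = rmse, nrmse = nrmse)
}

#' Annual minimum bottom dissolved oxygen
#'
#' The hypoxia index: the minimum of the daily bottom-layer DO in each
#' complete calendar year, with the day of occurrence (first occurrence on
#' ties).  Partial years are excluded with a warning.
#'
#' @param x a `lake_sim` or a data.frame with `date` and `do_bottom`
#' @return data.frame (year, min_do, day); `day` is the 1-based day of year
#' @export
annual_hypoxia_index <- function(x) {
  if (inherits(x, "lake_sim"))
    x <- data.frame(date = x$date, do_bottom = x$bottom$do)
  stopifnot(all(c("date", "do_bottom") %in% names(x)))
  x$date <- as.Date(x$date)
  yr <- as.integer(format(x$date, "%Y"))
  out <- lapply(unique(yr), function(y) {
    i <- which(yr == y)
    ylen <- as.integer(as.Date(sprintf("%d-12-31", y)) -
                         as.Date(sprintf("%d-01-01", y))) + 1
    if (length(i) < ylen) return(NULL)
    j <- i[which.min(x$do_bottom[i])]
    data.frame(year = y, min_do = x$do_bottom[j],
               day = as.integer(format(x$date[j], "%j")))
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " partial year(s) excluded from the hypoxia index")
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no complete calendar year in the series")
  res
}

#' Observation-style turnover criterion from DO alone
#'
#' Emulates the monitoring-based turnover judgement: the first date in each
#' cold season on which the surface and bottom DO concentrations are both
#' within a band (default 10-11 mg/L).  Used to cross-validate
#' [detect_turnover()] against observation-style series.
#'
#' @param series data.frame with `date`, `do_surface`, `do_bottom`
#'   (weekly or finer)
#' @param lo,hi band limits (mg/L)
#' @param years detection years; default as in [detect_turnover()]
#' @param window_start,window_end search window
#' @return data.frame (year, detected, date, timing)
#' @export
observed_turnover_criterion <- function(series, lo = 10, hi = 11,
                                        years = NULL,
                                        window_start = "12-01",
                                        window_end = "04-30") {
  need <- c("date", "do_surface", "do_bottom")
  if (!all(need %in% names(series)))
    stop("series is missing columns: ",
         paste(setdiff(need, names(series)), collapse = ", "))
  series$date <- as.Date(series$date)
  if (is.null(years)) {
    yr_all <- as.integer(format(series$date, "%Y"))
    cand <- seq(min(yr_all), max(yr_all) + 1)
    years <- Filter(function(y) {
      w <- turnover_window(y, window_start, window_end)
      min(w) >= min(series$date) && max(w) <= max(series$date)
    }, cand)
  }
  out <- lapply(years, function(y) {
    w <- turnover_window(y, window_start, window_end)
    os <- fill_series(series$date, series$do_surface, w)
    ob <- fill_series(series$date, series$do_bottom, w)
    hit <- which(os >= lo & os <= hi & ob >= lo & ob <= hi)
    if (length(hit) == 0) {
      data.frame(year = y, detected = FALSE, date = as.Date(NA),
                 timing = NA_integer_)
    } else {
      data.frame(year = y, detected = TRUE, date = w[hit[1]],
                 timing = date_to_timing(w[hit[1]], y))
    }
  })
  do.call(rbind, out)
}
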