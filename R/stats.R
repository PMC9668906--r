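#' Build the per-year predictor table for turnover-driver analysis
#'
#' One row per detection year with the candidate drivers of turnover
#' timing: air temperature (AT, degC), precipitation (pptn, mm/day), cloud
#' cover (CC, fraction), wind speed (WS, m/s, station values before the
#' land-to-lake correction), the bottom-minus-surface density difference
#' (DD, kg/m3) and the surface POC concentration (POC, mgC/m3) from the
#' simulation, plus the turnover timing response.  Aggregation is either
#' over the cold season (November 1 of the previous year through April 30)
#' or over the calendar year.  Failed-turnover years keep their predictor
#' row but carry an NA response and are flagged.
#'
#' @param sim a `lake_sim`
#' @param meteo the forcing series that drove `sim`
#' @param turnover output of [detect_turnover()] on the run
#' @param mode "cold_season" (default) or "annual"
#' @return data.frame (year, AT, pptn, CC, DD, POC, WS, timing, failed)
#' @export
aggregate_predictors <- function(sim, meteo, turnover,
                                 mode = c("cold_season", "annual")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sim, "lake_sim"))
  md <- as.Date(meteo$date)
  sd <- as.Date(sim$date)
  n <- length(sim$z_mid)
  dd_series <- sim$density[, n] - sim$density[, 1]
  poc_series <- sim$poc[, 1]

  rows <- lapply(turnover$year, function(y) {
    if (mode == "cold_season") {
      from <- as.Date(sprintf("%d-11-01", y - 1))
      to <- as.Date(sprintf("%d-04-30", y))
    } else {
      from <- as.Date(sprintf("%d-01-01", y))
      to <- as.Date(sprintf("%d-12-31", y))
    }
    im <- md >= from & md <= to
    is <- sd >= from & sd <= to
    if (!any(im) || !any(is)) return(NULL)
    # incomplete aggregation season: drop the row
    span <- as.integer(to - from) + 1
    if (sum(im) < span || sum(is) < span) {
      warning("year ", y, " dropped: incomplete ", mode, " coverage")
      return(NULL)
    }
    data.frame(year = y,
               AT = mean(meteo$air_temp_c[im]),
               pptn = mean(meteo$precip_mm[im]),
               CC = mean(meteo$cloud_frac[im]),
               DD = mean(dd_series[is]),
               POC = mean(poc_series[is]),
               WS = mean(meteo$wind_ms[im]),
               timing = turnover$timing[turnover$year == y],
               failed = turnover$failed[turnover$year == y])
  })
  res <- do.call(rbind, rows)
  if (!is.null(res)) attr(res, "mode") <- mode
  res
}

#' Random-forest variable importance for turnover timing
#'
#' Fits a bagged regression-tree ensemble of the turnover timing on the
#' predictor table and reports, per predictor, the out-of-bag permutation
#' importance (percentage increase in mean squared error) and the total
#' node-purity (residual-sum-of-squares) decrease, plus the out-of-bag
#' variance explained.  Failed-turnover years (NA response) are excluded.
#' Fixed seed makes the ensemble reproducible.
#'
#' @param table predictor table from [aggregate_predictors()], or any
#'   data.frame with predictor columns and a `timing` response
#' @param n_trees number of trees
#' @param seed integer seed
#' @param predictors predictor column names (default the six standard ones
#'   that are present)
#' @return list of class `importance_table`: `importance` (data.frame
#'   predictor, pct_inc_mse, node_purity), `var_explained` (percent,
#'   out-of-bag), `n`, `n_trees`, `seed`
#' @export
forest_importance <- function(table, n_trees = 500, seed = 1,
                              predictors = NULL) {
  if (is.null(predictors))
    predictors <- intersect(c("AT", "pptn", "CC", "DD", "POC", "WS"),
                            names(table))
  if (length(predictors) < 2)
    stop("statistical error: need at least 2 predictors")
  keep <- !is.na(table$timing)
  x <- table[keep, predictors, drop = FALSE]
  y <- table$timing[keep]
  if (nrow(x) < 8)
    stop("statistical error: need at least 8 modelling rows, have ", nrow(x))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE, keep.forest = FALSE)
  imp <- randomForest::importance(rf)
  res <- list(
    importance = data.frame(predictor = rownames(imp),
                            pct_inc_mse = imp[, "%IncMSE"],
                            node_purity = imp[, "IncNodePurity"],
                            row.names = NULL),
    var_explained = 100 * rf$rsq[n_trees],
    n = nrow(x), n_trees = n_trees, seed = seed)
  class(res) <- "importance_table"
  res
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf(
    "<importance_table> %d rows, %d trees, OOB variance explained %.2f%%\n",
    x$n, x$n_trees, x$var_explained))
  print(x$importance[order(-x$importance$pct_inc_mse), ], row.names = FALSE)
  invisible(x)
}

#' Ordinary least-squares fit with confidence interval
#'
#' Simple linear regression y = a + b x with R-squared, the 95 percent
#' confidence interval of the slope (t-distribution), and the residual
#' standard deviation.
#'
#' @param x,y numeric vectors (NA pairs dropped), n >= 3
#' @return list of class `lake_regression`: slope, intercept, r2, n,
#'   ci_lo, ci_hi, residual_sd
#' @export
#' @examples
#' linear_fit(1:10, 2 * (1:10) + 1)$slope # 2
linear_fit <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("statistical error: need n >= 3 finite pairs")
  if (sd(x) == 0) stop("singular fit: zero variance in x")
  fit <- lm(y ~ x)
  ci <- confint(fit, "x", level = 0.95)
  s <- summary(fit)
  res <- list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
              r2 = s$r.squared, n = length(x),
              ci_lo = ci[1], ci_hi = ci[2], residual_sd = s$sigma)
  class(res) <- "lake_regression"
  res
}

#' @export
print.lake_regression <- function(x, ...) {
  cat(sprintf(
    "<lake_regression> slope %.4g [%.4g, %.4g], intercept %.4g, R2 %.3f, n %d\n",
    x$slope, x$ci_lo, x$ci_hi, x$intercept, x$r2, x$n))
  invisible(x)
}

#' Period-split linear regressions
#'
#' Fits [linear_fit()] independently on the years up to and including
#' `split_year` ("before") and the years after it ("after"), the standard
#' device for separating an eutrophication era from a climate-dominated
#' era.
#'
#' @param x,y numeric vectors, one value per year
#' @param years calendar year of each observation
#' @param split_year boundary year, assigned to the "before" period
#' @return list with elements `before` and `after`, each a
#'   `lake_regression`
#' @export
period_split_fit <- function(x, y, years, split_year = 1980) {
  stopifnot(length(x) == length(y), length(x) == length(years))
  i <- years <= split_year
  if (sum(i) < 3 || sum(!i) < 3)
    stop("statistical error: each period needs at least 3 years (have ",
         sum(i), " / ", sum(!i), ")")
  list(before = linear_fit(x[i], y[i]), after = linear_fit(x[!i], y[!i]))
}
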