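# registered CSV schemas: column names and types
csv_schemas <- list(
  forcing = c(date = "Date", air_temp_c = "numeric", wind_ms = "numeric",
              cloud_frac = "numeric", precip_mm = "numeric",
              shortwave_wm2 = "numeric"),
  loading = c(year = "integer", tn_load = "numeric", tp_load = "numeric"),
  monitoring = c(date = "Date", depth_m = "numeric", temp_c = "numeric",
                 do_mgl = "numeric"),
  turnover = c(year = "integer", timing_days = "integer",
               failed = "logical", delta_t = "numeric", delta_do = "numeric")
)

#' Read a typed series CSV against a registered schema
#'
#' Headers must match the schema exactly; a mismatch raises a format error
#' naming the missing and extra columns.  Dates must be ISO-8601; a cell
#' that fails to parse raises an error with its line number.  Only an
#' explicitly empty cell becomes NA.
#'
#' @param path file path
#' @param schema one of `"forcing"`, `"loading"`, `"monitoring"`,
#'   `"turnover"`
#' @return a data.frame with typed columns
#' @export
read_series_csv <- function(path, schema = c("forcing", "loading",
                                             "monitoring", "turnover")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- csv_schemas[[schema]]
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(names(spec), names(raw))
  extra <- setdiff(names(raw), names(spec))
  if (length(missing) || length(extra))
    stop("format error in ", path, ": expected columns {",
         paste(names(spec), collapse = ", "), "}; missing {",
         paste(missing, collapse = ", "), "}; unexpected {",
         paste(extra, collapse = ", "), "}")
  out <- raw
  for (col in names(spec)) {
    v <- raw[[col]]
    empty <- !nzchar(v)
    parsed <- switch(spec[[col]],
      Date = as.Date(v, format = "%Y-%m-%d"),
      numeric = suppressWarnings(as.numeric(v)),
      integer = suppressWarnings(as.integer(v)),
      logical = as.logical(v))
    bad <- which(is.na(parsed) & !empty)
    if (length(bad))
      stop("unparseable ", spec[[col]], " in column '", col, "' of ", path,
           " at line ", bad[1] + 1) # +1 for the header line
    parsed[empty] <- NA
    out[[col]] <- parsed
  }
  out
}

#' Write a forcing series CSV
#'
#' Schema: `date,air_temp_c,wind_ms,cloud_frac,precip_mm,shortwave_wm2`,
#' ISO dates, one row per day.  Round-trips losslessly through
#' [read_series_csv()] at full double precision.
#'
#' @param meteo a forcing data.frame from [generate_meteo()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_forcing_csv <- function(meteo, path) {
  stopifnot(all(names(csv_schemas$forcing) %in% names(meteo)))
  out <- meteo[names(csv_schemas$forcing)]
  out$date <- format(out$date, "%Y-%m-%d")
  for (col in names(out)[-1]) out[[col]] <- format(out[[col]], digits = 17)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a turnover record CSV
#'
#' Schema: `year,timing_days,failed,delta_t,delta_do`.
#'
#' @param turnover output of [detect_turnover()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_turnover_csv <- function(turnover, path) {
  out <- data.frame(year = turnover$year, timing_days = turnover$timing,
                    failed = turnover$failed, delta_t = turnover$delta_t,
                    delta_do = turnover$delta_do)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation archive as long-format CSV
#'
#' Schema: `time,depth_m,var,value`, one row per day, layer, and variable.
#' The header comment line carries the run's config hash and package
#' version so outputs are traceable to their configuration.
#'
#' @param sim a `lake_sim`
#' @param path output path
#' @param vars variables to write
#' @return `path`, invisibly
#' @export
write_sim_csv <- function(sim, path, vars = c("temp", "do", "phy", "din",
                                              "dip", "poc")) {
  stopifnot(inherits(sim, "lake_sim"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# monomict %s config_hash %s",
                     sim$meta$version, sim$meta$hash), con)
  nd <- length(sim$date); nl <- length(sim$z_mid)
  blocks <- lapply(vars, function(v) {
    m <- sim[[v]]
    data.frame(time = rep(format(sim$date), nl),
               depth_m = rep(sim$z_mid, each = nd),
               var = v, value = as.vector(m))
  })
  write.csv(do.call(rbind, blocks), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Extract surface and bottom series from long-format monitoring data
#'
#' Takes a monitoring table (`date,depth_m,temp_c,do_mgl`) and returns the
#' shallowest depth as the surface and the deepest as the bottom, in the
#' series layout expected by [detect_turnover()] and [rmse_nrmse()].
#'
#' @param monitoring data.frame from
#'   `read_series_csv(path, "monitoring")`
#' @return data.frame (date, t_surface, t_bottom, do_surface, do_bottom)
#' @export
monitoring_to_series <- function(monitoring) {
  stopifnot(all(c("date", "depth_m", "temp_c", "do_mgl") %in%
                  names(monitoring)))
  zs <- min(monitoring$depth_m); zb <- max(monitoring$depth_m)
  if (zs == zb) stop("monitoring data has a single depth")
  s <- monitoring[monitoring$depth_m == zs, ]
  b <- monitoring[monitoring$depth_m == zb, ]
  m <- merge(s[, c("date", "temp_c", "do_mgl")],
             b[, c("date", "temp_c", "do_mgl")],
             by = "date", suffixes = c("_s", "_b"))
  data.frame(date = m$date, t_surface = m$temp_c_s, t_bottom = m$temp_c_b,
             do_surface = m$do_mgl_s, do_bottom = m$do_mgl_b)
}
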