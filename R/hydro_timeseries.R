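#' Hourly water-table series
#'
#' Levels are metres relative to the ground surface: negative below ground,
#' positive ponded above. Timestamps must be strictly increasing; the
#' nominal cadence is hourly, with gaps permitted (statistics are computed
#' over the available records without imputation).
#'
#' @param timestamps `POSIXct` vector (UTC recommended).
#' @param level_m Numeric levels (m relative to ground).
#' @param well_id Optional identifier.
#' @return A `wt_series` data.frame with columns `timestamp`, `level_m`.
#' @export
water_table_series <- function(timestamps, level_m, well_id = NA_character_) {
  if (!inherits(timestamps, "POSIXct"))
    stop("`timestamps` must be POSIXct")
  if (length(timestamps) != length(level_m))
    stop("timestamps and levels differ in length")
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  structure(data.frame(timestamp = timestamps, level_m = as.numeric(level_m)),
            well_id = well_id, class = c("wt_series", "data.frame"))
}

#' Read well logger CSVs
#'
#' Expected columns: `well_id`, `timestamp` (ISO 8601), `level_m`.
#'
#' @param path CSV path.
#' @param tz Timezone for parsing (default UTC).
#' @return Named list of `wt_series`, one per well.
#' @export
read_well_csv <- function(path, tz = "UTC") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well_id", "timestamp", "level_m")
  if (!all(need %in% names(df)))
    stop("well CSV must have columns: ", paste(need, collapse = ", "))
  ts <- as.POSIXct(df$timestamp, tz = tz,
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  out <- lapply(split(seq_len(nrow(df)), df$well_id), function(i) {
    o <- order(ts[i])
    water_table_series(ts[i][o], df$level_m[i][o], well_id = df$well_id[i][1])
  })
  out
}

#' Seasonal subset of a water-table series
#'
#' Summer is April through September (the period of significant water-table
#' drawdown on these bogs); winter is January-March plus October-December
#' of the same calendar year.
#'
#' @param series A `wt_series`.
#' @param year Calendar year.
#' @param season `"summer"` or `"winter"`.
#' @return A `wt_series` (possibly with zero rows).
#' @export
seasonal_subset <- function(series, year, season = c("summer", "winter")) {
  season <- match.arg(season)
  if (nrow(series) == 0L) stop("empty series")
  lt <- as.POSIXlt(series$timestamp)
  yr <- lt$year + 1900L
  mo <- lt$mon + 1L
  keep <- yr == year & if (season == "summer") mo %in% 4:9 else mo %in% c(1:3, 10:12)
  out <- series[keep, , drop = FALSE]
  attr(out, "well_id") <- attr(series, "well_id")
  class(out) <- class(series)
  out
}

#' Water-table exceedance statistics
#'
#' Duration-curve statistics of a level series. `Dp` is the level equalled
#' or exceeded (i.e. the water table at least as shallow) for p% of the
#' monitoring period, so D90 is the 10th percentile of levels, D10 the
#' 90th, D1 the 99th and D99 the 1st; `fluctuation = D1 - D99` measures the
#' range of water-table movement. Quantiles use the linear-interpolation
#' convention (R type 7).
#'
#' @param series A `wt_series` (any season subset).
#' @param min_obs Minimum number of observations required (default 100);
#'   shorter records are refused rather than summarised.
#' @return A `wt_stats` list: `d90`, `d10`, `median`, `d1`, `d99`,
#'   `fluctuation`, `n`.
#' @export
exceedance_stats <- function(series, min_obs = 100) {
  lev <- series$level_m[!is.na(series$level_m)]
  if (length(lev) < min_obs)
    stop(sprintf("only %d observations (< %d); refusing to compute statistics",
                 length(lev), min_obs))
  q <- stats::quantile(lev, c(0.01, 0.10, 0.50, 0.90, 0.99),
                       names = FALSE, type = 7)
  structure(list(d99 = q[1], d90 = q[2], median = q[3], d10 = q[4], d1 = q[5],
                 fluctuation = q[5] - q[1], n = length(lev)),
            class = "wt_stats")
}

#' @export
print.wt_stats <- function(x, ...) {
  cat(sprintf("D90 %.2f m | median %.2f m | D10 %.2f m | D1-D99 %.2f m (n = %d)\n",
              x$d90, x$median, x$d10, x$fluctuation, x$n))
  invisible(x)
}

#' Summarise daily meteorological forcing
#'
#' Seasonal and annual totals of precipitation and potential
#' evapotranspiration for one calendar year, plus rain-day (>= 1 mm) and
#' wet-day (>= 5 mm) counts and the percentage of the annual total falling
#' in each season. Summer is April-September, winter January-March plus
#' October-December. Missing days are tolerated (sums run over available
#' records).
#'
#' @param met data.frame with columns `date` (Date or parseable),
#'   `precip_mm` and optionally `pe_mm`.
#' @param year Calendar year.
#' @return A `met_summary` data.frame: one row per variable with `summer`,
#'   `winter`, `annual`, `prop_summer_pct`, `prop_winter_pct` (proportions
#'   rounded to integer for display parity with field reports).
#' @export
met_summary <- function(met, year) {
  if (!inherits(met$date, "Date")) met$date <- as.Date(met$date)
  met <- met[as.integer(format(met$date, "%Y")) == year, , drop = FALSE]
  if (nrow(met) == 0L) stop("no records for year ", year)
  mo <- as.integer(format(met$date, "%m"))
  summer <- mo %in% 4:9
  row_for <- function(name, x, counting = FALSE) {
    s <- sum(x[summer], na.rm = TRUE)
    w <- sum(x[!summer], na.rm = TRUE)
    a <- s + w
    data.frame(variable = name, summer = s, winter = w, annual = a,
               prop_summer_pct = ifelse(a > 0, round(100 * s / a), NA),
               prop_winter_pct = ifelse(a > 0, round(100 * w / a), NA))
  }
  out <- row_for("precip_mm", met$precip_mm)
  if (!is.null(met$pe_mm) && any(!is.na(met$pe_mm)))
    out <- rbind(out, row_for("pe_mm", met$pe_mm))
  out <- rbind(out,
               row_for("rain_days", as.numeric(met$precip_mm >= 1)),
               row_for("wet_days", as.numeric(met$precip_mm >= 5)))
  class(out) <- c("met_summary", "data.frame")
  out
}

#' Seasonal proportion from seasonal totals
#'
#' Display-rounded percentage of the annual total occurring in summer,
#' as tabulated in site meteorological summaries.
#'
#' @param summer_total,winter_total Seasonal totals (same units).
#' @return Integer percentage.
#' @export
seasonal_proportion_pct <- function(summer_total, winter_total) {
  round(100 * summer_total / (summer_total + winter_total))
}

#' Horizontal hydraulic gradient from a well triad
#'
#' Wells at each monitoring nest are arranged in an approximately
#' equilateral triangle; fitting the plane through their three heads gives
#' the local horizontal hydraulic gradient magnitude (dimensionless, m/m).
#'
#' @param x,y Well coordinates (m), length 3.
#' @param head_m Hydraulic heads (m AMSL), length 3.
#' @return Gradient magnitude `|grad h|`.
#' @export
horizontal_gradient <- function(x, y, head_m) {
  stopifnot(length(x) == 3, length(y) == 3, length(head_m) == 3)
  M <- cbind(1, x, y)
  if (abs(det(M)) < 1e-12 * (max(abs(c(x, y))) + 1)^2)
    stop("well positions are collinear; no unique plane")
  coef <- solve(M, head_m)
  unname(sqrt(coef[2]^2 + coef[3]^2))
}

#' Vertical hydraulic gradient
#'
#' `(head_shallow - head_deep) / separation`; positive values indicate a
#' downward gradient (recharge), negative an upward gradient (discharge).
#'
#' @param head_shallow_m Head in the water-table well (m AMSL).
#' @param head_deep_m Head in the basal piezometer (m AMSL).
#' @param separation_m Vertical distance between screen mid-depths (m, > 0).
#' @return Dimensionless gradient.
#' @export
vertical_gradient <- function(head_shallow_m, head_deep_m, separation_m) {
  if (separation_m <= 0) stop("`separation_m` must be positive")
  (head_shallow_m - head_deep_m) / separation_m
}

#' Barometric compensation of logger pressure
#'
#' Plumbing helper converting absolute transducer pressure to water level:
#' the water column above the sensor is `(p_total - p_baro) / (rho * g)`,
#' and the level relative to ground is that column minus the sensor's cable
#' depth below ground. Uses the freshwater density 1000 kg/m^3.
#'
#' @param p_total_kpa Absolute pressure at the sensor (kPa).
#' @param p_baro_kpa Barometric pressure (kPa).
#' @param cable_depth_m Sensor depth below ground surface (m).
#' @return Water level in m relative to ground (negative below ground).
#' @export
compensate_level <- function(p_total_kpa, p_baro_kpa, cable_depth_m) {
  column_m <- (p_total_kpa - p_baro_kpa) * 1000 / (1000 * 9.80665)
  column_m - cable_depth_m
}
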