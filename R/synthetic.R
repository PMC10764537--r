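# run code with a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic blanket-bog DEM
#'
#' Parameterises the terrain forms the analysis expects on a blanket bog:
#' one or more flat-topped plateaus with sloping aprons, a regional tilt
#' draining towards the eastern edge, an optional incised channel, optional
#' shallow artificial drains (0.5-0.75 m deep is typical of historical
#' ditching), and microtopographic noise.
#'
#' @param nrow,ncol Grid extent in cells.
#' @param cell_size Cell size in metres (default 1).
#' @param base_elev_m Elevation at the western edge before tilt (m).
#' @param tilt_m_per_km Regional eastward downhill tilt (m/km).
#' @param plateaus List of `list(row, col, radius_m, height_m,
#'   apron_m)`: a near-flat disc of extra elevation with a linear apron.
#'   Discs are weakly domed at `dome_m_per_km` (real bog plateaus are
#'   gently convex, not perfectly flat); set it to 0 for a constant disc.
#' @param dome_m_per_km Radial gradient of plateau tops (m/km, default 2).
#' @param channel Optional `list(row, depth_m, width_m)`: a west-east
#'   channel incised along a grid row.
#' @param drains Optional list of `list(row1, col1, row2, col2, depth_m)`
#'   straight drain segments carved into the surface.
#' @param noise_amp_m Standard deviation of microtopographic noise (m).
#' @param seed RNG seed; the DEM is reproducible from it.
#' @return A `bog_dem_spec` list.
#' @export
bog_dem_spec <- function(nrow = 80, ncol = 100, cell_size = 1,
                         base_elev_m = 150, tilt_m_per_km = 20,
                         plateaus = list(list(row = 40, col = 30,
                                              radius_m = 18, height_m = 2,
                                              apron_m = 15)),
                         dome_m_per_km = 6, channel = NULL, drains = NULL,
                         noise_amp_m = 0.02, seed = 1) {
  if (nrow < 3 || ncol < 3) stop("degenerate extent")
  structure(list(nrow = nrow, ncol = ncol, cell_size = cell_size,
                 base_elev_m = base_elev_m, tilt_m_per_km = tilt_m_per_km,
                 plateaus = plateaus, dome_m_per_km = dome_m_per_km,
                 channel = channel, drains = drains,
                 noise_amp_m = noise_amp_m, seed = seed),
            class = "bog_dem_spec")
}

#' Generate a synthetic blanket-bog DEM
#'
#' Deterministic given the spec's seed. The regional tilt guarantees at
#' least one outlet on the (lower) eastern edge.
#'
#' @param spec A [bog_dem_spec()].
#' @return A `raster_grid` of elevations (m).
#' @export
generate_bog_dem <- function(spec) {
  stopifnot(inherits(spec, "bog_dem_spec"))
  nr <- spec$nrow; nc <- spec$ncol; cs <- spec$cell_size
  col_x <- (seq_len(nc) - 0.5) * cs
  z <- matrix(rep(spec$base_elev_m - spec$tilt_m_per_km / 1000 * col_x,
                  each = nr), nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (p in spec$plateaus) {
    r <- sqrt(((rows - p$row) * cs)^2 + ((cols - p$col) * cs)^2)
    apron <- if (is.null(p$apron_m)) 15 else p$apron_m
    prof <- pmin(1, pmax(0, 1 - (r - p$radius_m) / apron))
    z <- z + p$height_m * prof +
      spec$dome_m_per_km / 1000 * pmax(0, p$radius_m - r)
  }
  if (!is.null(spec$channel)) {
    ch <- spec$channel
    dist_m <- abs(rows - ch$row) * cs
    z <- z - ch$depth_m * exp(-(dist_m / ch$width_m)^2)
  }
  if (!is.null(spec$drains)) {
    for (d in spec$drains) {
      npts <- max(abs(d$row2 - d$row1), abs(d$col2 - d$col1)) + 1L
      rr <- round(seq(d$row1, d$row2, length.out = npts))
      cc <- round(seq(d$col1, d$col2, length.out = npts))
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      z[cbind(rr[ok], cc[ok])] <- z[cbind(rr[ok], cc[ok])] - d$depth_m
    }
  }
  if (spec$noise_amp_m > 0) {
    z <- z + .with_seed(spec$seed,
                        matrix(stats::rnorm(nr * nc, sd = spec$noise_amp_m), nr, nc))
  }
  raster_grid(z, cs, units = "m elevation")
}

#' Generate daily meteorological forcing
#'
#' Daily precipitation and potential evapotranspiration with the seasonal
#' structure observed at the study sites: wetter winters (occurrence and
#' intensity both higher October-March) and roughly 80% of annual PE
#' falling in the April-September summer. Annual totals are normalised to
#' the requested values (within 1% by construction; the normalisation is
#' exact, noise enters only the daily pattern).
#'
#' @param seed RNG seed.
#' @param annual_precip_mm,annual_pe_mm Target annual totals (mm/yr).
#' @param years Number of calendar years to generate.
#' @param start_year First calendar year (default 2019).
#' @return data.frame with `date`, `precip_mm`, `pe_mm`.
#' @export
generate_met_series <- function(seed, annual_precip_mm, annual_pe_mm,
                                years = 1, start_year = 2019) {
  if (annual_precip_mm < 0 || annual_pe_mm <= 0)
    stop("annual totals must be positive (precipitation may be zero)")
  .with_seed(seed, {
    out <- lapply(seq_len(years) - 1L, function(k) {
      yr <- start_year + k
      dates <- seq(as.Date(sprintf("%d-01-01", yr)),
                   as.Date(sprintf("%d-12-31", yr)), by = "day")
      doy <- as.integer(format(dates, "%j"))
      nd <- length(dates)
      # precipitation: seasonal occurrence (~60% winter, ~45% summer) and
      # winter-weighted intensity, then exact normalisation to the target
      p_wet <- 0.62 + 0.10 * cos(2 * pi * (doy - 15) / 365.25)
      wet <- stats::runif(nd) < p_wet
      amt <- ifelse(wet,
                    stats::rgamma(nd, shape = 1.1,
                                  scale = 5 * (1 + 0.35 * cos(2 * pi * (doy - 15) / 365.25))),
                    0)
      if (annual_precip_mm == 0) {
        precip <- rep(0, nd)
      } else {
        precip <- amt * annual_precip_mm / sum(amt)
      }
      # PE: summer-peaked deterministic shape (~80% Apr-Sep) plus mild noise
      shape <- 0.12 + exp(-0.5 * ((doy - 190) / 58)^2)
      pe <- shape * exp(stats::rnorm(nd, 0, 0.10))
      pe <- pe * annual_pe_mm / sum(pe)
      data.frame(date = dates, precip_mm = precip, pe_mm = pe)
    })
    do.call(rbind, out)
  })
}

#' Specification for the water-table simulator
#'
#' Phenomenological bucket model whose single contract is the structure the
#' regression analysis assumes: the summer D90 of a simulated well at MFAC
#' `m` km has expectation `a + b * log10(m)` (metres relative to ground),
#' with well-to-well noise of standard deviation `sigma`. Recession during
#' dry spells is slower at higher MFAC (greater drawdown resilience where
#' upslope contributions persist), recharge events drive the level towards
#' the surface, and ponding is capped at a small overtopping bound.
#'
#' @param a Intercept of the D90 relation (m, default -0.35).
#' @param b Slope per log10 km (default 0.12).
#' @param sigma Well-level noise sd (m, default 0.04).
#' @param recession,recharge Dimensionless scalings of the bucket dynamics;
#'   setting both to zero yields a constant series.
#' @param overtop_m Maximum ponded level above ground (m, default 0.05).
#' @param seed RNG seed for the well-level noise; `NA` draws from the
#'   ambient RNG stream instead (useful when simulating many wells under
#'   one externally controlled seed).
#' @return A `wt_sim_spec` list.
#' @export
wt_sim_spec <- function(a = -0.35, b = 0.12, sigma = 0.04,
                        recession = 1, recharge = 1,
                        overtop_m = 0.05, seed = 1) {
  structure(list(a = a, b = b, sigma = sigma, recession = recession,
                 recharge = recharge, overtop_m = overtop_m, seed = seed),
            class = "wt_sim_spec")
}

#' Simulate an hourly water-table series for one well
#'
#' Runs a linear-reservoir bucket at hourly resolution driven by the daily
#' precipitation of `met`, with recession rate decreasing in log10(MFAC),
#' then anchors the series so that the 10th percentile of its summer
#' (April-September) deterministic component equals `a + b * log10(mfac)`
#' plus the well's noise draw. Levels are capped at the overtopping bound.
#'
#' @param mfac MFAC value of the well (km, > 0).
#' @param met data.frame from [generate_met_series()].
#' @param spec A [wt_sim_spec()].
#' @return A `wt_series` of hourly levels.
#' @export
generate_water_table_series <- function(mfac, met, spec = wt_sim_spec()) {
  stopifnot(inherits(spec, "wt_sim_spec"))
  if (mfac <= 0) stop("`mfac` must be positive")
  nh <- nrow(met) * 24L
  ts <- seq(as.POSIXct(paste(met$date[1], "00:00:00"), tz = "UTC"),
            by = 3600, length.out = nh)
  rain_h <- rep(met$precip_mm / 24, each = 24L)
  # recession rate per hour, decreasing in log10(mfac)
  rho <- 0.004 * spec$recession * mfac^(-0.4)
  gain <- 0.0035 * spec$recharge          # m of water-table rise per mm rain
  floor_m <- -0.45
  input <- gain * rain_h + rho * floor_m
  D <- as.numeric(stats::filter(input, 1 - rho, method = "recursive", init = 0))
  D <- pmin(D, 0)
  mo <- as.POSIXlt(ts)$mon + 1L
  summer <- mo %in% 4:9
  anchor <- if (any(summer)) stats::quantile(D[summer], 0.10, names = FALSE)
            else stats::quantile(D, 0.10, names = FALSE)
  eps <- if (is.na(spec$seed)) stats::rnorm(1, 0, spec$sigma)
         else .with_seed(spec$seed, stats::rnorm(1, 0, spec$sigma))
  target <- spec$a + spec$b * log10(mfac)
  level <- pmin(D - anchor + target + eps, spec$overtop_m)
  water_table_series(ts, level)
}

#' Load a bundled study summary table
#'
#' The package ships transcriptions of the summary tables from the
#' four-site blanket-bog monitoring campaign (Garron, Cuilcagh,
#' Letterunshin and Fiddandarry): site climate and stream-formation
#' thresholds, seasonal meteorological summaries, per-well water-table
#' statistics with MFAC values, the MFAC wetness class scheme, and the
#' regression residual table. Levels are printed at 2 dp (m relative to
#' ground, negative below); missing seasons (e.g. no 2020 record at
#' Cuilcagh, no 2019 logger record at wells GG and LG) are `NA`.
#'
#' @param name One of `"site_climate"`, `"met_summary"`, `"well_stats"`,
#'   `"mfac_classes"`, `"model_residuals"` (aliases `"table1"` ...
#'   `"table5"` in that order).
#' @return A data.frame.
#' @export
load_study_table <- function(name) {
  alias <- c(table1 = "site_climate", table2 = "met_summary",
             table3 = "well_stats", table4 = "mfac_classes",
             table5 = "model_residuals")
  if (name %in% names(alias)) name <- alias[[name]]
  files <- c(site_climate = "site_climate.csv", met_summary = "met_summary.csv",
             well_stats = "well_stats.csv", mfac_classes = "mfac_classes.csv",
             model_residuals = "model_residuals.csv")
  if (!name %in% names(files))
    stop("unknown table '", name, "'; expected one of: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "mfac")
  if (!nzchar(path)) stop("bundled table not found: ", files[[name]])
  utils::read.csv(path, stringsAsFactors = FALSE)
}
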