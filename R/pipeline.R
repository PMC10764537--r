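#' Pipeline configuration
#'
#' Assembles and validates the configuration for a single-site MFAC run.
#' Accepts a named list or a YAML/JSON file with the same keys.
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param ... Individual keys overriding the file/list values: `dem`
#'   (path to an ESRI ASCII DTM, or a `raster_grid`), `out_dir`,
#'   `precip_mm_yr`, `pe_mm_yr`, `reference_er_mm_yr` (default 907),
#'   `stream_threshold_ha`, `flowline_threshold_m2` (default 1000),
#'   `smoothing_window_m` (default 5), `s_min` (default 0.1), `outlet`
#'   (optional `c(row, col)`), `seed` (default 1).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  config <- utils::modifyList(config, list(...))
  defaults <- list(reference_er_mm_yr = 907, flowline_threshold_m2 = 1000,
                   smoothing_window_m = 5, s_min = 0.1, outlet = NULL, seed = 1)
  config <- utils::modifyList(defaults, config)
  for (key in c("dem", "out_dir", "precip_mm_yr", "pe_mm_yr", "stream_threshold_ha"))
    if (is.null(config[[key]])) stop("config missing required key '", key, "'")
  for (key in c("stream_threshold_ha", "flowline_threshold_m2",
                "smoothing_window_m", "s_min"))
    if (config[[key]] <= 0) stop("config key '", key, "' must be positive")
  if (is.character(config$dem) && !file.exists(config$dem))
    stop("DEM path does not exist: ", config$dem)
  structure(config, class = "pipeline_config")
}

#' Default configuration for a synthetic study site
#'
#' A ready-to-run [pipeline_config()] for the default synthetic bog of
#' [bog_dem_spec()]: a ~0.5 ha east-draining hillslope with one weakly
#' domed plateau. Climate matches a Letterunshin-like lowland bog
#' (effective rainfall 907 mm/yr, so K = 1). The thresholds are scaled to
#' the small synthetic catchment: stream formation at 0.1 ha, flowlines
#' seeded at 150 m2, and a slope floor of 2 m/km (gradients below that are
#' not resolvable on a 5 m-smoothed surface given typical LiDAR vertical
#' accuracy of +/- 0.15 m).
#'
#' @param dem A `raster_grid` or DTM path; default the seed-1 synthetic
#'   bog.
#' @param out_dir Output directory (default a fresh temporary directory).
#' @param ... Overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
synthetic_site_config <- function(dem = generate_bog_dem(bog_dem_spec()),
                                  out_dir = tempfile("mfac_site_"), ...) {
  pipeline_config(list(dem = dem, out_dir = out_dir,
                       precip_mm_yr = 1465, pe_mm_yr = 558,
                       stream_threshold_ha = 0.1,
                       flowline_threshold_m2 = 150,
                       smoothing_window_m = 5, s_min = 2), ...)
}

#' Run the MFAC pipeline for one site
#'
#' Executes the full chain DTM -> filled DEM -> D8 directions -> flow
#' accumulation -> flowlines -> 5 m flowline sampling -> natural-neighbour
#' interpolation of contributing area -> smoothed-DEM slope -> MFAC ->
#' classes -> class-area distribution, and writes the artifact bundle
#' (MFAC and class grids as ESRI ASCII, flowlines as GeoJSON, class
#' distribution CSV, and a machine-readable run manifest with input and
#' config hashes). The run is a pure function of (inputs, config): no
#' randomness is involved and reruns are byte-identical.
#'
#' Any stage failure aborts with the stage name and removes partial
#' outputs.
#'
#' @param config A [pipeline_config()] (or list/path coerced through it).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the intermediate and final objects:
#'   `dem`, `filled`, `fdir`, `facc`, `catchment`, `flowlines`, `samples`,
#'   `area_interp`, `slope`, `surface`, `distribution`, `paths`.
#' @export
run_site <- function(config, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    mfac = file.path(config$out_dir, "mfac.asc"),
    classes = file.path(config$out_dir, "mfac_classes.asc"),
    flowlines = file.path(config$out_dir, "flowlines.geojson"),
    distribution = file.path(config$out_dir, "class_distribution.csv"),
    manifest = file.path(config$out_dir, "manifest.json"))
  say <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  stage <- "setup"
  result <- tryCatch({
    stage <- "load_dem"
    dem <- if (is_raster_grid(config$dem)) config$dem
           else read_ascii_grid(config$dem, units = "m elevation")
    say(stage, "%d x %d cells @ %g m, elevation %.1f-%.1f m",
        nrow(dem$values), ncol(dem$values), dem$cell_size,
        min(dem$values, na.rm = TRUE), max(dem$values, na.rm = TRUE))

    stage <- "fill_sinks"
    filled <- fill_sinks(dem)
    say(stage, "max raise %.3f m", max(filled$values - dem$values, na.rm = TRUE))

    stage <- "flow_direction"
    fdir <- d8_flow_direction(filled)

    stage <- "flow_accumulation"
    facc <- flow_accumulation(fdir)
    say(stage, "max contributing area %.3g m2", max(facc$values, na.rm = TRUE))

    stage <- "catchment"
    catchment <- if (!is.null(config$outlet))
      delineate_catchment(fdir, config$outlet) else NULL

    stage <- "flowlines"
    net <- extract_flowlines(facc, fdir, config$flowline_threshold_m2)
    say(stage, "%d chains at threshold %g m2",
        length(net$chains), config$flowline_threshold_m2)

    stage <- "flowline_sampling"
    samples <- sample_flowline_area(net, interval = 5)
    say(stage, "%d sample points", nrow(samples))

    stage <- "area_interpolation"
    stream_m2 <- config$stream_threshold_ha * 1e4
    area_interp <- interpolate_area_nn(samples, facc, catchment_mask = catchment,
                                       stream_threshold = stream_m2)

    stage <- "slope"
    smoothed <- focal_mean_smooth(dem, config$smoothing_window_m)
    slope <- slope_m_per_km(smoothed, s_min = config$s_min)
    say(stage, "slope %.2f-%.2f m/km", min(slope$values, na.rm = TRUE),
        max(slope$values, na.rm = TRUE))

    stage <- "mfac"
    clim <- site_climate(config$precip_mm_yr, config$pe_mm_yr,
                         config$reference_er_mm_yr)
    surface <- compute_mfac(area_interp, slope, clim$k_factor, stream_m2,
                            raw_area_grid = facc)
    surface <- classify_mfac(surface)
    dist <- class_area_distribution(surface)
    say(stage, "K = %.4g; MFAC up to %.2f km", clim$k_factor,
        max(surface$mfac$values, na.rm = TRUE))

    stage <- "write_outputs"
    write_ascii_grid(surface$mfac, paths$mfac)
    class_idx <- matrix(match(surface$class_labels, surface$scheme$label),
                        nrow(surface$class_labels), ncol(surface$class_labels))
    write_ascii_grid(raster_grid(class_idx + 0, surface$mfac$cell_size,
                                 surface$mfac$origin_x, surface$mfac$origin_y,
                                 units = "MFAC class index"),
                     paths$classes)
    write_flowlines_geojson(net, paths$flowlines)
    utils::write.csv(dist, paths$distribution, row.names = FALSE)

    stage <- "manifest"
    cfg_plain <- unclass(config)
    cfg_plain$dem <- if (is.character(config$dem)) config$dem else "<in-memory grid>"
    cfg_file <- tempfile(fileext = ".json")
    jsonlite::write_json(cfg_plain, cfg_file, auto_unbox = TRUE, digits = NA)
    manifest <- list(
      package_version = as.character(utils::packageVersion("mfac")),
      config = cfg_plain,
      config_md5 = unname(tools::md5sum(cfg_file)),
      input_md5 = if (is.character(config$dem)) unname(tools::md5sum(config$dem)) else NA,
      output_md5 = lapply(paths[c("mfac", "classes", "flowlines", "distribution")],
                          function(p) unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
    unlink(cfg_file)

    list(dem = dem, filled = filled, fdir = fdir, facc = facc,
         catchment = catchment, flowlines = net, samples = samples,
         area_interp = area_interp, slope = slope, surface = surface,
         distribution = dist, paths = paths)
  }, error = function(e) {
    unlink(unlist(paths))
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

#' Recompute the campaign regression statistics from the bundled tables
#'
#' Reruns the regression analysis on the bundled per-well water-table
#' table: summer D90 on log10(MFAC) for 2019, 2020 and both summers
#' pooled; the water-table fluctuation (D1 - D99) regressions for 2019 and
#' 2020; the threshold count of deep water tables at low-MFAC wells; the
#' climatic K factors from the site effective-rainfall values; and the
#' summer precipitation proportion for Letterunshin 2020. Each computed
#' value is compared against the corresponding statistic reported for the
#' original campaign, with a pass flag at the stated tolerance.
#'
#' @param r2_tol Tolerance on r-squared comparisons (default 0.02,
#'   reflecting the 2 dp rounding of the tabulated levels).
#' @param f_tol_rel Relative tolerance on F statistics (default 0.05).
#' @return A data.frame with `quantity`, `computed`, `reference`, `pass`.
#' @export
reproduce_study_stats <- function(r2_tol = 0.02, f_tol_rel = 0.05) {
  t1 <- load_study_table("site_climate")
  t2 <- load_study_table("met_summary")
  t3 <- load_study_table("well_stats")

  fits <- list(
    d90_2019 = fit_log_linear(t3$mfac_km, t3$d90_2019_m, t3$well_id),
    d90_2020 = fit_log_linear(t3$mfac_km, t3$d90_2020_m, t3$well_id),
    d90_pooled = fit_log_linear(rep(t3$mfac_km, 2),
                                c(t3$d90_2019_m, t3$d90_2020_m),
                                paste(rep(t3$well_id, 2),
                                      rep(c(2019, 2020), each = nrow(t3)))),
    fluct_2019 = fit_log_linear(t3$mfac_km, t3$fluct_2019_m, t3$well_id),
    fluct_2020 = fit_log_linear(t3$mfac_km, t3$fluct_2020_m, t3$well_id))

  reference <- list(
    d90_2019 = c(n = 35, r2 = 0.63, f = 55.78),
    d90_2020 = c(n = 33, r2 = 0.66, f = 61.31),
    d90_pooled = c(n = 68, r2 = 0.57, f = 86.09),
    fluct_2019 = c(n = 35, r2 = 0.48, f = 30.91),
    fluct_2020 = c(n = 33, r2 = 0.55, f = 37.82))

  rows <- list()
  add <- function(q, comp, ref, pass) {
    rows[[length(rows) + 1L]] <<- data.frame(
      quantity = q, computed = comp, reference = ref, pass = pass)
  }
  for (nm in names(fits)) {
    ft <- fits[[nm]]; rf <- reference[[nm]]
    add(paste0(nm, "_n"), ft$n, rf["n"], ft$n == rf["n"])
    add(paste0(nm, "_r2"), ft$r_squared, rf["r2"],
        abs(ft$r_squared - rf["r2"]) <= r2_tol)
    add(paste0(nm, "_F"), ft$f_statistic, rf["f"],
        abs(ft$f_statistic - rf["f"]) / rf["f"] <= f_tol_rel)
  }

  tc <- threshold_counts(t3$mfac_km, t3$d90_2019_m, mfac_cut = 1.5, depth_cut = 0.20)
  add("wells_below_1.5km", tc[1], 13, tc[1] == 13)
  add("deep_d90_below_1.5km", tc[2], 11, tc[2] == 11)

  ref_er <- t1$effective_rainfall_mm_yr[t1$site == "Letterunshin"]
  for (i in seq_len(nrow(t1))) {
    k <- climatic_k(t1$effective_rainfall_mm_yr[i], ref_er)
    add(paste0("k_", tolower(t1$site[i])), round(k, 2), t1$k_factor[i],
        abs(round(k, 2) - t1$k_factor[i]) < 1e-9)
  }

  l20 <- t2[t2$site == "Letterunshin" & t2$year == 2020 &
              t2$variable == "precip_mm", ]
  prop <- seasonal_proportion_pct(l20$summer, l20$winter)
  add("letterunshin_2020_summer_precip_pct", prop, l20$prop_summer_pct,
      prop == l20$prop_summer_pct)

  do.call(rbind, rows)
}
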