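#' Site climate and climatic correction factor
#'
#' The MFAC climatic correction factor K scales a site's long-term annual
#' effective rainfall (precipitation minus potential evapotranspiration,
#' mm/yr) against a reference site, so that wetness surfaces computed for
#' different bogs are mutually comparable. The reference is the
#' Letterunshin baseline of 907 mm/yr effective rainfall (K = 1 there).
#'
#' @param precip_mm_yr,pe_mm_yr Annual average precipitation and potential
#'   evapotranspiration (mm/yr).
#' @param reference_er_mm_yr Reference effective rainfall (mm/yr),
#'   default 907.
#' @return A `site_climate` list with `effective_rainfall_mm_yr` and
#'   `k_factor` (carried at full precision; two-decimal display is a
#'   reporting convention).
#' @export
site_climate <- function(precip_mm_yr, pe_mm_yr, reference_er_mm_yr = 907) {
  er <- precip_mm_yr - pe_mm_yr
  structure(list(precip_mm_yr = precip_mm_yr, pe_mm_yr = pe_mm_yr,
                 effective_rainfall_mm_yr = er,
                 reference_er_mm_yr = reference_er_mm_yr,
                 k_factor = climatic_k(er, reference_er_mm_yr)),
            class = "site_climate")
}

#' @rdname site_climate
#' @param effective_rainfall_mm_yr Site annual effective rainfall (mm/yr).
#' @export
climatic_k <- function(effective_rainfall_mm_yr, reference_er_mm_yr = 907) {
  if (effective_rainfall_mm_yr <= 0 || reference_er_mm_yr <= 0)
    stop("effective rainfall values must be positive")
  effective_rainfall_mm_yr / reference_er_mm_yr
}

#' MFAC wetness class scheme
#'
#' The five MFAC classes used to map relative surface wetness, with the
#' summer D90 water-table band (cm below ground) each class predicts under
#' the pooled 2019 regression. Bins are left-closed, right-open on (0, Inf).
#'
#' @return A data.frame with `label`, `lower_km`, `upper_km`,
#'   `predicted_d90_cm_band`.
#' @export
mfac_class_scheme <- function() {
  data.frame(
    label = c("0-0.5", "0.5-1", "1-2", "2-5", ">5"),
    lower_km = c(0, 0.5, 1, 2, 5),
    upper_km = c(0.5, 1, 2, 5, Inf),
    predicted_d90_cm_band = c(">=30", "25-30", "20-25", "13-20", "<13"),
    stringsAsFactors = FALSE)
}

#' Sample contributing area along flowlines
#'
#' Places points at fixed arc-length intervals along each flowline chain
#' (first point at the chain head), each carrying the flow accumulation of
#' its host cell. These points feed the catchment-wide natural-neighbour
#' interpolation of contributing area.
#'
#' @param network A `flowline_network` from [extract_flowlines()].
#' @param interval Spacing in metres (default 5).
#' @return A data.frame with `x`, `y`, `area_m2`, `chain`.
#' @export
sample_flowline_area <- function(network, interval = 5) {
  stopifnot(inherits(network, "flowline_network"))
  if (interval <= 0) stop("`interval` must be positive")
  out <- lapply(seq_along(network$chains), function(ci) {
    ch <- network$chains[[ci]]
    if (nrow(ch) == 1L)
      return(data.frame(x = ch$x, y = ch$y, area_m2 = ch$area_m2, chain = ci))
    seg <- sqrt(diff(ch$x)^2 + diff(ch$y)^2)
    arc <- c(0, cumsum(seg))
    targets <- seq(0, arc[length(arc)], by = interval)
    # host cell: vertex whose arc interval contains the target point
    host <- findInterval(targets, arc, rightmost.closed = TRUE)
    frac <- (targets - arc[host]) / ifelse(host < nrow(ch), seg[pmin(host, length(seg))], 1)
    nxt <- pmin(host + 1L, nrow(ch))
    data.frame(
      x = ch$x[host] + frac * (ch$x[nxt] - ch$x[host]),
      y = ch$y[host] + frac * (ch$y[nxt] - ch$y[host]),
      area_m2 = ch$area_m2[ifelse(frac < 0.5, host, nxt)],
      chain = ci)
  })
  do.call(rbind, out)
}

#' Interpolate contributing area across a catchment
#'
#' Sibson natural-neighbour interpolation of flowline-sampled contributing
#' area at every masked cell centre of the target grid. Sample points at or
#' above `stream_threshold` are excluded beforehand, so defined channels do
#' not inflate the interpolated surface.
#'
#' @param points data.frame from [sample_flowline_area()].
#' @param target A `raster_grid` defining the output footprint.
#' @param catchment_mask Optional `raster_grid` (0/1); cells outside the
#'   mask become `NA`.
#' @param stream_threshold Optional accumulation threshold (m^2); sample
#'   points with `area_m2 >=` this are dropped before interpolation.
#' @return A `raster_grid` of interpolated contributing area (m^2).
#' @export
interpolate_area_nn <- function(points, target, catchment_mask = NULL,
                                stream_threshold = NULL) {
  stopifnot(is_raster_grid(target))
  if (!is.null(stream_threshold))
    points <- points[points$area_m2 < stream_threshold, , drop = FALSE]
  if (nrow(points) == 0L) stop("no sample points to interpolate")
  nr <- nrow(target$values); nc <- ncol(target$values)
  sel <- !is.na(target$values)
  if (!is.null(catchment_mask))
    sel <- sel & !is.na(catchment_mask$values) & catchment_mask$values > 0
  idx <- which(sel, arr.ind = TRUE)
  xy <- cell_centre_xy(target, idx[, 1], idx[, 2])
  vals <- sibson_interpolate(points$x, points$y, points$area_m2,
                             xy[, 1], xy[, 2])
  out <- matrix(NA_real_, nr, nc)
  out[idx] <- vals
  raster_grid(out, target$cell_size, target$origin_x, target$origin_y,
              units = "m2 area")
}

#' Compute the MFAC surface
#'
#' Per-cell Modified Flow Accumulation Capacity,
#' `MFAC = (sqrt(A) / s) * K`, with A the contributing catchment area
#' (m^2), s the local surface slope (m/km) and K the climatic correction
#' factor; the result is in km. Cells whose contributing area meets the
#' stream-formation threshold are masked out: once a defined channel forms,
#' the surface-wetness assumption behind MFAC no longer holds and channels
#' would otherwise skew the surface.
#'
#' @param area_grid `raster_grid` of contributing area (m^2), usually the
#'   interpolated surface from [interpolate_area_nn()].
#' @param slope_grid `raster_grid` of slope (m/km) on the same footprint.
#' @param k Climatic correction factor (> 0).
#' @param stream_threshold_m2 Stream-formation threshold (m^2).
#' @param raw_area_grid Optional `raster_grid` of raw (non-interpolated)
#'   accumulation; cells at or above the threshold there are also masked,
#'   so actual channel cells are excluded even where the interpolated
#'   surface is smooth.
#' @return An `mfac_surface`: list with `mfac` (`raster_grid`, km),
#'   `stream_mask` (logical matrix) and the parameters used.
#' @export
compute_mfac <- function(area_grid, slope_grid, k, stream_threshold_m2,
                         raw_area_grid = NULL) {
  stopifnot(is_raster_grid(area_grid), is_raster_grid(slope_grid))
  if (!all(dim(area_grid$values) == dim(slope_grid$values)) ||
      area_grid$cell_size != slope_grid$cell_size)
    stop("area and slope grids must share footprint and cell size")
  if (k <= 0) stop("`k` must be positive")
  if (stream_threshold_m2 <= 0) stop("`stream_threshold_m2` must be positive")
  A <- area_grid$values
  s <- slope_grid$values
  if (any(s <= 0, na.rm = TRUE))
    stop("non-positive slope encountered; apply the slope floor first")
  stream <- !is.na(A) & A >= stream_threshold_m2
  if (!is.null(raw_area_grid)) {
    rA <- raw_area_grid$values
    stream <- stream | (!is.na(rA) & rA >= stream_threshold_m2)
  }
  mfac <- sqrt(A) / s * k   # sqrt(m^2) = m; m / (m/km) = km
  mfac[stream] <- NA_real_
  g <- raster_grid(mfac, area_grid$cell_size, area_grid$origin_x,
                   area_grid$origin_y, units = "km MFAC")
  structure(list(mfac = g, stream_mask = stream, k = k,
                 stream_threshold_m2 = stream_threshold_m2,
                 class_labels = NULL, scheme = NULL),
            class = "mfac_surface")
}

#' @export
print.mfac_surface <- function(x, ...) {
  v <- x$mfac$values
  cat(sprintf("<mfac_surface> %d x %d cells; K = %.4g; stream cells masked: %d\n",
              nrow(v), ncol(v), x$k, sum(x$stream_mask)))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  MFAC range: %.3g - %.3g km\n", rng[1], rng[2]))
  if (!is.null(x$class_labels)) cat("  classified:",
                                    paste(x$scheme$label, collapse = ", "), "\n")
  invisible(x)
}

#' Classify an MFAC surface
#'
#' Assigns each unmasked cell its wetness class under a left-closed,
#' right-open bin scheme (a cell exactly on an edge belongs to the upper
#' class, e.g. MFAC = 2.0 km is class "2-5").
#'
#' @param surface An `mfac_surface`.
#' @param scheme Class scheme data.frame; default [mfac_class_scheme()].
#' @return The surface with `class_labels` (character matrix) filled in.
#' @export
classify_mfac <- function(surface, scheme = mfac_class_scheme()) {
  stopifnot(inherits(surface, "mfac_surface"))
  v <- surface$mfac$values
  if (any(v < 0, na.rm = TRUE)) stop("negative MFAC values are invalid")
  bin <- findInterval(v, scheme$lower_km)  # left-closed bins
  lab <- matrix(NA_character_, nrow(v), ncol(v))
  ok <- !is.na(v)
  lab[ok] <- scheme$label[bin[ok]]
  surface$class_labels <- lab
  surface$scheme <- scheme
  surface
}

#' Class area distribution
#'
#' Percentage of the unmasked, in-catchment area in each MFAC class.
#'
#' @param surface A classified `mfac_surface`.
#' @return A data.frame with `label` and `percent` (sums to 100).
#' @export
class_area_distribution <- function(surface) {
  stopifnot(inherits(surface, "mfac_surface"))
  if (is.null(surface$class_labels))
    stop("surface must be classified first (see `classify_mfac()`)")
  lab <- surface$class_labels[!is.na(surface$class_labels)]
  if (length(lab) == 0L) stop("no in-catchment cells to summarise")
  counts <- table(factor(lab, levels = surface$scheme$label))
  data.frame(label = names(counts),
             percent = 100 * as.numeric(counts) / length(lab),
             stringsAsFactors = FALSE)
}
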