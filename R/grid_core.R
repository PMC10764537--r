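#' Georeferenced raster grid
#'
#' Lightweight container for the gridded quantities handled by the MFAC
#' pipeline: elevation (m), contributing area (m^2), slope (m/km) and MFAC
#' (km). The grid is stored north-up and row-major: row 1 is the northern
#' edge, column 1 the western edge. Missing cells are held as `NA`
#' internally; the `nodata` sentinel is only used on disk.
#'
#' @param values Numeric matrix of cell values, row 1 = north. Cells equal
#'   to `nodata` are converted to `NA`.
#' @param cell_size Cell edge length in metres (> 0).
#' @param origin_x,origin_y Planar coordinates (m) of the lower-left
#'   (south-west) corner of the grid.
#' @param nodata Sentinel used when reading/writing; defaults to -9999.
#' @param units Free-text units tag, e.g. `"m elevation"`, `"m2 area"`,
#'   `"m/km slope"`, `"km MFAC"`.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, cell_size, origin_x = 0, origin_y = 0,
                        nodata = -9999, units = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(is.infinite(values), na.rm = TRUE))
    stop("grid values must be finite or nodata")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         nodata = as.numeric(nodata), units = units),
    class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<raster_grid> %d rows x %d cols @ %g m [%s]\n",
              nrow(v), ncol(v), x$cell_size,
              if (nzchar(x$units)) x$units else "unitless"))
  cat(sprintf("  origin (xll, yll): (%g, %g); nodata cells: %d\n",
              x$origin_x, x$origin_y, sum(is.na(v))))
  rng <- suppressWarnings(range(v, na.rm = TRUE))
  if (is.finite(rng[1])) cat(sprintf("  range: [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

is_raster_grid <- function(x) inherits(x, "raster_grid")

#' Dimensions of a raster grid
#' @param x A `raster_grid`.
#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Planar coordinates of cell centres
#'
#' @param grid A `raster_grid`.
#' @param rows,cols Integer vectors of row/column indices (row 1 = north).
#' @return A two-column matrix of (x, y) centre coordinates in metres.
#' @export
cell_centre_xy <- function(grid, rows, cols) {
  nr <- nrow(grid$values)
  cs <- grid$cell_size
  cbind(x = grid$origin_x + (cols - 0.5) * cs,
        y = grid$origin_y + (nr - rows + 0.5) * cs)
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-key ESRI ASCII header (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by rows of
#' values from north to south. Bare-earth DTMs for the study sites were
#' supplied in this format.
#'
#' @param path Path to a `.asc` file.
#' @param units Units tag attached to the result.
#' @return A `raster_grid`.
#' @export
read_ascii_grid <- function(path, units = "") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 1
  while (i <= length(lines) && grepl("^[A-Za-z]", trimws(lines[i]))) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed header line %d: '%s'", i, lines[i]))
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]]) || is.na(hdr[[key]]))
      stop(sprintf("ESRI ASCII header missing key '%s'", key))
  }
  nodata <- if (!is.null(hdr[["nodata_value"]])) hdr[["nodata_value"]] else -9999
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  rows <- lines[i:length(lines)]
  if (length(rows) != nr)
    stop(sprintf("expected %d data rows, found %d", nr, length(rows)))
  vals <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    v <- as.numeric(strsplit(trimws(rows[r]), "[[:space:]]+")[[1]])
    if (length(v) != nc)
      stop(sprintf("row %d has %d values, expected %d", r, length(v), nc))
    vals[r, ] <- v
  }
  raster_grid(vals, hdr$cellsize, hdr$xllcorner, hdr$yllcorner,
              nodata = nodata, units = units)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]. `NA` cells are serialised as the grid's
#' nodata sentinel; values are formatted with 6 significant digits.
#'
#' @param grid A `raster_grid`.
#' @param path Output path.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(is_raster_grid(grid))
  v <- grid$values
  v[is.na(v)] <- grid$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %s", format(grid$origin_x, digits = 10)),
    sprintf("yllcorner %s", format(grid$origin_y, digits = 10)),
    sprintf("cellsize %s", format(grid$cell_size, digits = 10)),
    sprintf("NODATA_value %s", format(grid$nodata, digits = 10))
  ), con)
  writeLines(apply(v, 1, function(r)
    paste(formatC(r, format = "g", digits = 6), collapse = " ")), con)
  invisible(path)
}

#' Focal mean smoothing
#'
#' Replaces each cell by the mean of all non-missing cells in a square
#' window centred on it. This is the terrain-smoothing step used before
#' slope computation: microtopographic hummocks and hollows on a bog
#' surface would otherwise dominate the local slope estimate. For blanket
#' bogs a 5 m window is used (the 20 m window appropriate to the gentler
#' relief of raised bogs averages away real slope breaks).
#'
#' Edges use the partial window that remains on the grid. A window with no
#' valid cells yields `NA`.
#'
#' @param grid A `raster_grid`.
#' @param window_metres Side length of the square window in metres; must be
#'   at least one cell. Rounded to the nearest odd number of cells.
#' @return A `raster_grid` of the same footprint.
#' @export
focal_mean_smooth <- function(grid, window_metres = 5) {
  stopifnot(is_raster_grid(grid))
  if (window_metres < grid$cell_size)
    stop("`window_metres` must be at least one cell")
  w <- max(1L, round(window_metres / grid$cell_size))
  if (w %% 2 == 0) w <- w + 1L          # centred window needs odd width
  half <- (w - 1L) %/% 2L
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  ok <- !is.na(v)
  vz <- ifelse(ok, v, 0)
  # summed-area tables for values and valid-cell counts
  sat <- function(m) {
    m <- apply(m, 2, cumsum)
    t(apply(m, 1, cumsum))
  }
  S <- sat(vz); C <- sat(ok * 1)
  pad <- function(m) rbind(0, cbind(0, m))   # 1-based inclusive prefix sums
  S <- pad(S); C <- pad(C)
  r0 <- pmax(seq_len(nr) - half, 1L); r1 <- pmin(seq_len(nr) + half, nr)
  c0 <- pmax(seq_len(nc) - half, 1L); c1 <- pmin(seq_len(nc) + half, nc)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    a <- r0[r]; b <- r1[r]
    sum_v <- S[b + 1, c1 + 1] - S[a, c1 + 1] - S[b + 1, c0] + S[a, c0]
    cnt <- C[b + 1, c1 + 1] - C[a, c1 + 1] - C[b + 1, c0] + C[a, c0]
    out[r, ] <- ifelse(cnt > 0, sum_v / cnt, NA_real_)
  }
  out[!ok] <- NA_real_   # nodata cells stay nodata
  g <- grid
  g$values <- out
  g
}

#' Block-mean resampling to a coarser cell size
#'
#' Alternative to [focal_mean_smooth()] for sensitivity tests: aggregates
#' blocks of cells to a coarser resolution by their mean. The new cell size
#' must be an integer multiple of the old one.
#'
#' @param grid A `raster_grid`.
#' @param new_cell_size Target cell size in metres.
#' @return A `raster_grid` at the coarser resolution.
#' @export
resample_block_mean <- function(grid, new_cell_size) {
  stopifnot(is_raster_grid(grid))
  f <- new_cell_size / grid$cell_size
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("`new_cell_size` must be an integer multiple of the current cell size")
  f <- as.integer(round(f))
  v <- grid$values
  nr <- (nrow(v) %/% f) * f
  nc <- (ncol(v) %/% f) * f
  v <- v[seq_len(nr), seq_len(nc), drop = FALSE]
  ri <- (seq_len(nr) - 1L) %/% f
  ci <- (seq_len(nc) - 1L) %/% f
  sums <- rowsum(t(rowsum(ifelse(is.na(v), 0, v), ri)), ci)
  cnts <- rowsum(t(rowsum((!is.na(v)) * 1, ri)), ci)
  out <- t(ifelse(cnts > 0, sums / cnts, NA_real_))
  # top rows beyond the retained extent are dropped; origin stays at yll
  raster_grid(out, new_cell_size, grid$origin_x,
              grid$origin_y + (nrow(grid$values) - nr) * grid$cell_size,
              nodata = grid$nodata, units = grid$units)
}
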