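# D8 neighbour convention, clockwise from east; row 1 = north, so the row
# offset for "south" is +1. Ties in steepest descent are broken by taking
# the first maximum in this fixed order, which keeps routing deterministic
# across platforms.
.d8_dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
.d8_dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
.d8_names <- c("E", "SE", "S", "SW", "W", "NW", "N", "NE")
.d8_dist <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# Minimal binary min-heap on (key, id) used by the priority-flood fill.
.heap_new <- function(n) {
  env <- new.env(parent = emptyenv())
  env$key <- numeric(n); env$id <- integer(n); env$size <- 0L
  env
}
.heap_push <- function(h, key, id) {
  h$size <- h$size + 1L
  i <- h$size
  if (i > length(h$key)) { h$key <- c(h$key, numeric(i)); h$id <- c(h$id, integer(i)) }
  h$key[i] <- key; h$id[i] <- id
  while (i > 1L) {
    p <- i %/% 2L
    if (h$key[p] <= h$key[i]) break
    tmpk <- h$key[p]; h$key[p] <- h$key[i]; h$key[i] <- tmpk
    tmpi <- h$id[p]; h$id[p] <- h$id[i]; h$id[i] <- tmpi
    i <- p
  }
}
.heap_pop <- function(h) {
  top <- h$id[1L]
  h$key[1L] <- h$key[h$size]; h$id[1L] <- h$id[h$size]
  h$size <- h$size - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L
    if (l > h$size) break
    m <- if (r <= h$size && h$key[r] < h$key[l]) r else l
    if (h$key[i] <= h$key[m]) break
    tmpk <- h$key[m]; h$key[m] <- h$key[i]; h$key[i] <- tmpk
    tmpi <- h$id[m]; h$id[m] <- h$id[i]; h$id[i] <- tmpi
    i <- m
  }
  top
}

#' Fill depressions in a DTM
#'
#' Priority-flood depression filling with an epsilon gradient: closed
#' depressions are raised to their pour level and flats are resolved by
#' imposing a tiny increment (`epsilon` metres per cell step) away from the
#' pour point, so that every cell retains a strictly descending D8 path to
#' the grid edge (or to a nodata margin). Output elevations are never below
#' the input, and the operation is idempotent.
#'
#' @param dem A `raster_grid` of elevations (m).
#' @param epsilon Flat-resolution increment in metres per cell step.
#' @return A `raster_grid` of filled elevations.
#' @export
fill_sinks <- function(dem, epsilon = 1e-5) {
  stopifnot(is_raster_grid(dem))
  z <- dem$values
  nr <- nrow(z); nc <- ncol(z)
  valid <- !is.na(z)
  if (!any(valid)) stop("all-nodata grid cannot be filled")
  filled <- matrix(NA_real_, nr, nc)
  state <- matrix(0L, nr, nc)  # 0 = unseen, 1 = queued, 2 = done
  h <- .heap_new(64L)
  # seeds: valid cells on the grid edge or adjacent to nodata (can drain off)
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    if (!valid[r, co]) next
    edge <- r == 1L || r == nr || co == 1L || co == nc
    if (!edge) {
      for (k in 1:8) {
        if (!valid[r + .d8_dr[k], co + .d8_dc[k]]) { edge <- TRUE; break }
      }
    }
    if (edge) {
      filled[r, co] <- z[r, co]
      state[r, co] <- 1L
      .heap_push(h, z[r, co], (co - 1L) * nr + r)
    }
  }
  if (h$size == 0L) stop("grid has no edge cell that can drain")
  while (h$size > 0L) {
    id <- .heap_pop(h)
    r <- ((id - 1L) %% nr) + 1L
    co <- ((id - 1L) %/% nr) + 1L
    if (state[r, co] == 2L) next
    state[r, co] <- 2L
    for (k in 1:8) {
      rr <- r + .d8_dr[k]; cc <- co + .d8_dc[k]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (!valid[rr, cc] || state[rr, cc] != 0L) next
      filled[rr, cc] <- max(z[rr, cc], filled[r, co] + epsilon)
      state[rr, cc] <- 1L
      .heap_push(h, filled[rr, cc], (cc - 1L) * nr + rr)
    }
  }
  g <- dem
  g$values <- filled
  g
}

#' D8 flow directions
#'
#' Assigns each cell the direction of steepest descent among its eight
#' neighbours (drop divided by centre-to-centre distance; diagonals use
#' `cell_size * sqrt(2)`). The input must be sink-free (see
#' [fill_sinks()]); cells with no lower neighbour are outlets, permitted
#' only on the grid edge or beside nodata.
#'
#' @param filled_dem A sink-free `raster_grid` of elevations.
#' @return A `flow_direction` object: integer matrix with codes 1..8 =
#'   E, SE, S, SW, W, NW, N, NE; 0 = outlet; NA = nodata.
#' @export
d8_flow_direction <- function(filled_dem) {
  stopifnot(is_raster_grid(filled_dem))
  z <- filled_dem$values
  nr <- nrow(z); nc <- ncol(z)
  cs <- filled_dem$cell_size
  best_drop <- matrix(-Inf, nr, nc)
  dir <- matrix(0L, nr, nc)
  for (k in 1:8) {
    nz <- matrix(NA_real_, nr, nc)
    rsrc <- seq_len(nr) + .d8_dr[k]
    csrc <- seq_len(nc) + .d8_dc[k]
    rok <- rsrc >= 1L & rsrc <= nr
    cok <- csrc >= 1L & csrc <= nc
    nz[rok, cok] <- z[rsrc[rok], csrc[cok]]
    drop <- (z - nz) / (cs * .d8_dist[k])
    sel <- !is.na(drop) & drop > best_drop & drop > 0
    best_drop[sel] <- drop[sel]
    dir[sel] <- k
  }
  dir[is.na(z)] <- NA_integer_
  # outlets: no strictly lower neighbour; must sit on the edge or a nodata margin
  outlet <- !is.na(z) & dir == 0L
  if (any(outlet)) {
    idx <- which(outlet, arr.ind = TRUE)
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1]; co <- idx[i, 2]
      on_edge <- r == 1L || r == nr || co == 1L || co == nc
      if (!on_edge) {
        for (k in 1:8) {
          if (is.na(z[r + .d8_dr[k], co + .d8_dc[k]])) { on_edge <- TRUE; break }
        }
      }
      if (!on_edge)
        stop(sprintf("interior cell (%d, %d) has no downslope neighbour; input is not sink-free", r, co))
    }
  }
  structure(list(directions = dir, cell_size = cs,
                 origin_x = filled_dem$origin_x, origin_y = filled_dem$origin_y),
            class = "flow_direction")
}

#' @export
print.flow_direction <- function(x, ...) {
  cat(sprintf("<flow_direction> %d x %d @ %g m; %d outlets\n",
              nrow(x$directions), ncol(x$directions), x$cell_size,
              sum(x$directions == 0L, na.rm = TRUE)))
  invisible(x)
}

# linear index of the downstream cell for every valid cell (NA for outlets)
.downstream_index <- function(fdir) {
  d <- fdir$directions
  nr <- nrow(d); nc <- ncol(d)
  idx <- which(!is.na(d) & d > 0L)
  r <- ((idx - 1L) %% nr) + 1L
  co <- ((idx - 1L) %/% nr) + 1L
  k <- d[idx]
  down <- (co + .d8_dc[k] - 1L) * nr + (r + .d8_dr[k])
  list(from = idx, to = down)
}

#' D8 flow accumulation
#'
#' Contributing catchment area per cell, in square metres, computed in
#' topological order along the D8 links. The convention is self-inclusive:
#' every cell contributes its own area, so the minimum accumulation is one
#' cell area. (MFAC takes the square root of this quantity, and an
#' upstream-only convention would make headwater cells degenerate.)
#'
#' @param fdir A `flow_direction` object.
#' @return A `raster_grid` of contributing area in m^2.
#' @export
flow_accumulation <- function(fdir) {
  stopifnot(inherits(fdir, "flow_direction"))
  d <- fdir$directions
  nr <- nrow(d); nc <- ncol(d)
  n <- nr * nc
  count <- rep(NA_real_, n)
  valid <- which(!is.na(d))
  count[valid] <- 1
  dn <- .downstream_index(fdir)
  downstream <- rep(NA_integer_, n)
  downstream[dn$from] <- dn$to
  indeg <- integer(n)
  tb <- tabulate(dn$to, nbins = n)
  indeg <- tb
  queue <- valid[indeg[valid] == 0L]
  head <- 1L
  queue <- c(queue, integer(length(valid)))
  tail <- sum(indeg[valid] == 0L)
  processed <- 0L
  while (head <= tail) {
    c0 <- queue[head]; head <- head + 1L
    processed <- processed + 1L
    dwn <- downstream[c0]
    if (!is.na(dwn)) {
      count[dwn] <- count[dwn] + count[c0]
      indeg[dwn] <- indeg[dwn] - 1L
      if (indeg[dwn] == 0L) { tail <- tail + 1L; queue[tail] <- dwn }
    }
  }
  if (processed < length(valid))
    stop("cycle detected in flow direction grid")
  raster_grid(matrix(count * fdir$cell_size^2, nr, nc),
              fdir$cell_size, fdir$origin_x, fdir$origin_y,
              units = "m2 area")
}

#' Surface slope in metres per kilometre
#'
#' Slope magnitude from Horn's 3x3 finite differences on a (smoothed)
#' elevation grid, expressed as rise over run times 1000 (m/km). Edge cells
#' use replicated border values; missing neighbours fall back to the centre
#' value. Slopes below `s_min` are floored to `s_min` so that the MFAC
#' ratio `sqrt(A)/s` stays finite on perfectly flat ground.
#'
#' @param smoothed_dem A `raster_grid` of elevations, normally the output
#'   of [focal_mean_smooth()].
#' @param s_min Slope floor in m/km (default 0.1).
#' @return A `raster_grid` of slope in m/km.
#' @export
slope_m_per_km <- function(smoothed_dem, s_min = 0.1) {
  stopifnot(is_raster_grid(smoothed_dem))
  z <- smoothed_dem$values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("grid must be at least 3 x 3 for slope")
  cs <- smoothed_dem$cell_size
  # replicate-pad, then substitute the centre value for missing neighbours
  zp <- rbind(z[1, , drop = FALSE], z, z[nr, , drop = FALSE])
  zp <- cbind(zp[, 1, drop = FALSE], zp, zp[, nc, drop = FALSE])
  nb <- function(dr, dc) {
    m <- zp[seq_len(nr) + 1L + dr, seq_len(nc) + 1L + dc]
    ifelse(is.na(m), z, m)
  }
  a <- nb(-1L, -1L); b <- nb(-1L, 0L); cc_ <- nb(-1L, 1L)
  d <- nb(0L, -1L);                    f <- nb(0L, 1L)
  g <- nb(1L, -1L);  hh <- nb(1L, 0L); i <- nb(1L, 1L)
  dzdx <- ((cc_ + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * hh + i) - (a + 2 * b + cc_)) / (8 * cs)
  s <- sqrt(dzdx^2 + dzdy^2) * 1000
  s <- pmax(s, s_min)
  s[is.na(z)] <- NA_real_
  raster_grid(s, cs, smoothed_dem$origin_x, smoothed_dem$origin_y,
              units = "m/km slope")
}

#' Extract flowlines above an accumulation threshold
#'
#' Cells whose contributing area meets `flowline_threshold` form the
#' flowline network. Maximal downstream chains are returned; confluences
#' split chains, with the junction cell shared as the last vertex of each
#' upstream chain and the first vertex of the downstream chain.
#'
#' @param facc `raster_grid` of contributing area (m^2) from
#'   [flow_accumulation()].
#' @param fdir Matching `flow_direction`.
#' @param flowline_threshold Accumulation threshold in m^2 (default
#'   1000 m^2 = 0.1 ha).
#' @return A `flowline_network`: list of chains, each a data.frame with
#'   columns `row`, `col`, `x`, `y`, `area_m2`.
#' @export
extract_flowlines <- function(facc, fdir, flowline_threshold = 1000) {
  stopifnot(is_raster_grid(facc), inherits(fdir, "flow_direction"))
  if (flowline_threshold <= 0) stop("`flowline_threshold` must be positive")
  A <- facc$values
  d <- fdir$directions
  nr <- nrow(A); nc <- ncol(A)
  innet <- !is.na(A) & A >= flowline_threshold
  chains <- list()
  if (any(innet)) {
    n <- nr * nc
    dn <- .downstream_index(fdir)
    downstream <- rep(NA_integer_, n)
    downstream[dn$from] <- dn$to
    netidx <- which(innet)
    # in-network indegree: upstream neighbours that are themselves flowline cells
    to_in <- downstream[netidx]
    to_in <- to_in[!is.na(to_in) & innet[to_in]]
    indeg <- tabulate(to_in, nbins = n)
    heads <- netidx[indeg[netidx] != 1L]  # sources and junction cells start chains
    for (h0 in heads) {
      cur <- h0
      rows <- integer(0); cols <- integer(0)
      repeat {
        r <- ((cur - 1L) %% nr) + 1L
        co <- ((cur - 1L) %/% nr) + 1L
        rows <- c(rows, r); cols <- c(cols, co)
        nxt <- downstream[cur]
        if (is.na(nxt) || !innet[nxt]) break
        if (indeg[nxt] >= 2L) {  # junction: include as shared vertex, stop
          rows <- c(rows, ((nxt - 1L) %% nr) + 1L)
          cols <- c(cols, ((nxt - 1L) %/% nr) + 1L)
          break
        }
        cur <- nxt
      }
      xy <- cell_centre_xy(facc, rows, cols)
      chains[[length(chains) + 1L]] <- data.frame(
        row = rows, col = cols, x = xy[, 1], y = xy[, 2],
        area_m2 = A[cbind(rows, cols)])
    }
  }
  structure(list(chains = chains, cell_size = facc$cell_size,
                 threshold_m2 = flowline_threshold),
            class = "flowline_network")
}

#' @export
print.flowline_network <- function(x, ...) {
  nv <- sum(vapply(x$chains, nrow, 1L))
  cat(sprintf("<flowline_network> %d chains, %d vertices (threshold %g m2)\n",
              length(x$chains), nv, x$threshold_m2))
  invisible(x)
}

#' Export flowlines as GeoJSON LineStrings
#'
#' @param network A `flowline_network`.
#' @param path Output `.geojson` path.
#' @export
write_flowlines_geojson <- function(network, path) {
  feats <- lapply(network$chains, function(ch) {
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(Map(c, ch$x, ch$y))),
         properties = list(area_m2 = ch$area_m2))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Delineate the catchment of an outlet cell
#'
#' All cells whose D8 flow path passes through the outlet (the outlet
#' itself included).
#'
#' @param fdir A `flow_direction` object.
#' @param outlet Integer vector `c(row, col)` of the outlet cell.
#' @return A `raster_grid` of 0/1 membership (NA where nodata).
#' @export
delineate_catchment <- function(fdir, outlet) {
  stopifnot(inherits(fdir, "flow_direction"))
  d <- fdir$directions
  nr <- nrow(d); nc <- ncol(d)
  r <- outlet[1]; co <- outlet[2]
  if (r < 1 || r > nr || co < 1 || co > nc || is.na(d[r, co]))
    stop("outlet must be a valid (non-nodata) cell")
  n <- nr * nc
  dn <- .downstream_index(fdir)
  # upstream adjacency: for each cell, which cells drain directly into it
  ord <- order(dn$to)
  to_sorted <- dn$to[ord]; from_sorted <- dn$from[ord]
  first <- rep(0L, n + 1L)
  cnt <- tabulate(to_sorted, nbins = n)
  first <- cumsum(c(1L, cnt))
  mask <- rep(FALSE, n)
  start <- (co - 1L) * nr + r
  stack <- integer(64L); stack[1L] <- start; sp <- 1L
  mask[start] <- TRUE
  while (sp > 0L) {
    cur <- stack[sp]; sp <- sp - 1L
    lo <- first[cur]; hi <- first[cur + 1L] - 1L
    if (hi >= lo) {
      ups <- from_sorted[lo:hi]
      ups <- ups[!mask[ups]]
      for (u in ups) {
        mask[u] <- TRUE
        sp <- sp + 1L
        if (sp > length(stack)) stack <- c(stack, integer(length(stack)))
        stack[sp] <- u
      }
    }
  }
  out <- matrix(as.numeric(mask), nr, nc)
  out[is.na(d)] <- NA_real_
  raster_grid(out, fdir$cell_size, fdir$origin_x, fdir$origin_y,
              units = "catchment mask")
}
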