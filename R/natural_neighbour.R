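# Exact-geometry Sibson (natural neighbour) interpolation.
#
# A Voronoi cell is represented as a convex polygon (two-column matrix of
# vertices, counter-clockwise) obtained by clipping a bounding box with the
# perpendicular-bisector half-planes against the other sample points. The
# Sibson weight of sample s for a query q is the area the (augmented)
# Voronoi cell of q steals from the original cell of s. Interpolation is
# exact at sample locations and has linear precision in the interior.

# clip convex polygon `poly` to the half-plane a*x + b*y <= c
.clip_halfplane <- function(poly, a, b, co) {
  n <- nrow(poly)
  if (n == 0L) return(poly)
  d <- a * poly[, 1] + b * poly[, 2] - co
  inside <- d <= 1e-12
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  out <- matrix(0, n + 4L, 2L)
  m <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (inside[i]) { m <- m + 1L; out[m, ] <- poly[i, ] }
    if (inside[i] != inside[j]) {
      t <- d[i] / (d[i] - d[j])
      m <- m + 1L
      out[m, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(m), , drop = FALSE]
}

.poly_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# intersection of two convex polygons (clip a by each edge of b)
.poly_intersect <- function(a, b) {
  n <- nrow(b)
  if (n < 3L || nrow(a) < 3L) return(a[0, , drop = FALSE])
  # orient b counter-clockwise
  x <- b[, 1]; y <- b[, 2]
  j <- c(2:n, 1L)
  if (sum(x * y[j] - x[j] * y) < 0) b <- b[n:1, , drop = FALSE]
  poly <- a
  for (i in seq_len(nrow(b))) {
    k <- if (i == nrow(b)) 1L else i + 1L
    ex <- b[k, 1] - b[i, 1]; ey <- b[k, 2] - b[i, 2]
    # inside of a CCW edge is to its left: ey*x - ex*y <= ey*bx - ex*by
    poly <- .clip_halfplane(poly, ey, -ex, ey * b[i, 1] - ex * b[i, 2])
    if (nrow(poly) == 0L) break
  }
  poly
}

# Voronoi cell of the point (qx, qy) against samples pts (excluding row
# `skip` if given), clipped to the rectangle `box` = c(x0, y0, x1, y1).
# Bisectors are applied nearest-first and pruned once no remaining sample
# can cut the polygon.
.voronoi_cell <- function(qx, qy, pts, box, skip = 0L) {
  poly <- cbind(c(box[1], box[3], box[3], box[1]),
                c(box[2], box[2], box[4], box[4]))
  dx <- pts[, 1] - qx; dy <- pts[, 2] - qy
  d2 <- dx * dx + dy * dy
  ord <- order(d2)
  if (skip > 0L) ord <- ord[ord != skip]
  for (s in ord) {
    ds <- sqrt(d2[s])
    if (ds < 1e-12) next
    vd2 <- (poly[, 1] - qx)^2 + (poly[, 2] - qy)^2
    if (ds / 2 > sqrt(max(vd2))) break  # bisector cannot reach the polygon
    # half-plane of points nearer q than sample s
    mx <- (pts[s, 1] + qx) / 2; my <- (pts[s, 2] + qy) / 2
    poly <- .clip_halfplane(poly, dx[s], dy[s], dx[s] * mx + dy[s] * my)
    if (nrow(poly) == 0L) break
  }
  poly
}

#' Sibson natural-neighbour interpolation
#'
#' Interpolates scattered sample values at query points using Sibson's
#' area-stealing weights on the exact Voronoi geometry. Queries outside the
#' convex hull of the samples take the value of the nearest sample (a
#' documented extrapolation rule; true Sibson weights are undefined there).
#' With fewer than three samples, or collinear samples, the function falls
#' back to nearest-sample assignment and records a warning.
#'
#' @param px,py,pv Sample coordinates (m) and values.
#' @param qx,qy Query coordinates.
#' @return Numeric vector of interpolated values; attribute
#'   `"fallback"` is `TRUE` when nearest-sample fallback was used.
#' @export
sibson_interpolate <- function(px, py, pv, qx, qy) {
  stopifnot(length(px) == length(py), length(px) == length(pv))
  n <- length(px)
  pts <- cbind(px, py)
  nearest_val <- function(x, y) {
    pv[which.min((px - x)^2 + (py - y)^2)]
  }
  collinear <- n >= 3 && {
    dx <- px - px[1]; dy <- py - py[1]
    all(abs(dx * dy[2] - dy * dx[2]) < 1e-9 * (max(abs(c(dx, dy))) + 1)^2)
  }
  if (n < 3 || collinear) {
    warning("fewer than 3 non-collinear samples; using nearest-sample assignment")
    out <- vapply(seq_along(qx), function(i) nearest_val(qx[i], qy[i]), 0)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  span <- max(max(px) - min(px), max(py) - min(py), 1e-9)
  box <- c(min(px) - 0.5 * span, min(py) - 0.5 * span,
           max(px) + 0.5 * span, max(py) + 0.5 * span)
  hull <- grDevices::chull(px, py)
  hx <- px[hull]; hy <- py[hull]
  # orient hull CCW for the inside test
  nh <- length(hull)
  jj <- c(2:nh, 1L)
  if (sum(hx * hy[jj] - hx[jj] * hy) < 0) { hx <- rev(hx); hy <- rev(hy) }
  in_hull <- function(x, y) {
    for (i in seq_len(nh)) {
      k <- if (i == nh) 1L else i + 1L
      if ((hx[k] - hx[i]) * (y - hy[i]) - (hy[k] - hy[i]) * (x - hx[i]) < -1e-9 * span)
        return(FALSE)
    }
    TRUE
  }
  cells <- vector("list", n)  # original Voronoi cells, built lazily
  get_cell <- function(s) {
    if (is.null(cells[[s]]))
      cells[[s]] <<- .voronoi_cell(pts[s, 1], pts[s, 2], pts, box, skip = s)
    cells[[s]]
  }
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    x <- qx[i]; y <- qy[i]
    d2 <- (px - x)^2 + (py - y)^2
    s0 <- which.min(d2)
    if (d2[s0] < (1e-9 * span)^2) { out[i] <- pv[s0]; next }  # exact at samples
    if (!in_hull(x, y)) { out[i] <- pv[s0]; next }
    cellq <- .voronoi_cell(x, y, pts, box)
    if (nrow(cellq) < 3L) { out[i] <- pv[s0]; next }
    vd2 <- max((cellq[, 1] - x)^2 + (cellq[, 2] - y)^2)
    cand <- which(d2 <= 4 * vd2 + 1e-9)  # only these can share area with cellq
    wsum <- 0; vsum <- 0
    for (s in cand) {
      w <- .poly_area(.poly_intersect(cellq, get_cell(s)))
      if (w > 0) { wsum <- wsum + w; vsum <- vsum + w * pv[s] }
    }
    out[i] <- if (wsum > 0) vsum / wsum else pv[s0]
  }
  attr(out, "fallback") <- FALSE
  out
}
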