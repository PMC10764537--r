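# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the slowest, most literal formulation of each
# definition and share no code with the package internals.

.o_dr <- c(0, 1, 1, 1, 0, -1, -1, -1)
.o_dc <- c(1, 1, 0, -1, -1, -1, 0, 1)
.o_dist <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# Gauss-Seidel fixpoint flooding: F(c) = max(dem(c), min_n F(n) + eps),
# seeded with F = dem on the boundary and +Inf inside, swept to fixpoint.
oracle_fill <- function(z, eps = 1e-5) {
  nr <- nrow(z); nc <- ncol(z)
  f <- matrix(Inf, nr, nc)
  f[1, ] <- z[1, ]; f[nr, ] <- z[nr, ]; f[, 1] <- z[, 1]; f[, nc] <- z[, nc]
  repeat {
    changed <- FALSE
    for (r in 2:(nr - 1)) for (co in 2:(nc - 1)) {
      mn <- Inf
      for (k in 1:8) mn <- min(mn, f[r + .o_dr[k], co + .o_dc[k]])
      new <- max(z[r, co], mn + eps)
      if (new < f[r, co] - 1e-15) { f[r, co] <- new; changed <- TRUE }
    }
    if (!changed) break
  }
  f
}

# literal per-cell argmax of drop/distance over the 8 neighbours
oracle_d8 <- function(z, cs) {
  nr <- nrow(z); nc <- ncol(z)
  out <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    if (is.na(z[r, co])) { out[r, co] <- NA_integer_; next }
    best <- 0; bk <- 0L
    for (k in 1:8) {
      rr <- r + .o_dr[k]; cc <- co + .o_dc[k]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || is.na(z[rr, cc])) next
      drop <- (z[r, co] - z[rr, cc]) / (cs * .o_dist[k])
      if (drop > best) { best <- drop; bk <- k }
    }
    out[r, co] <- bk
  }
  out
}

# follow the direction codes from (r, c) and return the linear indices of
# every cell on the path, the start included
oracle_trace <- function(dirs, r, co) {
  nr <- nrow(dirs)
  path <- integer(0)
  repeat {
    path <- c(path, (co - 1L) * nr + r)
    k <- dirs[r, co]
    if (is.na(k) || k == 0L) break
    r <- r + .o_dr[k]; co <- co + .o_dc[k]
  }
  path
}

# contributing area by counting, for every cell, the cells whose traced
# path passes through it (self-inclusive)
oracle_accumulation <- function(dirs, cs) {
  nr <- nrow(dirs); nc <- ncol(dirs)
  count <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    if (is.na(dirs[r, co])) next
    count[oracle_trace(dirs, r, co)] <- count[oracle_trace(dirs, r, co)] + 1
  }
  count[is.na(dirs)] <- NA
  count * cs^2
}

# catchment membership by tracing every cell's path to see if it visits
# the outlet
oracle_catchment <- function(dirs, outlet) {
  nr <- nrow(dirs); nc <- ncol(dirs)
  target <- (outlet[2] - 1L) * nr + outlet[1]
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (co in seq_len(nc)) {
    if (is.na(dirs[r, co])) { out[r, co] <- NA; next }
    if (target %in% oracle_trace(dirs, r, co)) out[r, co] <- 1
  }
  out
}

# linear-interpolation (type 7) quantile from the sorted array, written
# out longhand
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# closed-form simple OLS via the normal equations, with textbook interval
# formulas
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b <- sum((x - mean(x)) * (y - mean(y))) / sxx
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  s2 <- ss_res / (n - 2)
  f <- (ss_tot - ss_res) / s2
  list(a = a, b = b, r2 = r2, f = f, s2 = s2, sxx = sxx, n = n,
       ci = function(x0, level = 0.95) {
         se <- sqrt(s2 * (1 / n + (x0 - mean(x))^2 / sxx))
         tq <- qt(1 - (1 - level) / 2, n - 2)
         c(a + b * x0 - tq * se, a + b * x0 + tq * se)
       },
       pi = function(x0, level = 0.95) {
         se <- sqrt(s2 * (1 + 1 / n + (x0 - mean(x))^2 / sxx))
         tq <- qt(1 - (1 - level) / 2, n - 2)
         c(a + b * x0 - tq * se, a + b * x0 + tq * se)
       })
}

# rough random terrain for routing tests: smooth ramp plus noise
random_dem <- function(nr, nc, seed, relief = 3) {
  set.seed(seed)
  ramp <- outer(seq(relief, 0, length.out = nr), seq(relief, 0, length.out = nc), "+")
  raster_grid(ramp + matrix(runif(nr * nc, 0, relief / 2), nr, nc), 1,
              units = "m elevation")
}
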