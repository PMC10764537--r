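test_that("fill_sinks leaves drainable terrain alone and raises pits to pour level", {
  plane <- raster_grid(outer(seq(5, 1, length.out = 5),
                             seq(3, 0, length.out = 6), "+"), 1)
  expect_equal(fill_sinks(plane)$values, plane$values)

  pit <- raster_grid(matrix(c(5, 5, 5, 5, 1, 5, 5, 5, 5), 3, 3), 1)
  filled <- fill_sinks(pit)
  expect_equal(filled$values[2, 2], 5 + 1e-5, tolerance = 1e-12)

  expect_error(fill_sinks(raster_grid(matrix(NA_real_, 3, 3), 1)), "nodata")
})

test_that("fill_sinks agrees with the iterative flooding fixpoint and is idempotent", {
  dem <- random_dem(30, 30, seed = 11)
  # add closed depressions so the fill has real work to do
  dem$values[8:10, 8:10] <- dem$values[8:10, 8:10] - 2
  dem$values[20:24, 15:18] <- dem$values[20:24, 15:18] - 3
  filled <- fill_sinks(dem)
  expect_true(all(filled$values >= dem$values - 1e-12))
  expect_equal(filled$values, oracle_fill(dem$values), tolerance = 1e-12)
  expect_equal(fill_sinks(filled)$values, filled$values, tolerance = 1e-12)
})

test_that("D8 directions follow the steepest descent with the documented tie-break", {
  # plane dipping east: every interior cell points E (code 1)
  east <- raster_grid(matrix(rep(seq(10, 2, length.out = 6), each = 5), 5, 6), 1)
  fd <- d8_flow_direction(east)
  expect_true(all(fd$directions[, 1:5] == 1L))
  expect_true(all(fd$directions[, 6] == 0L))   # east edge cells are outlets

  # symmetric peak: the four cardinal drops tie exactly, first in the fixed
  # E, SE, S, SW, W, NW, N, NE order wins (E)
  z <- matrix(12, 3, 3)
  z[2, 2] <- 10
  z[cbind(c(2, 3, 2, 1), c(3, 2, 1, 2))] <- 8
  fd <- d8_flow_direction(raster_grid(z, 1))
  expect_equal(fd$directions[2, 2], 1L)

  dem <- fill_sinks(random_dem(20, 20, seed = 5))
  fd <- d8_flow_direction(dem)
  expect_equal(fd$directions, oracle_d8(dem$values, 1))
})

test_that("flow accumulation is self-inclusive and matches upstream-set counting", {
  single <- raster_grid(matrix(5, 1, 1), 2)
  fa <- flow_accumulation(d8_flow_direction(single))
  expect_equal(fa$values[1, 1], 4)   # one 2 m cell: its own area

  row5 <- raster_grid(matrix(seq(5, 1), 1, 5), 1)
  fa <- flow_accumulation(d8_flow_direction(row5))
  expect_equal(as.numeric(fa$values), c(1, 2, 3, 4, 5))

  dem <- fill_sinks(random_dem(25, 25, seed = 2))
  fd <- d8_flow_direction(dem)
  fa <- flow_accumulation(fd)
  expect_equal(fa$values, oracle_accumulation(fd$directions, 1))
})

test_that("accumulation conserves area and never decreases downstream", {
  dem <- fill_sinks(random_dem(18, 22, seed = 21))
  fd <- d8_flow_direction(dem)
  fa <- flow_accumulation(fd)
  # conservation: outlet areas partition the full grid
  expect_equal(sum(fa$values[fd$directions == 0L]), 18 * 22)
  # monotonicity along every traced path
  for (start in c(1, 50, 137, 300)) {
    path <- oracle_trace(fd$directions, ((start - 1) %% 18) + 1,
                         ((start - 1) %/% 18) + 1)
    expect_true(all(diff(fa$values[path]) >= 0))
  }
})

test_that("slope in m/km matches analytic gradients and applies the floor", {
  # z = 0.01 * x: slope 10 m/km everywhere away from edge effects
  xs <- matrix(rep((1:20 - 0.5) * 0.01, each = 20), 20, 20)
  sl <- slope_m_per_km(raster_grid(xs, 1))
  expect_equal(sl$values[5:15, 5:15], matrix(10, 11, 11), tolerance = 1e-9)

  flat <- slope_m_per_km(raster_grid(matrix(3, 5, 5), 1), s_min = 0.1)
  expect_true(all(flat$values == 0.1))

  # smooth random cubic surface: Horn within 5% of the analytic gradient
  # (slope magnitude does not depend on axis orientation, so the surface is
  # written directly in row/column metres)
  set.seed(9)
  cf <- runif(6, 0.5, 1.5) * c(0.02, 0.03, 1e-4, 1e-4, 1e-6, 1e-6)
  n <- 30
  f <- function(r, co) cf[1] * co + cf[2] * r + cf[3] * r * co +
    cf[4] * co^2 + cf[5] * co^3 + cf[6] * r^3
  gc_ <- function(r, co) cf[1] + cf[3] * r + 2 * cf[4] * co + 3 * cf[5] * co^2
  gr_ <- function(r, co) cf[2] + cf[3] * co + 3 * cf[6] * r^2
  rc <- (1:n) - 0.5
  z <- outer(rc, rc, f)
  analytic <- outer(rc, rc, function(r, co) sqrt(gc_(r, co)^2 + gr_(r, co)^2)) * 1000
  sl <- slope_m_per_km(raster_grid(z, 1))
  interior <- 3:(n - 2)
  rel <- abs(sl$values[interior, interior] / analytic[interior, interior] - 1)
  expect_lt(max(rel), 0.05)

  expect_error(slope_m_per_km(raster_grid(matrix(1, 2, 2), 1)), "3 x 3")
})

test_that("flowline extraction cuts at the threshold and splits at junctions", {
  row5 <- raster_grid(matrix(seq(5, 1), 1, 5), 1)
  fd <- d8_flow_direction(row5)
  fa <- flow_accumulation(fd)
  net <- extract_flowlines(fa, fd, 3)
  expect_length(net$chains, 1)
  expect_equal(net$chains[[1]]$area_m2, c(3, 4, 5))

  expect_length(extract_flowlines(fa, fd, 99)$chains, 0)

  dem <- y_valley_dem()
  fd <- d8_flow_direction(fill_sinks(dem))
  fa <- flow_accumulation(fd)
  net <- extract_flowlines(fa, fd, y_valley_threshold)
  expect_length(net$chains, 3)
  key <- vapply(net$chains, function(ch) paste(ch$row, ch$col, sep = ",", collapse = ";"), "")
  expect_setequal(key, c("2,3;3,4;4,5", "6,3;5,4;4,5", "4,5;4,6;4,7;4,8;4,9"))
})

test_that("catchment delineation matches brute-force path tracing", {
  # bowl: everything drains to the single lowest edge cell
  bowl <- raster_grid(outer((1:9 - 5)^2, (1:9 - 9)^2 / 4, "+"), 1)
  fd <- d8_flow_direction(fill_sinks(bowl))
  mask <- delineate_catchment(fd, c(5, 9))
  expect_true(all(mask$values == 1))

  # a local high point has no upstream cells
  dem <- fill_sinks(random_dem(20, 20, seed = 6))
  fd <- d8_flow_direction(dem)
  ridge <- which(oracle_accumulation(fd$directions, 1) == 1, arr.ind = TRUE)[1, ]
  mask <- delineate_catchment(fd, ridge)
  expect_equal(sum(mask$values), 1)

  out_cell <- which(fd$directions == 0L, arr.ind = TRUE)[1, ]
  mask <- delineate_catchment(fd, out_cell)
  expect_equal(mask$values, oracle_catchment(fd$directions, out_cell))

  expect_error(delineate_catchment(fd, c(0, 5)), "valid")
})

test_that("routing stack equals brute-force oracles on many random grids", {
  for (seed in 1:15) {
    dem <- random_dem(10, 10, seed = seed, relief = 2)
    filled <- fill_sinks(dem)
    expect_equal(fill_sinks(filled)$values, filled$values, tolerance = 1e-12)
    fd <- d8_flow_direction(filled)
    expect_equal(fd$directions, oracle_d8(filled$values, 1))
    fa <- flow_accumulation(fd)
    expect_equal(fa$values, oracle_accumulation(fd$directions, 1))
    out_cell <- which(fd$directions == 0L, arr.ind = TRUE)[1, ]
    expect_equal(delineate_catchment(fd, out_cell)$values,
                 oracle_catchment(fd$directions, out_cell))
  }
})
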