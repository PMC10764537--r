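test_that("climatic K is the effective-rainfall ratio and rounds to tabulated values", {
  expect_equal(round(climatic_k(1194, 907), 2), 1.32)
  expect_equal(round(climatic_k(1586, 907), 2), 1.75)
  expect_equal(round(climatic_k(900, 907), 2), 0.99)
  expect_equal(climatic_k(907, 907), 1)
  # full precision is carried internally
  expect_equal(climatic_k(1194, 907), 1194 / 907)
  expect_error(climatic_k(-10, 907), "positive")
  expect_error(climatic_k(1000, 0), "positive")
  sc <- site_climate(1465, 558)
  expect_equal(sc$effective_rainfall_mm_yr, 907)
  expect_equal(sc$k_factor, 1)
})

test_that("flowline sampling spaces points by arc length with host-cell areas", {
  row13 <- raster_grid(matrix(seq(13, 1), 1, 13), 1)
  fd <- d8_flow_direction(row13)
  fa <- flow_accumulation(fd)
  net <- extract_flowlines(fa, fd, 1)    # whole 13-cell row, 12 m of arc
  pts <- sample_flowline_area(net, 5)
  expect_equal(nrow(pts), 3)             # arc lengths 0, 5, 10
  expect_equal(pts$area_m2, c(1, 6, 11))

  # degenerate single-cell chain: one point at the head
  net1 <- extract_flowlines(fa, fd, 13)
  expect_equal(nrow(net1$chains[[1]]), 1)
  expect_equal(nrow(sample_flowline_area(net1, 5)), 1)

  # Y-network: point count is sum over chains of floor(length/5) + 1
  dem <- y_valley_dem()
  fd <- d8_flow_direction(fill_sinks(dem))
  net <- extract_flowlines(flow_accumulation(fd), fd, y_valley_threshold)
  pts <- sample_flowline_area(net, 5)
  expected <- sum(vapply(net$chains, function(ch) {
    len <- sum(sqrt(diff(ch$x)^2 + diff(ch$y)^2))
    floor(len / 5) + 1
  }, 0))
  expect_equal(nrow(pts), expected)
})

test_that("Sibson interpolation is exact at samples and has linear precision", {
  set.seed(42)
  px <- runif(40, 0, 10); py <- runif(40, 0, 10)
  pv <- 2 * px + 3 * py
  out <- sibson_interpolate(px, py, pv, px[1:10], py[1:10])
  expect_equal(out, pv[1:10], ignore_attr = TRUE)

  qx <- runif(60, 3, 7); qy <- runif(60, 3, 7)
  out <- sibson_interpolate(px, py, pv, qx, qy)
  expect_lt(max(abs(out - (2 * qx + 3 * qy)) / abs(2 * qx + 3 * qy)), 1e-6)

  # four unit-square corners, centre query: symmetry gives the plain mean
  expect_equal(sibson_interpolate(c(0, 1, 1, 0), c(0, 0, 1, 1),
                                  c(1, 2, 3, 4), 0.5, 0.5),
               2.5, ignore_attr = TRUE)

  # values stay within the sample range
  pv2 <- runif(40)
  o <- sibson_interpolate(px, py, pv2, runif(100, 0, 10), runif(100, 0, 10))
  expect_gte(min(o), min(pv2) - 1e-9)
  expect_lte(max(o), max(pv2) + 1e-9)
})

test_that("degenerate sample sets fall back to nearest-sample with a warning", {
  expect_warning(o <- sibson_interpolate(c(0, 1), c(0, 0), c(5, 9), 0.2, 3),
                 "nearest")
  expect_equal(o, 5, ignore_attr = TRUE)
  expect_warning(o <- sibson_interpolate(c(0, 1, 2), c(0, 1, 2), c(1, 2, 3),
                                         c(0.1, 1.9), c(0.1, 1.9)),
                 "collinear")
  expect_equal(o, c(1, 3), ignore_attr = TRUE)
})

test_that("MFAC arithmetic, units and scaling follow the defining equation", {
  A <- raster_grid(matrix(25, 4, 4), 1, units = "m2 area")
  s <- raster_grid(matrix(5, 4, 4), 1, units = "m/km slope")
  surf <- compute_mfac(A, s, k = 1, stream_threshold_m2 = 1e6)
  expect_equal(surf$mfac$values, matrix(1, 4, 4))  # sqrt(25)/5 = 1 km

  set.seed(15)
  Ar <- raster_grid(matrix(runif(100, 1, 400), 10, 10), 1)
  sr <- raster_grid(matrix(runif(100, 0.5, 30), 10, 10), 1)
  base <- compute_mfac(Ar, sr, 1, 1e6)$mfac$values
  expect_equal(compute_mfac(Ar, sr, 2, 1e6)$mfac$values, 2 * base)
  half_s <- raster_grid(sr$values / 2, 1)
  expect_equal(compute_mfac(Ar, half_s, 1, 1e6)$mfac$values, 2 * base)

  expect_error(compute_mfac(Ar, raster_grid(matrix(1, 5, 5), 1), 1, 1e6),
               "footprint")
  expect_error(compute_mfac(Ar, sr, 0, 1e6), "positive")
})

test_that("a uniform tilted-plane flow column reproduces the hand calculation", {
  # single 400-cell column at 1 m cells, accumulation 1..400 m^2 downslope,
  # uniform slope 10 m/km, K = 1: foot MFAC = sqrt(400)/10 = 2 km
  A <- raster_grid(matrix(as.numeric(1:400), 400, 1), 1)
  s <- raster_grid(matrix(10, 400, 1), 1)
  surf <- compute_mfac(A, s, 1, stream_threshold_m2 = 1e6)
  expect_equal(surf$mfac$values[400, 1], 2)
  # MFAC rises monotonically downslope until the stream threshold truncates
  expect_true(all(diff(surf$mfac$values[, 1]) > 0))
  surf2 <- compute_mfac(A, s, 1, stream_threshold_m2 = 300)
  expect_true(all(is.na(surf2$mfac$values[300:400, 1])))
  expect_true(all(!is.na(surf2$mfac$values[1:299, 1])))
})

test_that("stream masking removes channel cells and sample points", {
  A <- raster_grid(matrix(rep(c(10, 50, 2000), each = 2), 2, 3), 1)
  s <- raster_grid(matrix(5, 2, 3), 1)
  surf <- compute_mfac(A, s, 1, stream_threshold_m2 = 1000)
  expect_true(all(is.na(surf$mfac$values[, 3])))
  expect_true(all(surf$stream_mask[, 3]))
  expect_true(all(!is.na(surf$mfac$values[, 1:2])))
  # no unmasked cell carries A at or above the threshold
  expect_true(all(A$values[!surf$stream_mask] < 1000))

  pts <- data.frame(x = c(0.5, 1.5, 2.5), y = c(0.5, 0.5, 0.5),
                    area_m2 = c(10, 50, 2000))
  target <- raster_grid(matrix(0, 2, 3), 1)
  suppressWarnings(out <- interpolate_area_nn(pts, target,
                                              stream_threshold = 1000))
  expect_lt(max(out$values), 1000)  # channel sample excluded from inputs
})

test_that("classification uses left-closed bins and the tabulated bands", {
  mk <- function(vals) {
    A <- raster_grid(matrix(vals^2 * 25, 1, length(vals)), 1)  # s=5, K=1
    s <- raster_grid(matrix(5, 1, length(vals)), 1)
    classify_mfac(compute_mfac(A, s, 1, 1e9))
  }
  surf <- mk(c(3, 2, 0.3, 5, 0.5, 1))
  expect_equal(as.character(surf$class_labels),
               c("2-5", "2-5", "0-0.5", ">5", "0.5-1", "1-2"))
  sch <- mfac_class_scheme()
  expect_equal(sch$predicted_d90_cm_band[sch$label == "2-5"], "13-20")
  expect_equal(sch$predicted_d90_cm_band[sch$label == "0-0.5"], ">=30")
})

test_that("class area distribution counts cells and is scale invariant", {
  A <- raster_grid(matrix(25, 3, 3), 1)
  s <- raster_grid(matrix(5, 3, 3), 1)
  surf <- classify_mfac(compute_mfac(A, s, 1, 1e9))
  d <- class_area_distribution(surf)
  expect_equal(d$percent[d$label == "1-2"], 100)
  expect_equal(sum(d$percent), 100)

  set.seed(8)
  vals <- runif(400, 0.05, 8)
  for (cs in c(1, 5)) {
    A <- raster_grid(matrix(vals^2 * 25, 20, 20), cs)
    s <- raster_grid(matrix(5, 20, 20), cs)
    surf <- classify_mfac(compute_mfac(A, s, 1, 1e9))
    d <- class_area_distribution(surf)
    counts <- table(cut(vals, c(0, 0.5, 1, 2, 5, Inf), right = FALSE))
    expect_equal(d$percent, as.numeric(counts) / 4, tolerance = 1e-12)
    expect_equal(sum(d$percent), 100)
  }
})
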