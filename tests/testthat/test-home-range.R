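# MCP, href bandwidth, kernel UD, contours, area accumulation.

test_that("MCP of a unit square at full retention is 1 ha", {
  fx <- data.frame(x = c(0, 100, 100, 0, 50), y = c(0, 0, 100, 100, 50))
  hr <- mcp(fx, retention = 1)
  expect_equal(hr$area_ha, 1)
  expect_identical(hr$estimator, "MCP100")
})

test_that("MCP95 equals the brute-force quantile-filter + hull oracle", {
  fx <- uniform_fixes(1000)
  hr <- mcp(fx, 0.95)
  # independent oracle: manual type-7 quantile, chull, shoelace
  cx <- mean(fx$x); cy <- mean(fx$y)
  d <- sqrt((fx$x - cx)^2 + (fx$y - cy)^2)
  ds <- sort(d)
  h <- (length(d) - 1) * 0.95 + 1
  thr <- ds[floor(h)] + (h - floor(h)) * (ds[ceiling(h)] - ds[floor(h)])
  keep <- d <= thr
  idx <- chull(fx$x[keep], fx$y[keep])
  ring_x <- fx$x[keep][c(idx, idx[1])]; ring_y <- fx$y[keep][c(idx, idx[1])]
  expect_equal(hr$area_ha, oracle_ring_area(ring_x, ring_y) / 1e4,
               tolerance = 1e-12)
  expect_identical(hr$n_used, sum(keep))
})

test_that("MCP rejects degenerate geometry and needs 5 fixes", {
  fx <- data.frame(x = c(1, 1, 1, 1, 1), y = c(1, 2, 3, 4, 5))
  expect_error(mcp(fx, 1), "degenerate")
  expect_error(mcp(data.frame(x = 1:3, y = c(1, 5, 2))), "nrow")
})

test_that("MCP area is invariant under rigid rotation", {
  fx <- uniform_fixes(300)
  a0 <- mcp(fx)$area_ha
  th <- riparia:::deg2rad(37)
  rot <- data.frame(x = fx$x * cos(th) - fx$y * sin(th),
                    y = fx$x * sin(th) + fx$y * cos(th))
  expect_equal(mcp(rot)$area_ha, a0, tolerance = 1e-9)
})

test_that("href follows the bivariate normal-reference closed form", {
  # var(x) = var(y) = 1e4 m^2 and n = 64 give h = 100 * 64^(-1/6) = 50
  set.seed(2)
  z <- scale(rnorm(64)) * 100
  w <- scale(rnorm(64)) * 100
  fx <- data.frame(x = as.numeric(z), y = as.numeric(w))
  expect_equal(href_bandwidth(fx), 50, tolerance = 1e-9)
  # doubling coordinates doubles h
  expect_equal(href_bandwidth(data.frame(x = 2 * fx$x, y = 2 * fx$y)), 100,
               tolerance = 1e-9)
  # h decreases monotonically with n at fixed spread
  hs <- vapply(c(16, 64, 256), function(n) {
    sqrt((1e4 + 1e4) / 2) * n^(-1 / 6)
  }, 0)
  expect_true(all(diff(hs) < 0))
  expect_error(href_bandwidth(data.frame(x = c(1, 1), y = c(2, 2))), "spread")
})

test_that("kernel UD normalizes, peaks at a lone fix, and guards its grid", {
  fx1 <- data.frame(x = 500, y = 500)
  ud <- kernel_ud(fx1, h = 30, cell_size = 5)
  expect_equal(sum(ud$density) * ud$cell_size^2, 1, tolerance = 1e-6)
  peak <- which(ud$density == max(ud$density), arr.ind = TRUE)
  gx <- ud$origin[1] + (peak[1] - 0.5) * ud$cell_size
  gy <- ud$origin[2] + (peak[2] - 0.5) * ud$cell_size
  expect_lt(max(abs(c(gx - 500, gy - 500))), ud$cell_size)

  fx <- uniform_fixes(50)
  expect_equal(sum(kernel_ud(fx)$density) * kernel_ud(fx)$cell_size^2, 1,
               tolerance = 1e-6)
  expect_error(
    kernel_ud(fx, h = 50,
              grid = list(origin = c(0, 0), cell_size = 10, dim = c(10, 10))),
    "grid too small")
})

test_that("K95 on Gaussian fixes matches the smoothed-Gaussian closed form", {
  set.seed(31)
  n <- 2000; sigma <- 100; h <- 50
  fx <- data.frame(x = rnorm(n, 0, sigma), y = rnorm(n, 0, sigma))
  ud <- kernel_ud(fx, h = h, cell_size = 5)
  k95 <- ud_contour(ud, 0.95)
  closed_form <- pi * qchisq(0.95, 2) * (sigma^2 + h^2) / 1e4
  expect_lt(abs(k95$area_ha - closed_form) / closed_form, 0.05)
})

test_that("kernel contours nest and match the grid-quantile oracle", {
  tr <- fixture_track()
  ud <- kernel_ud(tr)
  k50 <- ud_contour(ud, 0.50); k75 <- ud_contour(ud, 0.75)
  k95 <- ud_contour(ud, 0.95)
  expect_true(all(k75$cells[k50$cells]))
  expect_true(all(k95$cells[k75$cells]))
  expect_true(k50$area_ha <= k75$area_ha && k75$area_ha <= k95$area_ha)

  # oracle: the area must equal cell_area times the smallest count of
  # descending-density cells whose mass reaches the level
  dens <- sort(as.vector(ud$density), decreasing = TRUE)
  mass <- cumsum(dens) * ud$cell_size^2
  expect_equal(k75$area_ha, which(mass >= 0.75)[1] * ud$cell_size^2 / 1e4)
})

test_that("a uniform UD at level 0.95 keeps 95 of 100 cells", {
  ud <- structure(list(origin = c(0, 0), cell_size = 10,
                       density = matrix(1 / (100 * 100), 10, 10),
                       h = 10, n = 1),
                  class = "utilization_distribution")
  k <- ud_contour(ud, 0.95)
  expect_identical(sum(k$cells), 95L)
})

test_that("area accumulation saturates for resident but not drifting birds", {
  t0 <- as.POSIXct("2014-08-08 07:00:00", tz = "UTC")
  set.seed(5)
  n_day <- 40; days <- 6
  stamp <- rep(t0 + (0:(days - 1)) * 86400, each = n_day) +
    rep(600 * seq_len(n_day), times = days)
  resident <- data.frame(bird_id = "R", timestamp = stamp,
                         x = rnorm(n_day * days, 0, 80),
                         y = rnorm(n_day * days, 0, 80))
  curve_r <- area_accumulation(resident)
  expect_true(attr(curve_r, "saturated"))

  drift <- resident
  drift$x <- drift$x + seq(0, 4000, length.out = nrow(drift))
  curve_d <- area_accumulation(drift)
  expect_false(attr(curve_d, "saturated"))

  # final point of the curve equals the full-data estimate
  expect_equal(curve_r$mcp_ha[nrow(curve_r)], mcp(resident)$area_ha)
})
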