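# TOA reflectance, vegetation indices, distance rasters.

make_stack <- function(vals) {
  bands <- lapply(vals, function(v) matrix(v, 2, 2))
  raster_stack(bands, origin = c(0, 0), cell_size = 10)
}

test_that("TOA conversion is exact in the identity configuration", {
  st <- make_stack(list(Blue = 0.4, Green = 0.3, Red = 0.2, RedEdge = 0.5,
                        NIR = 0.6))
  cf <- lapply(st$bands, function(b) list(scale = 1, esun = pi))
  out <- toa_reflectance(st, cf, sun_elevation = 90, earth_sun_distance = 1)
  for (b in names(st$bands)) expect_equal(out$bands[[b]], st$bands[[b]])

  # doubling esun halves reflectance
  cf2 <- lapply(st$bands, function(b) list(scale = 1, esun = 2 * pi))
  out2 <- toa_reflectance(st, cf2, 90)
  expect_equal(out2$bands$Blue, out$bands$Blue / 2)

  expect_error(toa_reflectance(st, cf, sun_elevation = 0), "zenith")
  expect_error(toa_reflectance(st, NULL, 45), "coefficients")
  expect_error(toa_reflectance(st, cf[1:3], 45), "missing TOA")
})

test_that("the seven indices follow their printed formulas", {
  st <- make_stack(list(Blue = 0.05, Green = 0.25, Red = 0.2, RedEdge = 0.5,
                        NIR = 0.5))
  out <- vegetation_indices(st)
  g <- function(b) out$bands[[b]][1, 1]
  expect_equal(g("NDVI"), (0.5 - 0.2) / (0.5 + 0.2))       # ~0.4286
  expect_equal(g("REGNDVI"), (0.5 - 0.25) / (0.5 + 0.25))
  expect_equal(g("GNDVI"), (0.5 - 0.25) / (0.5 + 0.25))
  expect_equal(g("NDRE"), 0)                               # NIR = RedEdge
  expect_equal(g("GRM"), 0)
  expect_equal(g("GCM"), 1)                                # NIR / Green - 1
  expect_equal(g("RENDVI"), (0.5 - 0.2) / (0.5 + 0.2))

  # NIR = 0.6, Red = 0.2 -> NDVI = 0.5
  st2 <- make_stack(list(Green = 0.3, Red = 0.2, RedEdge = 0.4, NIR = 0.6))
  expect_equal(vegetation_indices(st2)$bands$NDVI[1, 1], 0.5)
})

test_that("indices are bounded and propagate nodata", {
  set.seed(4)
  st <- make_stack(list(Blue = 0.1, Green = runif(1, 0.01, 1),
                        Red = runif(1, 0.01, 1), RedEdge = runif(1, 0.01, 1),
                        NIR = runif(1, 0.01, 1)))
  out <- vegetation_indices(st)
  for (b in c("NDVI", "REGNDVI", "GNDVI", "NDRE", "RENDVI"))
    expect_true(all(abs(out$bands[[b]]) <= 1))

  zero <- make_stack(list(Green = 0, Red = 0.2, RedEdge = 0.3, NIR = 0))
  z <- vegetation_indices(zero)
  expect_true(all(is.na(z$bands$GCM)))     # NIR / 0
  expect_true(all(is.na(z$bands$GNDVI)))   # 0 / 0

  na_in <- make_stack(list(Green = 0.2, Red = NA_real_, RedEdge = 0.3,
                           NIR = 0.5))
  expect_true(all(is.na(vegetation_indices(na_in)$bands$NDVI)))
})

test_that("distance rasters are exact on simple geometries", {
  map <- tiny_map()   # river along y = 0, settlement point at (150, 150)
  dr <- distance_raster(map, "river")
  # cell centres on the bottom row are 5 m above the river line
  expect_equal(dr$bands[[1]][, 1], rep(5, 20))
  expect_equal(dr$bands[[1]][1, 20], 195)

  ds <- distance_raster(map, "settlement")
  ij <- riparia:::cell_index(map, 145, 145)   # the settlement cell centre
  expect_equal(ds$bands[[1]][ij], 0, tolerance = 1e-9)
  expect_equal(ds$bands[[1]][ij[1], 1], 140)  # straight south of the point

  expect_error(distance_raster(map, "road"), "empty target")
})

test_that("class-distance rasters match a brute-force scan and are Lipschitz", {
  set.seed(12)
  grid <- matrix(2L, 50, 50)
  grid[sample(2500, 40)] <- 1L
  map <- landcover_map(grid, c(0, 0), 10, c("lantana", "crops_high"),
                       river = cbind(x = c(0, 500), y = c(0, 0)))
  d <- distance_raster(map, "lantana")$bands[[1]]

  ctr <- riparia:::grid_centers(map)
  targets <- which(grid == 1L, arr.ind = TRUE)
  tx <- ctr$x[targets[, 1]]; ty <- ctr$y[targets[, 2]]
  for (k in sample(2500, 50)) {
    i <- (k - 1) %% 50 + 1; j <- (k - 1) %/% 50 + 1
    brute <- min(sqrt((ctr$x[i] - tx)^2 + (ctr$y[j] - ty)^2))
    expect_equal(d[i, j], brute, tolerance = 1e-9)
  }
  # 1-Lipschitz across adjacent cells (step <= cell diagonal)
  expect_lte(max(abs(diff(d))), sqrt(2) * 10 + 1e-9)
  expect_lte(max(abs(diff(t(d)))), sqrt(2) * 10 + 1e-9)
})
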