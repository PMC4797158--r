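# Generators: landscapes, tracks, bearings, reflectance rasters.

test_that("landscape generation is deterministic and hits its target mix", {
  s <- landscape_spec(seed = 3)
  m1 <- generate_landscape(s)
  m2 <- generate_landscape(s)
  expect_identical(m1$grid, m2$grid)
  expect_identical(m1$river, m2$river)

  # realized fractions within 20% relative of targets (area-summation oracle:
  # direct cell counting against the class grid)
  tab <- table(factor(m1$class_levels[m1$grid], levels = m1$class_levels))
  frac <- as.numeric(tab) / sum(tab)
  names(frac) <- names(tab)
  for (cls in names(s$class_mix)) {
    expect_lt(abs(frac[cls] - s$class_mix[cls]) / s$class_mix[cls], 0.2,
              label = paste("relative error for", cls))
  }
  # composition table agrees with the counting oracle
  comp <- landscape_composition(m1)
  expect_equal(comp$pct[match(names(tab), comp$class)] / 100,
               as.numeric(frac), tolerance = 1e-12)
  expect_equal(sum(comp$pct), 100, tolerance = 0.2)
})

test_that("a zero lantana fraction yields a lantana-free map", {
  mix <- c(indigenous = 0.01, mixed = 0.03, lantana = 0,
           crops_low = 0.09, settlement = 0.04)
  m <- generate_landscape(landscape_spec(class_mix = mix, seed = 5))
  expect_false("lantana" %in% m$class_levels[unique(as.vector(m$grid))])
  expect_null(landcover_polygons(m)$lantana)
})

test_that("an infeasible class mix is rejected", {
  expect_error(landscape_spec(class_mix = c(lantana = 0.7, crops_low = 0.5)),
               "infeasible")
})

test_that("thicket concentrates near the river", {
  m <- fixture_map()
  ctr <- riparia:::grid_centers(m)
  d <- dim(m$grid)
  px <- rep(ctr$x, times = d[2]); py <- rep(ctr$y, each = d[1])
  dist <- riparia:::dist_to_polyline(px, py, m$river)
  thicket <- m$class_levels[m$grid] %in% c("lantana", "mixed", "indigenous")
  expect_lt(median(dist[thicket]), median(dist[!thicket]))
  # the bulk of the thicket lies inside the corridor (spill-over is allowed)
  expect_gt(mean(dist[thicket] <= 400), 0.9)
})

test_that("tracks are deterministic, evenly sampled, and extent-bounded", {
  map <- fixture_map()
  sp <- movement_spec(n_fixes = 100, seed = 21)
  t1 <- generate_track(map, sp, "A")
  t2 <- generate_track(map, sp, "A")
  expect_identical(t1$fixes, t2$fixes)
  expect_true(all(t1$steps$dt_min == 10))
  ext <- riparia:::map_extent(map)
  expect_true(all(t1$fixes$x >= ext[1] & t1$fixes$x <= ext[2]))
  expect_true(all(t1$fixes$y >= ext[3] & t1$fixes$y <= ext[4]))
})

test_that("per-habitat step-length means are recovered from a long track", {
  map <- fixture_map()
  tr <- generate_track(map, movement_spec(n_fixes = 2000, seed = 9), "L")
  mv <- movement_by_habitat(tr, map)
  means <- tapply(mv$dist_per_10min, mv$habitat, mean)
  ns <- table(mv$habitat)
  spec_means <- movement_spec()$step_mean
  for (cls in c("lantana", "crops_high")) {   # the two well-sampled classes
    expect_gt(ns[cls], 50)
    expect_lt(abs(means[cls] - spec_means[cls]) / spec_means[cls], 0.10,
              label = paste("step-mean recovery for", cls))
  }
})

test_that("equal step means and no biases give habitat-independent steps", {
  map <- fixture_map()
  sp <- movement_spec(
    step_mean = c(lantana = 250, mixed = 250, crops_low = 250,
                  crops_high = 250, indigenous = 250, settlement = 250),
    river_attraction = 0, home_radius = Inf,
    habitat_weight = c(lantana = 1, mixed = 1, crops_low = 1,
                       crops_high = 1, indigenous = 1, settlement = 1),
    n_fixes = 2000, start = c(1000, 1000), seed = 33)
  mv <- movement_by_habitat(generate_track(map, sp, "N"), map)
  g <- split(mv$dist_per_10min, mv$habitat)
  g <- g[vapply(g, length, 0L) > 50]
  expect_gte(length(g), 2)
  # two-sample location test between the two largest classes
  big <- names(sort(vapply(g, length, 0L), decreasing = TRUE))[1:2]
  expect_gt(t.test(g[[big[1]]], g[[big[2]]])$p.value, 0.01)
})

test_that("river attraction pulls fixes toward the river", {
  map <- fixture_map()
  base <- movement_spec(river_attraction = 0, home_radius = Inf,
                        habitat_weight = c(lantana = 1, mixed = 1,
                                           crops_low = 1, crops_high = 1,
                                           indigenous = 1, settlement = 1),
                        n_fixes = 600, start = c(1000, 1500), seed = 44)
  pull <- base; pull$river_attraction <- 1.5
  t0 <- generate_track(map, base, "C")
  t1 <- generate_track(map, pull, "R")
  d0 <- riparia:::dist_to_polyline(t0$fixes$x, t0$fixes$y, map$river)
  d1 <- riparia:::dist_to_polyline(t1$fixes$x, t1$fixes$y, map$river)
  expect_lt(median(d1), median(d0))
})

test_that("bearings invert to the generating fixes at zero noise", {
  tr <- fixture_track()
  be <- generate_bearings(tr, c(-200, 1000), c(2200, 900), noise_sd_deg = 0)
  expect_equal(nrow(be), nrow(tr$fixes))
  expect_true(all(be$obs_a_az >= 0 & be$obs_a_az < 360))
  fx <- triangulate_bearings(be)
  expect_true(all(fx$valid))
  expect_lt(max(abs(fx$x - tr$fixes$x)), 1e-6)
  expect_lt(max(abs(fx$y - tr$fixes$y)), 1e-6)
})

test_that("bearing noise and seed behave as expected", {
  tr <- fixture_track()
  b1 <- generate_bearings(tr, c(0, 0), c(2000, 0), noise_sd_deg = 2, seed = 8)
  b2 <- generate_bearings(tr, c(0, 0), c(2000, 0), noise_sd_deg = 2, seed = 8)
  expect_identical(b1, b2)
  expect_error(generate_bearings(tr, c(5, 5), c(5, 5), 0), "co-located")

  # triangulation error grows with fix-observer distance (geometry of
  # bearing error): compare near vs far halves by observer-a distance
  fx <- triangulate_bearings(b1)
  err <- sqrt((fx$x - tr$fixes$x)^2 + (fx$y - tr$fixes$y)^2)
  ok <- fx$valid
  near <- fx$dist_a[ok] <= median(fx$dist_a[ok])
  expect_lt(median(err[ok][near]), median(err[ok][!near]))
})

test_that("reflectance rasters are class-exact at zero noise and seeded", {
  map <- tiny_map()
  sp0 <- spectral_spec(noise_sd = 0, seed = 2)
  st <- generate_raster(map, sp0)
  expect_identical(names(st$bands), c("Blue", "Green", "Red", "RedEdge", "NIR"))
  lant <- map$grid == 1L
  for (b in names(st$bands)) {
    expect_true(all(st$bands[[b]][lant] == sp0$means["lantana", b]))
    expect_true(all(st$bands[[b]][!lant] == sp0$means["crops_high", b]))
  }
  spn <- spectral_spec(noise_sd = 0.02, seed = 2)
  expect_identical(generate_raster(map, spn), generate_raster(map, spn))
  r <- generate_raster(map, spn)
  expect_true(all(unlist(r$bands) >= 0 & unlist(r$bands) <= 1))
})
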