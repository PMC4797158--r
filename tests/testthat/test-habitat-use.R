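# Jacobs index, sign test, habitat fractions, movement samples, ANOVA,
# landscape composition.

test_that("Jacobs index reproduces its limits and printed formula", {
  expect_equal(jacobs_index(0.3, 0.3), 0)
  expect_equal(jacobs_index(1, 0.5), 1)
  expect_equal(jacobs_index(0, 0.5), -1)
  expect_equal(jacobs_index(0.6, 0.3), 0.5556, tolerance = 1e-4)
  expect_warning(out <- jacobs_index(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("Jacobs index is antisymmetric and monotone in use", {
  set.seed(9)
  r <- runif(50, 0.01, 0.99); p <- runif(50, 0.01, 0.99)
  expect_equal(jacobs_index(r, p), -jacobs_index(p, r), tolerance = 1e-12)
  expect_true(all(jacobs_index(r, p) >= -1 & jacobs_index(r, p) <= 1))
  for (pp in c(0.2, 0.5, 0.8)) {
    d <- jacobs_index(seq(0.01, 0.99, 0.01), pp)
    expect_true(all(diff(d) > 0), label = paste("monotone at p =", pp))
  }
})

test_that("sign test matches exhaustive binomial enumeration", {
  # closed-form checks
  expect_equal(sign_test(rep(1, 14))$p_value, 2 * 0.5^14, tolerance = 1e-10)
  expect_equal(sign_test(c(1, 1, 1, -1))$p_value, 0.625, tolerance = 1e-12)
  expect_equal(sign_test(5)$p_value, 1)
  expect_true(is.na(sign_test(c(0, 0))$p_value))
  # zeros are dropped before counting
  expect_identical(sign_test(c(0, 1, 1, -1))$n, 3L)

  # enumeration oracle for all s at n <= 12: two-sided exact p as the total
  # probability of outcomes no more likely than the observed count
  for (n in c(3, 7, 12)) {
    probs <- dbinom(0:n, n, 0.5)
    for (s in 0:n) {
      p_oracle <- sum(probs[probs <= probs[s + 1] + 1e-12])
      vals <- c(rep(1, s), rep(-1, n - s))
      expect_equal(sign_test(vals)$p_value, p_oracle, tolerance = 1e-9,
                   label = paste("n =", n, "s =", s))
    }
  }
})

test_that("habitat fractions match polygon geometry on a known map", {
  map <- tiny_map()   # west half lantana, east half crops_high, 200 m square
  inside <- cbind(x = c(20, 80, 80, 20, 20), y = c(20, 20, 80, 80, 20))
  f1 <- habitat_fractions(inside, map)
  expect_equal(unname(f1["lantana"]), 1)

  straddle <- cbind(x = c(50, 150, 150, 50, 50), y = c(20, 20, 180, 180, 20))
  f2 <- habitat_fractions(straddle, map)
  expect_equal(unname(f2["lantana"]), 0.5, tolerance = 1e-9)
  expect_equal(unname(f2["crops_high"]), 0.5, tolerance = 1e-9)

  expect_error(habitat_fractions(
    cbind(x = c(1e5, 1e5 + 1, 1e5, 1e5), y = c(0, 0, 1, 0)), map))
})

test_that("movement samples normalize to m per 10 min and obey the gap rule", {
  t0 <- as.POSIXct("2014-08-08 07:00:00", tz = "UTC")
  fx <- data.frame(bird_id = "b",
                   timestamp = t0 + c(0, 600, 1800, 2400),
                   x = c(10, 160, 160, 460), y = c(10, 10, 10, 10))
  tr <- build_trajectory(fx)
  mv <- movement_by_habitat(tr, tiny_map())
  # steps: 150 m in 10 min (kept), 0 m in 20 min (gap, dropped),
  # 300 m in 10 min (kept)
  expect_equal(nrow(mv), 2)
  expect_equal(mv$dist_per_10min, c(150, 300))
  # start fixes at x = 10 (west, lantana) and x = 160 (east, crops)
  expect_identical(mv$habitat, c("lantana", "crops_high"))

  # a start fix outside the map is unmapped
  fx2 <- data.frame(bird_id = "b", timestamp = t0 + c(0, 600),
                    x = c(-500, 10), y = c(10, 10))
  mv2 <- movement_by_habitat(build_trajectory(fx2), tiny_map())
  expect_identical(mv2$habitat, "unmapped")
})

test_that("one-way ANOVA matches hand decomposition and handles transforms", {
  res <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$F, 13.5)
  expect_equal(c(res$df1, res$df2), c(1, 4))

  same <- one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$F, 0)

  expect_error(one_way_anova(list(a = c(1, 1), b = c(1, 1))), "variance")
  expect_error(one_way_anova(list(a = 1:3)), "length")

  lg <- one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)), "log1p")
  expect_identical(lg$transform, "log1p")
  expect_equal(lg$F, one_way_anova(list(a = log1p(c(1, 2, 3)),
                                        b = log1p(c(4, 5, 6))))$F)
})

test_that("landscape composition reports hectares and percentages", {
  # one 200 x 200 m map, half lantana: 2 ha each class
  comp <- landscape_composition(tiny_map())
  expect_equal(comp$area_ha[comp$class == "lantana"], 2)
  expect_equal(sum(comp$pct), 100, tolerance = 1e-9)

  # a river buffer restricts the assessed area
  comp_b <- landscape_composition(tiny_map(), buffer_m = 55)
  expect_lt(sum(comp_b$area_ha), sum(comp$area_ha))
  expect_equal(sum(comp_b$pct), 100, tolerance = 1e-9)
})

test_that("printed composition percentages follow from printed hectares", {
  comp <- study_area_composition()
  tot <- sum(comp$area_ha)
  expect_equal(tot, 148.2, tolerance = 1e-9)
  pct <- 100 * comp$area_ha / tot
  expect_equal(round(pct[comp$class == "settlement"], 1), 4.3)
  expect_equal(round(pct[comp$class == "thicket"], 1), 30.1)
})

test_that("tracks biased into lantana prefer it and avoid the crop matrix", {
  map <- fixture_map()
  comp <- landscape_composition(map)
  p <- setNames(comp$pct / 100, comp$class)
  Ds <- t(vapply(1:4, function(b) {
    tr <- generate_track(map, movement_spec(n_fixes = 300, seed = 50 + b),
                         paste0("J", b))
    k75 <- ud_contour(kernel_ud(tr), 0.75, paste0("J", b))
    r <- habitat_fractions(k75, map)
    c(lantana = jacobs_index(r["lantana"], p["lantana"]),
      crops_high = jacobs_index(r["crops_high"], p["crops_high"]))
  }, c(lantana = 0, crops_high = 0)))
  expect_gt(mean(Ds[, "lantana"]), 0)
  expect_lt(mean(Ds[, "crops_high"]), 0)
})
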