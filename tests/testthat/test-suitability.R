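# Maximum-entropy model, AUC, omission threshold, mask chain, sub-models.

test_that("a constant predictor yields the uniform maximum-entropy density", {
  p <- matrix(1, 20, 1, dimnames = list(NULL, "z"))
  b <- matrix(1, 60, 1, dimnames = list(NULL, "z"))
  m <- fit_maxent(p, b)
  expect_equal(predict(m, b, type = "raw"), rep(1 / 60, 60), tolerance = 1e-12)
  expect_equal(predict(m, b, type = "logistic"), rep(0.5, 60),
               tolerance = 1e-9)
})

test_that("raw output sums to one over the background", {
  set.seed(6)
  b <- cbind(z1 = rnorm(400), z2 = runif(400))
  p <- cbind(z1 = rnorm(40, 1), z2 = runif(40, 0.3, 1))
  m <- fit_maxent(p, b)
  expect_equal(sum(predict(m, b, type = "raw")), 1, tolerance = 1e-6)
})

test_that("a separable synthetic presence signal is recovered", {
  set.seed(7)
  b <- cbind(z = rnorm(600))
  p <- cbind(z = rnorm(60, 0))
  p <- p[p[, 1] > 1, , drop = FALSE]
  while (nrow(p) < 25) p <- rbind(p, cbind(z = abs(rnorm(10)) + 1))
  m <- fit_maxent(p, b)
  sb <- predict(m, b); sp <- predict(m, p)
  expect_gt(evaluate_auc(sp, sb), 0.9)
  # fitted response is monotone increasing in z over the data range
  zs <- seq(-2, 2, 0.1)
  resp <- predict(m, cbind(z = zs))
  expect_gt(cor(zs, resp, method = "spearman"), 0.95)
})

test_that("the coordinate-descent fit agrees with a generic optimizer", {
  # 100-cell instance, near-unpenalized; oracle: BFGS on the smooth
  # negative log-likelihood
  set.seed(8)
  b <- cbind(z1 = rnorm(100), z2 = runif(100))
  p <- b[order(b[, 1] + b[, 2], decreasing = TRUE)[1:20], , drop = FALSE]
  m <- fit_maxent(p, b, reg = 1e-8, features = "linear",
                  max_cycles = 2000, tol = 1e-10)
  fx <- m$expansion
  Fp <- riparia:::expand_features(fx, p)
  Fb <- riparia:::expand_features(fx, b)
  nll <- function(l) -mean(Fp %*% l) + log(mean(exp(Fb %*% l)))
  o <- optim(c(0, 0), nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(unname(m$lambda), o$par, tolerance = 1e-3)
})

test_that("increasing L1 regularization is monotone in sparsity", {
  set.seed(9)
  b <- cbind(z1 = rnorm(300), z2 = runif(300), z3 = rnorm(300, 2))
  p <- cbind(z1 = rnorm(40, 0.8), z2 = runif(40, 0.4, 1), z3 = rnorm(40, 2))
  nz <- vapply(c(0.1, 1, 5, 25), function(r)
    sum(fit_maxent(p, b, reg = r)$lambda != 0), 0L)
  expect_true(all(diff(nz) <= 0))
})

test_that("AUC matches exhaustive pairwise comparison", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.4), c(0.7, 0.3, 0.1)), 8 / 9)
  expect_equal(evaluate_auc(c(2, 3), c(0, 1)), 1)
  expect_equal(evaluate_auc(rep(0.5, 4), rep(0.5, 6)), 0.5)

  set.seed(10)
  for (i in 1:5) {
    sp <- round(runif(12), 2); sb <- round(runif(25), 2)
    pairs <- outer(sp, sb, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(evaluate_auc(sp, sb), mean(pairs))
  }
})

test_that("the omission threshold follows the lower-percentile rule", {
  expect_equal(omission_threshold(seq(0.1, 1, 0.1), 10), 0.2)
  expect_equal(omission_threshold(rep(0.37, 15), 10), 0.37)
  expect_equal(omission_threshold(c(0.5, 0.1, 0.9), 0), 0.1)
  # >= 90% of training presences stay above the threshold
  set.seed(11)
  v <- runif(57)
  t10 <- omission_threshold(v, 10)
  expect_gte(mean(v >= t10), 0.9)
  expect_lt(mean(v >= t10 + 1e-9) , 0.9)
})

test_that("the distance-to-river mask excludes far-from-river cells", {
  map <- fixture_map()
  tr <- fixture_track()
  dr <- distance_raster(map, "river")
  msk <- build_mask(tr$fixes, dr, seed = 13)
  band <- dr$bands[[1]]
  expect_true(any(msk$mask))
  expect_lt(mean(band[msk$mask]), mean(band))

  # determinism
  msk2 <- build_mask(tr$fixes, dr, seed = 13)
  expect_identical(msk$mask, msk2$mask)

  # a 0-percentile threshold keeps every cell at least as suitable as the
  # least suitable presence, hence all training cells
  msk0 <- build_mask(tr$fixes, dr, percentile = 0, seed = 13)
  expect_true(all(msk0$mask[msk0$presence_cells]))
})

test_that("the lantana sub-model separates a distinct spectrum", {
  map <- fixture_map()
  st <- vegetation_indices(generate_raster(map, spectral_spec(noise_sd = 0,
                                                              seed = 3)))
  lm0 <- lantana_model(map, st, n_random = 120, seed = 14)
  pr <- as.vector(lm0$prob$bands$lantana_prob)
  lab <- map$class_levels[map$grid] == "lantana"
  expect_gt(evaluate_auc(pr[lab], pr[!lab]), 0.99)

  # identical spectra carry no information
  flat <- spectral_spec(means = matrix(0.4, nrow = 6, ncol = 5,
                                       dimnames = list(rownames(default_spectra()),
                                                       colnames(default_spectra()))),
                        noise_sd = 0.02, seed = 3)
  st2 <- vegetation_indices(generate_raster(map, flat))
  lm2 <- lantana_model(map, st2, n_random = 120, seed = 14)
  pr2 <- as.vector(lm2$prob$bands$lantana_prob)
  expect_lt(abs(evaluate_auc(pr2[lab], pr2[!lab]) - 0.5), 0.1)

  # determinism and input guards
  lm3 <- lantana_model(map, st, n_random = 120, seed = 14)
  expect_identical(lm0$prob$bands$lantana_prob, lm3$prob$bands$lantana_prob)
  expect_error(lantana_model(map, st, n_random = 5), "at least 10")
})

test_that("species models report contributions summing to 100 and stay masked", {
  map <- fixture_map()
  st <- vegetation_indices(generate_raster(map, spectral_spec(seed = 3)))
  trs <- lapply(1:2, function(b)
    generate_track(map, movement_spec(n_fixes = 250, seed = 60 + b),
                   paste0("S", b)))
  pooled <- do.call(rbind, lapply(trs, function(t) t$fixes))
  dr <- distance_raster(map, "river")
  msk <- build_mask(pooled, dr, seed = 15)
  lm0 <- lantana_model(map, st, n_random = 120, seed = 16)
  pb <- st$bands[c("NDVI", "REGNDVI", "GNDVI", "NDRE", "GCM", "GRM", "RENDVI")]
  pb$lantana_prob <- lm0$prob$bands$lantana_prob
  pb$dist_mixed <- distance_raster(map, "mixed")$bands[[1]]
  pb$dist_settlement <- distance_raster(map, "settlement")$bands[[1]]
  preds <- raster_stack(pb, st$origin, st$cell_size)
  sm <- suppressMessages(fit_species_model(pooled, msk, preds,
                                           n_replicates = 3, seed = 17))
  expect_equal(sum(sm$contributions), 100, tolerance = 0.1)
  expect_identical(nrow(sm$replicates), 3L)
  expect_true(all(sm$replicates$n_test >= 4))
  pred <- sm$prediction$bands$suitability
  expect_true(all(is.na(pred[!msk$mask])))
  inside <- pred[msk$mask]
  expect_true(all(is.na(inside) | (inside >= 0 & inside <= 1)))
})
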