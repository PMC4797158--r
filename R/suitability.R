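# Chained habitat-suitability workflow:
#   distance-to-river pre-model -> 10-percentile omission mask ->
#   L. camara spectral sub-model -> per-species masked models with 10x70/30
#   replicate AUC evaluation.

#' Build the distance-to-river mask
#'
#' First stage of the chained suitability design: the environmental background
#' is restricted to the 100% minimum convex polygon enclosing the pooled
#' radio-tracking fixes of all individuals, a maximum-entropy model is fitted
#' with distance to river as single predictor (linear + quadratic features),
#' and the resulting logistic map is binarized with the
#' `percentile`-training-omission threshold. The binary mask confines all
#' later models to the preferred river distances.
#'
#' @param fixes Data.frame of pooled fixes (`x`, `y`) across all individuals.
#' @param dist_river A [distance_raster()] stack for target `"river"`.
#' @param reg Regularization multiplier.
#' @param percentile Training-omission percentile.
#' @param n_background Background sample cap (cells, seeded subsample).
#' @param seed Integer seed.
#' @return An object of class `mask_chain`: `model`, `mask` (logical matrix),
#'   `hull` (background MCP ring), `threshold`, `presence_cells` (training
#'   cell indices), grid metadata.
#' @export
build_mask <- function(fixes, dist_river, reg = 1, percentile = 10,
                       n_background = 10000, seed = NULL) {
  fixes <- as_fix_frame(fixes)
  stopifnot(inherits(dist_river, "raster_stack"))
  band <- dist_river$bands[[1]]
  hull <- convex_hull_ring(fixes$x, fixes$y)
  ctr <- raster_centers(dist_river)
  d <- dim(band)
  px <- rep(ctr$x, times = d[2]); py <- rep(ctr$y, each = d[1])
  inside <- points_in_rings(list(hull), px, py)
  if (!any(inside)) stop("no raster cells inside the pooled MCP")
  bg_idx <- which(inside)
  bg_idx <- sample_cap(bg_idx, n_background, seed)
  bg <- matrix(band[bg_idx], ncol = 1, dimnames = list(NULL, "dist_river"))

  ij <- raster_cell_index(dist_river, fixes$x, fixes$y)
  ok <- !is.na(ij[, 1])
  cell <- unique((ij[ok, 2] - 1L) * d[1] + ij[ok, 1])
  # training cells are those inside the background (fixes on the hull edge
  # can fall into cells whose centre lies just outside the MCP)
  cell <- intersect(cell, which(inside))
  pres <- matrix(band[cell], ncol = 1, dimnames = list(NULL, "dist_river"))

  model <- fit_maxent(pres, bg, reg = reg, features = c("linear", "quadratic"))
  train_pred <- predict(model, pres, type = "logistic")
  thr <- omission_threshold(train_pred, percentile)

  logi <- matrix(NA_real_, d[1], d[2])
  logi[inside] <- predict(model,
    matrix(band[which(inside)], ncol = 1, dimnames = list(NULL, "dist_river")),
    type = "logistic")
  mask <- !is.na(logi) & logi >= thr
  structure(list(model = model, mask = mask, hull = hull, threshold = thr,
                 presence_cells = cell,
                 origin = dist_river$origin, cell_size = dist_river$cell_size,
                 crs = dist_river$crs),
            class = "mask_chain")
}

#' @export
print.mask_chain <- function(x, ...) {
  cat("Distance-to-river mask: threshold", round(x$threshold, 3), ";",
      sum(x$mask), "cells retained\n")
  invisible(x)
}

#' Spectral sub-model of L. camara cover
#'
#' The detailed land-cover map covers only part of the modelled study area, so
#' *L. camara* cover is extrapolated spectrally: presences are random points
#' inside the mapped pure *L. camara* polygons, the background is the whole
#' raster grid, and the predictors are the seven vegetation indices. The
#' logistic probability raster is then used as an environmental predictor in
#' the final species models.
#'
#' @param map A [landcover_map()] with lantana polygons.
#' @param index_stack A [vegetation_indices()] stack.
#' @param n_random Number of random presence points (>= 10).
#' @param reg Regularization multiplier.
#' @param n_background Background sample cap.
#' @param seed Integer seed.
#' @return List of class `lantana_model`: `prob` (single-band
#'   [raster_stack()] `lantana_prob`), `model`, `presence_xy`.
#' @export
lantana_model <- function(map, index_stack, n_random = 500, reg = 1,
                          n_background = 10000, seed = NULL) {
  stopifnot(inherits(map, "landcover_map"), inherits(index_stack, "raster_stack"))
  if (n_random < 10) stop("n_random must be at least 10")
  k <- match("lantana", map$class_levels)
  if (is.na(k) || !any(map$grid == k)) stop("no lantana polygons in the map")
  idx_bands <- c("NDVI", "REGNDVI", "GNDVI", "NDRE", "GCM", "GRM", "RENDVI")
  miss <- setdiff(idx_bands, names(index_stack$bands))
  if (length(miss)) stop("index stack lacks bands: ", paste(miss, collapse = ", "))
  d <- dim(index_stack$bands[[1]])

  with_seed(seed, {
    cells <- which(map$grid == k)
    pick <- cells[sample.int(length(cells), n_random, replace = TRUE)]
    ci <- ((pick - 1) %% nrow(map$grid)) + 1
    cj <- ((pick - 1) %/% nrow(map$grid)) + 1
    pxy <- cbind(
      x = map$origin[1] + (ci - 1 + stats::runif(n_random)) * map$cell_size,
      y = map$origin[2] + (cj - 1 + stats::runif(n_random)) * map$cell_size)

    vals <- raster_values(index_stack, idx_bands)
    ij <- raster_cell_index(index_stack, pxy[, 1], pxy[, 2])
    pres_cell <- (ij[, 2] - 1L) * d[1] + ij[, 1]
    pres <- vals[pres_cell, , drop = FALSE]
    bg_idx <- sample_cap(which(stats::complete.cases(vals)), n_background, NULL)
    bg <- vals[bg_idx, , drop = FALSE]
    model <- fit_maxent(pres[stats::complete.cases(pres), , drop = FALSE], bg,
                        reg = reg)
    prob <- matrix(NA_real_, d[1], d[2])
    okc <- stats::complete.cases(vals)
    prob[okc] <- predict(model, vals[okc, , drop = FALSE], type = "logistic")
    structure(list(
      prob = raster_stack(list(lantana_prob = prob), index_stack$origin,
                          index_stack$cell_size, index_stack$crs),
      model = model, presence_xy = pxy
    ), class = "lantana_model")
  })
}

#' Fit a masked species habitat-suitability model
#'
#' Final stage of the chained design: for one species, presences are the
#' (deduplicated) fix cells inside the intersection of the species' 100% MCP
#' and the distance-to-river mask; the background is the same intersection.
#' Ten replicate models are fitted on random 70/30 presence splits
#' (replicates with fewer than 4 test presences are redrawn), each evaluated
#' by training and test AUC against the background; the reported prediction
#' raster is the mean of the replicate predictions, and per-predictor percent
#' contributions are averaged over replicates.
#'
#' @param fixes Data.frame of the species' fixes (`x`, `y`).
#' @param mask A [build_mask()] result.
#' @param predictors A [raster_stack()] of predictor bands (typically the
#'   seven vegetation indices, the lantana probability, and the distances to
#'   mixed thicket and settlement).
#' @param reg Regularization multiplier.
#' @param n_replicates Number of split replicates.
#' @param split_fraction Training fraction of presences.
#' @param percentile Training-omission percentile for the reported threshold.
#' @param n_background Background sample cap.
#' @param seed Integer seed.
#' @return An object of class `suitability_model`: `replicates` (data.frame of
#'   per-replicate AUCs and thresholds), `mean_test_auc`, `mean_training_auc`,
#'   `threshold`, `contributions` (percent, sums to 100), `prediction`
#'   (single-band [raster_stack()] `suitability`), `n_presence`.
#' @export
fit_species_model <- function(fixes, mask, predictors, reg = 1,
                              n_replicates = 10, split_fraction = 0.7,
                              percentile = 10, n_background = 10000,
                              seed = NULL) {
  fixes <- as_fix_frame(fixes)
  stopifnot(inherits(mask, "mask_chain"), inherits(predictors, "raster_stack"))
  d <- dim(predictors$bands[[1]])
  stopifnot(identical(d, dim(mask$mask)))
  hull <- convex_hull_ring(fixes$x, fixes$y)
  ctr <- raster_centers(predictors)
  px <- rep(ctr$x, times = d[2]); py <- rep(ctr$y, each = d[1])
  region <- mask$mask & matrix(points_in_rings(list(hull), px, py), d[1], d[2])
  if (!any(region)) stop("mask is empty within the species MCP")

  vals <- raster_values(predictors)
  ok <- stats::complete.cases(vals) & as.vector(region)
  bg_all <- which(ok)

  ij <- raster_cell_index(predictors, fixes$x, fixes$y)
  good <- !is.na(ij[, 1])
  cell <- unique((ij[good, 2] - 1L) * d[1] + ij[good, 1])
  pres_cells <- intersect(cell, bg_all)
  n_dropped <- length(cell) - length(pres_cells)
  if (length(pres_cells) < 10)
    stop("fewer than 10 presence cells inside the mask")
  if (n_dropped > 0)
    message(n_dropped, " presence cell(s) outside the mask dropped")

  m <- length(pres_cells)
  n_train <- max(1, round(split_fraction * m))
  # a split leaving fewer than 4 test presences is degenerate; shrink the
  # training fold (logged) rather than evaluate on a vanishing test set
  if (m - n_train < 4 && m >= 8) {
    message("training fold shrunk to keep >= 4 test presences")
    n_train <- m - 4
  }
  pred_sum <- matrix(0, d[1], d[2])
  contrib_sum <- NULL
  reps <- list()

  with_seed(seed, {
    bg_idx <- sample_cap(bg_all, n_background, NULL)
    bg <- vals[bg_idx, , drop = FALSE]
    for (r in seq_len(n_replicates)) {
      tr <- sample.int(m, n_train)
      te <- setdiff(seq_len(m), tr)
      model <- fit_maxent(vals[pres_cells[tr], , drop = FALSE], bg, reg = reg)
      sc_bg <- predict(model, bg, type = "logistic")
      sc_tr <- predict(model, vals[pres_cells[tr], , drop = FALSE], "logistic")
      auc_tr <- evaluate_auc(sc_tr, sc_bg)
      auc_te <- if (length(te))
        evaluate_auc(predict(model, vals[pres_cells[te], , drop = FALSE],
                             "logistic"), sc_bg) else NA_real_
      thr <- omission_threshold(sc_tr, percentile)
      pr <- rep(NA_real_, length(ok))
      pr[ok] <- predict(model, vals[ok, , drop = FALSE], type = "logistic")
      pred_sum <- pred_sum + matrix(pr, d[1], d[2])
      cb <- model$contributions
      contrib_sum <- if (is.null(contrib_sum)) cb else contrib_sum + cb
      reps[[r]] <- data.frame(replicate = r, training_auc = auc_tr,
                              test_auc = auc_te, threshold = thr,
                              n_train = length(tr), n_test = length(te))
    }
  })

  reps <- do.call(rbind, reps)
  contrib <- contrib_sum / n_replicates
  if (sum(contrib) > 0) contrib <- 100 * contrib / sum(contrib)
  pred <- pred_sum / n_replicates
  structure(list(
    replicates = reps,
    mean_training_auc = mean(reps$training_auc),
    mean_test_auc = mean(reps$test_auc, na.rm = TRUE),
    threshold = mean(reps$threshold),
    contributions = contrib,
    prediction = raster_stack(list(suitability = pred), predictors$origin,
                              predictors$cell_size, predictors$crs),
    n_presence = m, n_dropped = n_dropped, seed = seed
  ), class = "suitability_model")
}

#' @export
print.suitability_model <- function(x, ...) {
  cat("Habitat suitability model:", x$n_presence, "presence cells,",
      nrow(x$replicates), "replicates\n")
  cat("  mean training AUC", round(x$mean_training_auc, 3),
      "; mean test AUC", round(x$mean_test_auc, 3),
      "; threshold", round(x$threshold, 3), "\n")
  top <- sort(x$contributions, decreasing = TRUE)
  cat("  contributions:", paste(names(top), paste0(round(top, 1), "%"),
                                collapse = ", "), "\n")
  invisible(x)
}

# seeded subsample of an index vector, capped at n
sample_cap <- function(idx, n, seed) {
  if (length(idx) <= n) return(idx)
  with_seed(seed, sort(sample(idx, n)))
}
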