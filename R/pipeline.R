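#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()]. Exactly one
#' of `bearings_csv` / `fixes_csv` must be supplied (or the `simulate` stage
#' enabled, which writes both inputs itself).
#'
#' @param out_dir Output directory (created if missing).
#' @param bearings_csv,fixes_csv,landcover_geojson,raster_tif Input paths.
#' @param stages Stages to run, in pipeline order; subset of
#'   `c("simulate", "triangulate", "homerange", "preference", "movement",
#'   "fidelity", "indices", "suitability")`.
#' @param seed Master seed; stage seeds are derived from it.
#' @param max_dist Observer-distance fix filter (m).
#' @param retention MCP retention fraction.
#' @param kernel_levels Kernel utilization levels.
#' @param n_sims RWM simulations per bird.
#' @param reg Maxent regularization multiplier.
#' @param percentile Training-omission percentile.
#' @param n_random Lantana sub-model presence count.
#' @param max_gap Movement step gap cutoff (min).
#' @param buffer_m River buffer for composition (NULL = whole map).
#' @param n_replicates Suitability split replicates.
#' @param simulate Named list of overrides for the simulate stage
#'   (`n_birds`, `n_fixes`, plus any [landscape_spec()], [movement_spec()],
#'   [spectral_spec()] arguments).
#' @param crs CRS label for generated data.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            bearings_csv = NULL, fixes_csv = NULL,
                            landcover_geojson = NULL, raster_tif = NULL,
                            stages = c("triangulate", "homerange", "preference",
                                       "movement", "fidelity", "indices",
                                       "suitability"),
                            seed = 1L,
                            max_dist = 1000, retention = 0.95,
                            kernel_levels = c(0.95, 0.75, 0.50),
                            n_sims = 1000, reg = 1, percentile = 10,
                            n_random = 300, max_gap = 10, buffer_m = NULL,
                            n_replicates = 10,
                            simulate = list(), crs = "local-metric") {
  all_stages <- c("simulate", "triangulate", "homerange", "preference",
                  "movement", "fidelity", "indices", "suitability")
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  sim <- "simulate" %in% cfg$stages
  if (!sim) {
    n_src <- sum(!is.null(cfg$bearings_csv), !is.null(cfg$fixes_csv))
    if (n_src != 1)
      stop("exactly one of bearings_csv / fixes_csv must be supplied")
    for (p in c(cfg$bearings_csv, cfg$fixes_csv, cfg$landcover_geojson))
      if (!is.null(p) && !file.exists(p)) stop("input not found: ", p)
    if (is.null(cfg$landcover_geojson))
      stop("landcover_geojson is required")
    if ("suitability" %in% cfg$stages || "indices" %in% cfg$stages) {
      if (is.null(cfg$raster_tif)) stop("raster_tif is required for the ",
                                        "indices/suitability stages")
      if (!file.exists(cfg$raster_tif)) stop("input not found: ", cfg$raster_tif)
    }
  }
  invisible(cfg)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in order: simulate (optional synthetic
#' inputs) -> triangulate & filter -> home ranges -> habitat preference ->
#' movement -> site-fidelity null model -> vegetation indices & distance
#' rasters -> chained habitat suitability. Each stage writes its artifacts
#' into `out_dir`; a JSON manifest listing every artifact with the parameters
#' and seeds used is written last.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (also written to `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  add <- function(name, path, ...) {
    art[[name]] <<- c(list(path = path), list(...))
  }
  stages <- config$stages

  # ---- simulate ----------------------------------------------------------
  if ("simulate" %in% stages) {
    sim <- config$simulate
    n_birds <- if (!is.null(sim$n_birds)) sim$n_birds else 3
    n_fixes <- if (!is.null(sim$n_fixes)) sim$n_fixes else 300
    lspec <- landscape_spec(
      extent = sim$extent %||% c(0, 2000, 0, 2000),
      cell_size = sim$cell_size %||% 10,
      seed = derive_seed(config$seed, "landscape"))
    map <- generate_landscape(lspec)
    sspec <- spectral_spec(noise_sd = sim$noise_sd %||% 0.02,
                           seed = derive_seed(config$seed, "raster"))
    stack <- generate_raster(map, sspec)
    bearings <- list()
    ext <- map_extent(map)
    for (b in seq_len(n_birds)) {
      mspec <- movement_spec(n_fixes = n_fixes,
                             seed = derive_seed(config$seed, paste0("track", b)))
      tr <- generate_track(map, mspec, bird_id = sprintf("SY%d", b))
      obs_a <- c(ext[1] + 0.4 * (ext[2] - ext[1]), ext[3] + 0.45 * (ext[4] - ext[3]))
      obs_b <- c(ext[1] + 0.6 * (ext[2] - ext[1]), ext[3] + 0.55 * (ext[4] - ext[3]))
      bearings[[b]] <- generate_bearings(tr, obs_a, obs_b, noise_sd_deg = 1,
                                         seed = derive_seed(config$seed,
                                                            paste0("bear", b)))
    }
    config$landcover_geojson <- file.path(config$out_dir, "landcover.geojson")
    write_landcover(map, config$landcover_geojson)
    add("landcover", config$landcover_geojson, seed = lspec$seed)
    config$raster_tif <- file.path(config$out_dir, "reflectance.tif")
    write_raster(stack, config$raster_tif)
    add("raster", config$raster_tif, seed = sspec$seed)
    config$bearings_csv <- file.path(config$out_dir, "bearings.csv")
    write_bearings(do.call(rbind, bearings), config$bearings_csv)
    add("bearings", config$bearings_csv, n_birds = n_birds, n_fixes = n_fixes)
  }

  map <- read_landcover(config$landcover_geojson)

  # ---- triangulate & filter ---------------------------------------------
  if (!is.null(config$bearings_csv)) {
    bearings <- read_bearings(config$bearings_csv)
    fixes <- triangulate_bearings(bearings)
  } else {
    fixes <- read_fixes(config$fixes_csv)
    if (is.null(fixes$valid)) fixes$valid <- TRUE
  }
  fixes <- filter_fixes(fixes, config$max_dist, quiet = TRUE)
  fix_path <- file.path(config$out_dir, "fixes.csv")
  write_fixes(fixes, fix_path)
  add("fixes", fix_path, n_removed = attr(fixes, "n_removed"),
      max_dist = config$max_dist)

  trajs <- lapply(split(fixes, fixes$bird_id), build_trajectory)

  # ---- home ranges -------------------------------------------------------
  hr_rows <- list(); k75 <- list(); mcp95 <- list()
  if (any(c("homerange", "preference", "fidelity") %in% stages)) {
    all_hr <- list()
    for (id in names(trajs)) {
      tr <- trajs[[id]]
      m <- mcp(tr, config$retention)
      mcp95[[id]] <- m
      h <- href_bandwidth(tr)
      ud <- kernel_ud(tr, h = h)
      hr_rows[[length(hr_rows) + 1]] <-
        data.frame(bird = id, estimator = m$estimator,
                   area_ha = round(m$area_ha, 2), h = NA_real_)
      all_hr[[length(all_hr) + 1]] <- m
      for (lv in config$kernel_levels) {
        est <- ud_contour(ud, lv, bird_id = id)
        if (abs(lv - 0.75) < 1e-9) k75[[id]] <- est
        hr_rows[[length(hr_rows) + 1]] <-
          data.frame(bird = id, estimator = est$estimator,
                     area_ha = round(est$area_ha, 2), h = round(h, 2))
        all_hr[[length(all_hr) + 1]] <- est
      }
    }
    if ("homerange" %in% stages) {
      hr_path <- file.path(config$out_dir, "home_ranges.csv")
      utils::write.csv(do.call(rbind, hr_rows), hr_path, row.names = FALSE)
      add("home_ranges", hr_path, retention = config$retention)
      gj_path <- file.path(config$out_dir, "home_ranges.geojson")
      write_home_ranges(all_hr, gj_path)
      add("home_range_polygons", gj_path)
    }
  }

  # ---- habitat preference ------------------------------------------------
  if ("preference" %in% stages) {
    jt <- jacobs_table(k75, map)
    j_path <- file.path(config$out_dir, "jacobs.csv")
    utils::write.csv(jt, j_path, row.names = FALSE)
    add("jacobs", j_path)
    st <- do.call(rbind, lapply(split(jt, jt$class), function(g) {
      s <- sign_test(g$D)
      data.frame(class = g$class[1], mean_D = mean(g$D, na.rm = TRUE),
                 s = s$s, n = s$n, p_value = s$p_value)
    }))
    st_path <- file.path(config$out_dir, "sign_tests.csv")
    utils::write.csv(st, st_path, row.names = FALSE)
    add("sign_tests", st_path)
    comp <- landscape_composition(map, config$buffer_m)
    c_path <- file.path(config$out_dir, "composition.csv")
    utils::write.csv(comp, c_path, row.names = FALSE)
    add("composition", c_path, buffer_m = config$buffer_m)
  }

  # ---- movement ----------------------------------------------------------
  if ("movement" %in% stages) {
    mv <- do.call(rbind, lapply(trajs, movement_by_habitat, map = map,
                                max_gap = config$max_gap))
    mv_path <- file.path(config$out_dir, "movement.csv")
    utils::write.csv(mv, mv_path, row.names = FALSE)
    add("movement", mv_path, max_gap = config$max_gap)
  }

  # ---- site fidelity -----------------------------------------------------
  if ("fidelity" %in% stages) {
    res <- lapply(names(trajs), function(id)
      rwm_simulate(trajs[[id]], n_sims = config$n_sims,
                   seed = derive_seed(config$seed, paste0("rwm", id))))
    rep <- rwm_report(res)
    r_path <- file.path(config$out_dir, "rwm.csv")
    utils::write.csv(rep, r_path, row.names = FALSE)
    add("rwm", r_path, n_sims = config$n_sims,
        fidelity_fraction = attr(rep, "fidelity_fraction"))
  }

  # ---- vegetation indices & distance rasters -----------------------------
  if (any(c("indices", "suitability") %in% stages)) {
    stack <- read_raster(config$raster_tif)
    stack <- vegetation_indices(stack)
    grid <- list(origin = stack$origin, cell_size = stack$cell_size,
                 dim = dim(stack$bands[[1]]))
    d_river <- distance_raster(map, "river", grid)
    d_mixed <- if ("mixed" %in% map$class_levels)
      distance_raster(map, "mixed", grid) else NULL
    d_settle <- distance_raster(map, "settlement", grid)
    if ("indices" %in% stages) {
      i_path <- file.path(config$out_dir, "indices.tif")
      write_raster(stack, i_path)
      add("indices", i_path)
      dr_path <- file.path(config$out_dir, "dist_river.tif")
      write_raster(d_river, dr_path)
      add("dist_river", dr_path)
    }
  }

  # ---- habitat suitability ----------------------------------------------
  if ("suitability" %in% stages) {
    pooled <- do.call(rbind, lapply(trajs, function(t) t$fixes))
    msk <- build_mask(pooled, d_river, reg = config$reg,
                      percentile = config$percentile,
                      seed = derive_seed(config$seed, "mask"))
    lm <- lantana_model(map, stack, n_random = config$n_random,
                        reg = config$reg,
                        seed = derive_seed(config$seed, "lantana"))
    pred_bands <- stack$bands[c("NDVI", "REGNDVI", "GNDVI", "NDRE",
                                "GCM", "GRM", "RENDVI")]
    pred_bands$lantana_prob <- lm$prob$bands$lantana_prob
    if (!is.null(d_mixed)) pred_bands$dist_mixed <- d_mixed$bands[[1]]
    pred_bands$dist_settlement <- d_settle$bands[[1]]
    preds <- raster_stack(pred_bands, stack$origin, stack$cell_size, stack$crs)
    summ <- list()
    for (id in names(trajs)) {
      sm <- fit_species_model(trajs[[id]], msk, preds, reg = config$reg,
                              n_replicates = config$n_replicates,
                              percentile = config$percentile,
                              seed = derive_seed(config$seed, paste0("sdm", id)))
      p_path <- file.path(config$out_dir, paste0("suitability_", id, ".tif"))
      write_raster(sm$prediction, p_path)
      summ[[id]] <- data.frame(bird = id,
                               training_auc = sm$mean_training_auc,
                               test_auc = sm$mean_test_auc,
                               threshold = sm$threshold,
                               t(sm$contributions), check.names = FALSE)
    }
    s_path <- file.path(config$out_dir, "suitability_summary.csv")
    utils::write.csv(do.call(rbind, summ), s_path, row.names = FALSE)
    add("suitability_summary", s_path, reg = config$reg,
        n_replicates = config$n_replicates)
    m_path <- file.path(config$out_dir, "mask.tif")
    write_raster(raster_stack(list(mask = msk$mask * 1), msk$origin,
                              msk$cell_size, msk$crs), m_path)
    add("mask", m_path, threshold = msk$threshold)
    l_path <- file.path(config$out_dir, "lantana_prob.tif")
    write_raster(lm$prob, l_path)
    add("lantana_prob", l_path, n_random = config$n_random)
  }

  manifest <- list(created = format(Sys.time(), tz = "UTC"),
                   seed = config$seed, stages = stages, artifacts = art)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
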