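# File formats: land-cover maps as GeoJSON FeatureCollections, raster stacks
# as multi-band 32-bit float TIFF (band values rescaled to [0,1]) plus a JSON
# sidecar with georeferencing and band metadata, tables as CSV.

#' Write a land-cover map to GeoJSON
#'
#' One FeatureCollection: the river as a LineString, settlements as Points,
#' and each polygon class as a MultiPolygon of merged grid-cell rectangles.
#' Every feature carries a `"class"` property from the schema.
#'
#' @param map A [landcover_map()].
#' @param path Output path (.geojson).
#' @return `path`, invisibly.
#' @export
write_landcover <- function(map, path) {
  feats <- list()
  coords_of <- function(ring) lapply(seq_len(nrow(ring)), function(i)
    c(ring[i, 1], ring[i, 2]))
  if (!is.null(map$river))
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(class = "river"),
      geometry = list(type = "LineString", coordinates = coords_of(map$river)))
  if (!is.null(map$settlements))
    for (i in seq_len(nrow(map$settlements)))
      feats[[length(feats) + 1]] <- list(
        type = "Feature", properties = list(class = "settlement"),
        geometry = list(type = "Point",
                        coordinates = c(map$settlements[i, 1],
                                        map$settlements[i, 2])))
  polys <- landcover_polygons(map)
  for (cls in names(polys))
    feats[[length(feats) + 1]] <- list(
      type = "Feature", properties = list(class = cls),
      geometry = list(type = "MultiPolygon",
                      coordinates = lapply(polys[[cls]], function(r)
                        list(coords_of(r)))))
  gj <- list(type = "FeatureCollection", crs_label = map$crs,
             cell_size = map$cell_size, features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a land-cover map from GeoJSON
#'
#' Accepts a FeatureCollection whose features carry a `"class"` property from
#' the schema ([landcover_classes()]); polygon features are rasterized onto a
#' square grid, the river LineString and settlement Points are kept as vector
#' geometry. Unclosed polygon rings are repaired (closed) with a logged
#' count; unknown classes are rejected.
#'
#' @param path GeoJSON file path.
#' @param cell_size Grid cell size (m) for rasterizing polygons; defaults to
#'   the `cell_size` stored by [write_landcover()], else 10 m.
#' @param default_class Class of cells not covered by any polygon.
#' @return A [landcover_map()].
#' @export
read_landcover <- function(path, cell_size = NULL, default_class = "crops_high") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  if (is.null(cell_size))
    cell_size <- if (!is.null(gj$cell_size)) gj$cell_size else 10
  river <- NULL; settlements <- list(); polys <- list(); n_repaired <- 0L
  for (f in gj$features) {
    cls <- f$properties$class
    if (is.null(cls)) stop("feature without a 'class' property")
    if (!cls %in% landcover_classes())
      stop("unknown land-cover class '", cls, "' in ", path)
    geom <- f$geometry
    if (geom$type == "LineString") {
      xy <- do.call(rbind, lapply(geom$coordinates, function(c) unlist(c)[1:2]))
      if (cls == "river") river <- xy
    } else if (geom$type == "Point") {
      settlements[[length(settlements) + 1]] <- unlist(geom$coordinates)[1:2]
    } else if (geom$type %in% c("Polygon", "MultiPolygon")) {
      rings <- if (geom$type == "Polygon") list(geom$coordinates) else geom$coordinates
      for (pg in rings) {
        ring <- do.call(rbind, lapply(pg[[1]], function(c) unlist(c)[1:2]))
        if (!all(ring[1, ] == ring[nrow(ring), ])) {
          ring <- rbind(ring, ring[1, , drop = FALSE])
          n_repaired <- n_repaired + 1L
        }
        polys[[length(polys) + 1]] <- list(class = cls, ring = ring)
      }
    }
  }
  if (n_repaired > 0)
    message(n_repaired, " polygon ring(s) repaired (closed)")
  if (!length(polys)) stop("no polygon features in ", path)
  allxy <- do.call(rbind, lapply(polys, `[[`, "ring"))
  if (!is.null(river)) allxy <- rbind(allxy, river)
  ext <- c(min(allxy[, 1]), max(allxy[, 1]), min(allxy[, 2]), max(allxy[, 2]))
  nx <- max(2L, ceiling((ext[2] - ext[1]) / cell_size))
  ny <- max(2L, ceiling((ext[4] - ext[3]) / cell_size))
  cx <- ext[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- ext[3] + (seq_len(ny) - 0.5) * cell_size
  px <- rep(cx, times = ny); py <- rep(cy, each = nx)
  levels <- union(default_class,
                  intersect(polygon_classes(),
                            unique(vapply(polys, `[[`, "", "class"))))
  grid <- matrix(match(default_class, levels), nx, ny)
  for (p in polys) {
    if (!p$class %in% polygon_classes()) next
    inside <- points_in_rings(list(p$ring), px, py)
    grid[matrix(inside, nx, ny)] <- match(p$class, levels)
  }
  landcover_map(grid, origin = c(ext[1], ext[3]), cell_size = cell_size,
                class_levels = levels, river = river,
                settlements = if (length(settlements))
                  do.call(rbind, settlements) else NULL,
                crs = if (!is.null(gj$crs_label)) gj$crs_label else "local-metric")
}

#' Write a raster stack
#'
#' Stores the bands as a multi-band 32-bit float TIFF with each band rescaled
#' to [0, 1], and a JSON sidecar (`<path>.json`) carrying origin, cell size,
#' CRS, band names and per-band offset/scale so that [read_raster()] restores
#' the original values. Nodata cells are stored as 0 and flagged in one mask
#' band per data band.
#'
#' @param stack A [raster_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(stack, path) {
  d <- dim(stack$bands[[1]])
  nb <- length(stack$bands)
  # one TIFF page per data band, followed by one nodata page per band
  pages <- vector("list", 2 * nb)
  meta_bands <- list()
  for (b in seq_len(nb)) {
    v <- stack$bands[[b]]
    nod <- !is.finite(v)
    lo <- suppressWarnings(min(v[!nod]))
    hi <- suppressWarnings(max(v[!nod]))
    if (!is.finite(lo)) { lo <- 0; hi <- 1 }
    scale <- if (hi > lo) hi - lo else 1
    sv <- (v - lo) / scale
    sv[nod] <- 0
    pages[[b]] <- t(sv[, rev(seq_len(d[2]))])   # TIFF rows = y, top-down
    pages[[nb + b]] <- t(nod[, rev(seq_len(d[2]))]) * 1
    meta_bands[[b]] <- list(name = names(stack$bands)[b], offset = lo,
                            scale = scale, nodata_band = nb + b)
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(origin = stack$origin, cell_size = stack$cell_size,
               crs = stack$crs, dim = d, bands = meta_bands)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a raster stack written by [write_raster()]
#' @param path TIFF path (expects the `.json` sidecar next to it).
#' @return A [raster_stack()].
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dim)
  bands <- list()
  for (b in seq_len(nrow(meta$bands))) {
    m <- t(pages[[b]])[, rev(seq_len(d[2]))] * meta$bands$scale[b] +
      meta$bands$offset[b]
    nb <- meta$bands$nodata_band[b]
    if (!is.null(nb) && !is.na(nb) && nb <= length(pages)) {
      nod <- t(pages[[nb]])[, rev(seq_len(d[2]))] > 0.5
      m[nod] <- NA_real_
    }
    bands[[meta$bands$name[b]]] <- m
  }
  raster_stack(bands, origin = as.numeric(meta$origin),
               cell_size = meta$cell_size, crs = meta$crs)
}

#' Write home-range polygons to GeoJSON
#'
#' @param estimates List of `home_range_estimate`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_home_ranges <- function(estimates, path) {
  if (inherits(estimates, "home_range_estimate")) estimates <- list(estimates)
  feats <- lapply(estimates, function(hr) list(
    type = "Feature",
    properties = list(bird = hr$bird_id, estimator = hr$estimator,
                      area_ha = round(hr$area_ha, 2),
                      h = if (!is.null(hr$h)) hr$h else NULL),
    geometry = list(type = "MultiPolygon",
                    coordinates = lapply(hr$polygons, function(r)
                      list(lapply(seq_len(nrow(r)), function(i)
                        c(r[i, 1], r[i, 2])))))))
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write/read fixes and bearings CSV
#'
#' Fixes CSV columns: `bird_id, timestamp (ISO-8601), x, y, dist_a, dist_b,
#' valid`; bearings CSV columns: `bird_id, timestamp, obs_a_x, obs_a_y,
#' obs_a_az, obs_b_x, obs_b_y, obs_b_az`.
#'
#' @param x Data.frame to write.
#' @param path CSV path.
#' @return `path` (writers, invisibly) or a data.frame (readers).
#' @export
write_fixes <- function(x, path) {
  x$timestamp <- format(x$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fixes
#' @export
read_fixes <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$timestamp <- as.POSIXct(x$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                            tz = "UTC")
  x
}

#' @rdname write_fixes
#' @export
write_bearings <- function(x, path) write_fixes(x, path)

#' @rdname write_fixes
#' @export
read_bearings <- function(path) read_fixes(path)
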