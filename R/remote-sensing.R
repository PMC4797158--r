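#' Top-of-atmosphere reflectance from radiance
#'
#' Converts sensor radiance to TOA reflectance per band:
#' `reflectance = radiance * scale * pi * d^2 / (esun * cos(solar zenith))`,
#' clipped to [0, 1]. The calibration coefficients come from the imagery
#' product specification and must be supplied by the caller; there are no
#' universal defaults.
#'
#' @param stack A [raster_stack()] of radiance bands.
#' @param coefficients Named list per band, each with `scale` and `esun`
#'   (exo-atmospheric irradiance).
#' @param sun_elevation Solar elevation angle (degrees above horizon).
#' @param earth_sun_distance Earth-sun distance (AU).
#' @return A [raster_stack()] of reflectance bands in [0, 1].
#' @export
toa_reflectance <- function(stack, coefficients, sun_elevation,
                            earth_sun_distance = 1) {
  stopifnot(inherits(stack, "raster_stack"))
  if (missing(coefficients) || is.null(coefficients))
    stop("TOA coefficients are required: supply per-band 'scale' and 'esun' ",
         "from the imagery product specification")
  miss <- setdiff(names(stack$bands), names(coefficients))
  if (length(miss))
    stop("missing TOA coefficients for band(s): ", paste(miss, collapse = ", "))
  zen <- deg2rad(90 - sun_elevation)
  cz <- cos(zen)
  if (cz < 1e-6) stop("solar zenith at or beyond 90 degrees: reflectance undefined")
  bands <- lapply(names(stack$bands), function(b) {
    cf <- coefficients[[b]]
    if (is.null(cf$scale) || is.null(cf$esun))
      stop("band ", b, ": coefficients must contain 'scale' and 'esun'")
    r <- stack$bands[[b]] * cf$scale * pi * earth_sun_distance^2 / (cf$esun * cz)
    pmin(pmax(r, 0), 1)
  })
  names(bands) <- names(stack$bands)
  raster_stack(bands, stack$origin, stack$cell_size, stack$crs)
}

#' Seven red-edge vegetation indices
#'
#' Adds the seven band-ratio indices used as habitat-suitability predictors:
#' NDVI = (NIR - Red)/(NIR + Red);
#' REGNDVI (red-edge green NDVI) = (RedEdge - Green)/(RedEdge + Green);
#' GNDVI = (NIR - Green)/(NIR + Green);
#' NDRE = (NIR - RedEdge)/(NIR + RedEdge);
#' GCM (chlorophyll green model) = NIR/Green - 1;
#' GRM (chlorophyll red-edge model) = NIR/RedEdge - 1;
#' RENDVI (red-edge NDVI) = (RedEdge - Red)/(RedEdge + Red).
#' Cells with a zero denominator (or any nodata operand) become nodata.
#'
#' @param stack A [raster_stack()] with bands Blue, Green, Red, RedEdge, NIR.
#' @return The stack with seven index bands appended.
#' @export
vegetation_indices <- function(stack) {
  need <- c("Green", "Red", "RedEdge", "NIR")
  miss <- setdiff(need, names(stack$bands))
  if (length(miss)) stop("missing band(s): ", paste(miss, collapse = ", "))
  G <- stack$bands$Green; R <- stack$bands$Red
  RE <- stack$bands$RedEdge; N <- stack$bands$NIR
  nd <- function(a, b) {
    s <- a + b
    s[abs(s) < .Machine$double.eps] <- NA
    (a - b) / s
  }
  rt <- function(a, b) {
    b2 <- b
    b2[abs(b2) < .Machine$double.eps] <- NA
    a / b2 - 1
  }
  idx <- list(
    NDVI = nd(N, R), REGNDVI = nd(RE, G), GNDVI = nd(N, G), NDRE = nd(N, RE),
    GCM = rt(N, G), GRM = rt(N, RE), RENDVI = nd(RE, R)
  )
  raster_stack(c(stack$bands, idx), stack$origin, stack$cell_size, stack$crs)
}

#' Distance raster to a target geometry
#'
#' Per-cell Euclidean distance (m) from the cell centre to the nearest target
#' geometry: the river polyline and settlement points are measured exactly
#' (point-to-segment / point-to-point); polygon classes (e.g. mixed thicket)
#' use the exact Euclidean distance transform of the class cells, with
#' distance 0 inside the class.
#'
#' @param map A [landcover_map()].
#' @param target `"river"`, `"settlement"`, or a polygon class name
#'   (e.g. `"mixed"`, `"lantana"`).
#' @param grid Optional list (`origin`, `cell_size`, `dim`) for the output
#'   grid; defaults to the land-cover grid.
#' @return A single-band [raster_stack()] named `dist_<target>` (metres).
#' @export
distance_raster <- function(map, target, grid = NULL) {
  stopifnot(inherits(map, "landcover_map"))
  if (is.null(grid)) {
    grid <- list(origin = map$origin, cell_size = map$cell_size,
                 dim = dim(map$grid))
  }
  nx <- grid$dim[1]; ny <- grid$dim[2]
  gx <- grid$origin[1] + (seq_len(nx) - 0.5) * grid$cell_size
  gy <- grid$origin[2] + (seq_len(ny) - 0.5) * grid$cell_size
  px <- rep(gx, times = ny); py <- rep(gy, each = nx)
  if (target == "river") {
    if (is.null(map$river) || nrow(map$river) < 2) stop("empty target: no river polyline")
    d <- dist_to_polyline(px, py, map$river)
  } else if (target == "settlement" && !is.null(map$settlements)) {
    if (nrow(map$settlements) == 0) stop("empty target: no settlement points")
    d <- dist_to_points(px, py, map$settlements)
  } else if (target %in% map$class_levels) {
    k <- match(target, map$class_levels)
    mask <- map$grid == k
    if (!any(mask)) stop("empty target: no cells of class ", target)
    if (identical(grid$origin, map$origin) &&
        identical(grid$cell_size, map$cell_size) &&
        identical(grid$dim, dim(map$grid))) {
      d <- distance_transform(mask) * map$cell_size
    } else {
      ctr <- grid_centers(map)
      idx <- which(mask, arr.ind = TRUE)
      d <- dist_to_points(px, py, cbind(ctr$x[idx[, 1]], ctr$y[idx[, 2]]))
    }
  } else {
    stop("empty target: '", target, "' not present in the map")
  }
  raster_stack(stats::setNames(list(matrix(d, nx, ny)), paste0("dist_", target)),
               grid$origin, grid$cell_size, map$crs)
}
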