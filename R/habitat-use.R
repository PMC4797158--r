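#' Habitat composition of a region
#'
#' Fraction of a region (home-range polygon set, e.g. the K75 core area)
#' covered by each land-cover class, computed by counting land-cover grid
#' cells whose centres fall inside the region polygons. This is the
#' raster-canonical intersection of a home range with the land-cover map.
#'
#' @param region A `home_range_estimate`, a single ring matrix, or a list of
#'   ring matrices (x, y columns, metres).
#' @param map A [landcover_map()].
#' @return Named numeric vector of per-class fractions (classes present in the
#'   map), with attribute `n_cells` (cells inside the region) and `unmapped`
#'   (fraction of region cells outside the mapped extent; region cells beyond
#'   the map count toward the total).
#' @export
habitat_fractions <- function(region, map) {
  rings <- region_rings(region)
  ctr <- grid_centers(map)
  # restrict to the rings' bounding box for speed
  bb <- apply(do.call(rbind, rings), 2, range)
  ix <- which(ctr$x >= bb[1, 1] - map$cell_size & ctr$x <= bb[2, 1] + map$cell_size)
  iy <- which(ctr$y >= bb[1, 2] - map$cell_size & ctr$y <= bb[2, 2] + map$cell_size)
  if (!length(ix) || !length(iy)) stop("region does not overlap the mapped extent")
  px <- rep(ctr$x[ix], times = length(iy))
  py <- rep(ctr$y[iy], each = length(ix))
  inside <- points_in_rings(rings, px, py)
  if (!any(inside)) stop("empty region: no land-cover cells inside")
  cls <- map$class_levels[map$grid[cbind(rep(ix, times = length(iy))[inside],
                                         rep(iy, each = length(ix))[inside])]]
  # region area that extends beyond the mapped extent
  ring_area <- sum(vapply(rings, polygon_area, 0))
  n_in <- sum(inside)
  tab <- table(factor(cls, levels = map$class_levels))
  frac <- as.numeric(tab) / n_in
  names(frac) <- map$class_levels
  mapped_area <- n_in * map$cell_size^2
  attr(frac, "n_cells") <- n_in
  attr(frac, "unmapped") <- max(0, 1 - mapped_area / max(ring_area, mapped_area))
  frac
}

region_rings <- function(region) {
  if (inherits(region, "home_range_estimate")) {
    if (!is.null(region$cells)) {
      # use the raster cells directly as rectangles? contours polygons suffice
      return(region$polygons)
    }
    return(region$polygons)
  }
  if (is.matrix(region)) return(list(region))
  if (is.list(region)) return(region)
  stop("region must be a home_range_estimate, a ring matrix, or a list of rings")
}

#' Jacobs selectivity index
#'
#' `D = (r - p) / (r + p - 2 r p)` for a used fraction `r` and an available
#' fraction `p`; ranges from -1 (total avoidance) through 0 (use proportional
#' to availability) to +1 (absolute preference). Undefined when `r = p = 0`
#' or `r = p = 1` (returned as `NA` with a warning).
#'
#' @param r Used fraction(s) in [0, 1].
#' @param p Available fraction(s) in [0, 1].
#' @return Selectivity D in [-1, 1] (vectorized).
#' @export
jacobs_index <- function(r, p) {
  stopifnot(all(r >= 0 & r <= 1, na.rm = TRUE), all(p >= 0 & p <= 1, na.rm = TRUE))
  denom <- r + p - 2 * r * p
  out <- ifelse(abs(denom) < .Machine$double.eps^0.5,
                ifelse(abs(r - p) < .Machine$double.eps^0.5, NA_real_,
                       sign(r - p)),
                (r - p) / denom)
  if (any(is.na(out) & !is.na(r) & !is.na(p)))
    warning("Jacobs index undefined where r = p = 0 or r = p = 1")
  out
}

#' Exact sign test against a null median
#'
#' Counts values above `mu` after dropping exact ties (the standard exact
#' sign-test convention) and computes the two-sided exact binomial p-value
#' with success probability 1/2 (via [stats::binom.test()]).
#'
#' @param values Numeric vector (e.g. per-individual Jacobs indices).
#' @param mu Null median (default 0, "no interaction").
#' @return List with `s` (count above `mu`), `n` (non-tied count), `p_value`.
#' @export
sign_test <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  nz <- values[values != mu]
  if (!length(nz))
    return(list(s = 0L, n = 0L, p_value = NA_real_,
                note = "all values equal the null median; test undefined"))
  s <- sum(nz > mu)
  list(s = as.integer(s), n = length(nz),
       p_value = stats::binom.test(s, length(nz), 0.5)$p.value)
}

#' Per-habitat movement samples from a trajectory
#'
#' One movement sample per step whose time gap does not exceed `max_gap`
#' minutes: the distance is normalized to metres per 10 minutes
#' (`length * 10 / dt`), and the habitat is the land-cover class containing
#' the step's start fix (point-in-polygon on the map grid). Steps starting
#' outside the mapped extent are labelled `"unmapped"`.
#'
#' @param traj A `trajectory`.
#' @param map A [landcover_map()].
#' @param max_gap Maximum step gap (min) retained.
#' @return Data.frame (`bird_id`, `habitat`, `dist_per_10min`) with attribute
#'   `small_classes`: classes with 50 or fewer samples (to be interpreted
#'   with caution / excluded from per-class tests).
#' @export
movement_by_habitat <- function(traj, map, max_gap = 10) {
  stopifnot(inherits(traj, "trajectory"))
  st <- traj$steps
  keep <- st$dt_min <= max_gap
  start <- traj$fixes[-nrow(traj$fixes), , drop = FALSE]
  hab <- class_at(map, start$x, start$y)
  out <- data.frame(
    bird_id = traj$bird_id,
    habitat = hab[keep],
    dist_per_10min = st$length[keep] * 10 / st$dt_min[keep]
  )
  tab <- table(out$habitat[out$habitat != "unmapped"])
  attr(out, "small_classes") <- names(tab)[tab <= 50]
  out
}

#' One-way ANOVA across groups
#'
#' Classical between/within one-way decomposition (delegated to
#' [stats::aov()]), with the option of a log(x+1) transform: `transform =
#' "auto"` applies it only when a Shapiro-Wilk test rejects normality of the
#' untransformed residuals at alpha = 0.05.
#'
#' @param groups Named list of numeric vectors (one per group), each n >= 2.
#' @param transform One of `"none"`, `"log1p"`, `"auto"`.
#' @return List with `F`, `df1`, `df2`, `p_value`, `transform` (applied).
#' @export
one_way_anova <- function(groups, transform = c("none", "log1p", "auto")) {
  transform <- match.arg(transform)
  stopifnot(is.list(groups), length(groups) >= 2,
            all(vapply(groups, length, 0L) >= 2))
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  applied <- "none"
  if (transform == "log1p") {
    y <- log1p(y); applied <- "log1p"
  } else if (transform == "auto") {
    res <- stats::residuals(stats::lm(y ~ g))
    if (stats::shapiro.test(res)$p.value < 0.05) {
      y <- log1p(y); applied <- "log1p"
    }
  }
  if (sum((y - stats::ave(y, g))^2) == 0)
    stop("zero within-group variance: F undefined")
  fit <- stats::aov(y ~ g)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
       p_value = s[["Pr(>F)"]][1], transform = applied)
}

#' Landscape composition table
#'
#' Absolute area (ha) and percentage of the assessed area per land-cover
#' class, optionally restricted to a buffer around the river (the corridor
#' actually mapped in the field).
#'
#' @param map A [landcover_map()].
#' @param buffer_m Buffer half-width around the river polyline (m), or NULL
#'   for the whole mapped extent.
#' @return Data.frame (`class`, `area_ha`, `pct`); percentages sum to 100.
#' @export
landscape_composition <- function(map, buffer_m = NULL) {
  cls <- map$class_levels[map$grid]
  if (!is.null(buffer_m)) {
    ctr <- grid_centers(map)
    d <- dim(map$grid)
    px <- rep(ctr$x, times = d[2]); py <- rep(ctr$y, each = d[1])
    keep <- dist_to_polyline(px, py, map$river) <= buffer_m
    cls <- cls[keep]
  }
  tab <- table(factor(cls, levels = map$class_levels))
  area <- as.numeric(tab) * map$cell_size^2 / 1e4
  data.frame(class = names(tab), area_ha = area,
             pct = 100 * area / sum(area), row.names = NULL)
}

#' Jacobs-index table for a cohort of birds
#'
#' Convenience wrapper reproducing the preference analysis: for each bird the
#' K75 core area is intersected with the land-cover map (used fractions r),
#' availability p is the class composition of the whole mapped study area, and
#' the Jacobs index is computed per class.
#'
#' @param core_areas Named list of `home_range_estimate`s (K75 per bird).
#' @param map A [landcover_map()].
#' @param available Optional availability fractions (defaults to the whole
#'   mapped area composition).
#' @return Data.frame (`bird_id`, `class`, `r`, `p`, `D`).
#' @export
jacobs_table <- function(core_areas, map, available = NULL) {
  if (is.null(available)) {
    comp <- landscape_composition(map)
    available <- stats::setNames(comp$pct / 100, comp$class)
  }
  rows <- lapply(core_areas, function(hr) {
    r <- habitat_fractions(hr, map)
    data.frame(bird_id = hr$bird_id, class = names(r),
               r = as.numeric(r), p = as.numeric(available[names(r)]))
  })
  out <- do.call(rbind, rows)
  out$D <- suppressWarnings(jacobs_index(out$r, out$p))
  rownames(out) <- NULL
  out
}
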