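#' Minimum convex polygon home range
#'
#' MCP estimator on the fraction of relocations closest to the arithmetic
#' centroid of the fixes: the distance threshold is the empirical
#' `retention`-quantile of centroid distances (linear interpolation, type 7);
#' fixes at exactly the threshold are retained. The area of the convex hull of
#' the retained fixes is reported in hectares.
#'
#' @param fixes Data.frame with `x`, `y` (and optionally `bird_id`), or a
#'   `trajectory`.
#' @param retention Fraction of relocations retained (default 0.95, the MCP95).
#' @return A `home_range_estimate`: list with `bird_id`, `estimator`,
#'   `polygons` (list of closed rings), `area_ha`, `retention`, `n_used`.
#' @export
mcp <- function(fixes, retention = 0.95) {
  fixes <- as_fix_frame(fixes)
  stopifnot(nrow(fixes) >= 5, retention > 0, retention <= 1)
  cx <- mean(fixes$x); cy <- mean(fixes$y)
  d <- sqrt((fixes$x - cx)^2 + (fixes$y - cy)^2)
  thr <- stats::quantile(d, retention, names = FALSE, type = 7)
  keep <- d <= thr
  ring <- convex_hull_ring(fixes$x[keep], fixes$y[keep])
  area <- polygon_area(ring)
  if (area <= 0)
    stop("degenerate geometry: retained fixes are collinear or identical")
  structure(list(
    bird_id = if (!is.null(fixes$bird_id)) fixes$bird_id[1] else NA_character_,
    estimator = paste0("MCP", round(100 * retention)),
    polygons = list(ring), area_ha = area / 1e4,
    retention = retention, n_used = sum(keep)
  ), class = "home_range_estimate")
}

#' @export
print.home_range_estimate <- function(x, ...) {
  cat(x$estimator, "home range", if (!is.na(x$bird_id)) paste0("(", x$bird_id, ")"),
      ":", format(round(x$area_ha, 2), nsmall = 2), "ha\n")
  invisible(x)
}

#' Normal-reference (href) kernel bandwidth
#'
#' The "ad hoc" reference bandwidth for a bivariate Gaussian kernel:
#' `h = sqrt((var(x) + var(y)) / 2) * n^(-1/6)`, with the usual n-1 variance
#' denominator.
#'
#' @param fixes Data.frame with `x`, `y`, or a `trajectory`.
#' @return Bandwidth h in metres.
#' @export
href_bandwidth <- function(fixes) {
  fixes <- as_fix_frame(fixes)
  n <- nrow(fixes)
  stopifnot(n >= 2)
  s2 <- (stats::var(fixes$x) + stats::var(fixes$y)) / 2
  if (s2 <= 0) stop("zero spread: href bandwidth undefined")
  sqrt(s2) * n^(-1 / 6)
}

#' Kernel utilization distribution
#'
#' Bivariate-Gaussian kernel density of the fixes on a square grid:
#' `UD(cell) = (1/n) * sum_i K(||cell - fix_i||; h)`, renormalized so that the
#' density integrates to one over the grid. The default grid covers the
#' bounding box of the fixes padded by `3h` (truncation error < 1% of mass).
#'
#' @param fixes Data.frame with `x`, `y`, or a `trajectory`.
#' @param h Bandwidth (m); default [href_bandwidth()].
#' @param cell_size Grid cell edge (m); default `h / 10`, capped so the grid
#'   stays below ~`max_cells` cells.
#' @param grid Optional list with `origin`, `cell_size`, `dim` overriding the
#'   automatic grid; must cover all fixes with a 3h margin.
#' @param max_cells Soft cap on the number of grid cells.
#' @return A `utilization_distribution`: `origin`, `cell_size`, `density`
#'   (matrix, per m^2), `h`, `n`.
#' @export
kernel_ud <- function(fixes, h = NULL, cell_size = NULL, grid = NULL,
                      max_cells = 4e5) {
  fixes <- as_fix_frame(fixes)
  if (is.null(h)) h <- href_bandwidth(fixes)
  stopifnot(h > 0)
  if (is.null(grid)) {
    pad <- 3 * h
    x0 <- min(fixes$x) - pad; x1 <- max(fixes$x) + pad
    y0 <- min(fixes$y) - pad; y1 <- max(fixes$y) + pad
    if (is.null(cell_size)) {
      cell_size <- h / 10
      need <- ((x1 - x0) / cell_size) * ((y1 - y0) / cell_size)
      if (need > max_cells) cell_size <- sqrt((x1 - x0) * (y1 - y0) / max_cells)
    }
    nx <- ceiling((x1 - x0) / cell_size); ny <- ceiling((y1 - y0) / cell_size)
    origin <- c(x0, y0)
  } else {
    origin <- grid$origin; cell_size <- grid$cell_size
    nx <- grid$dim[1]; ny <- grid$dim[2]
    if (min(fixes$x) - 3 * h < origin[1] ||
        max(fixes$x) + 3 * h > origin[1] + nx * cell_size ||
        min(fixes$y) - 3 * h < origin[2] ||
        max(fixes$y) + 3 * h > origin[2] + ny * cell_size)
      stop("grid too small: must cover all fixes plus a 3h margin")
  }
  gx <- origin[1] + (seq_len(nx) - 0.5) * cell_size
  gy <- origin[2] + (seq_len(ny) - 0.5) * cell_size
  # separable Gaussian: D = Phi_x %*% t(Phi_y) / n
  phx <- outer(gx, fixes$x, function(g, f) stats::dnorm(g, f, h))
  phy <- outer(gy, fixes$y, function(g, f) stats::dnorm(g, f, h))
  dens <- phx %*% t(phy) / nrow(fixes)
  tot <- sum(dens) * cell_size^2
  dens <- dens / tot
  structure(list(origin = origin, cell_size = cell_size, density = dens,
                 h = h, n = nrow(fixes)),
            class = "utilization_distribution")
}

#' @export
print.utilization_distribution <- function(x, ...) {
  d <- dim(x$density)
  cat("Utilization distribution:", d[1], "x", d[2], "cells of",
      round(x$cell_size, 2), "m; h =", round(x$h, 1), "m; n =", x$n, "\n")
  invisible(x)
}

#' Kernel home-range contour at a utilization level
#'
#' The smallest-density-threshold region accumulating at least `level` of the
#' total use mass: cells are sorted by descending density (ties broken by cell
#' index) and included until the cumulative mass reaches the level. The area
#' is the included cell count times the cell area; the isopleth at the
#' resulting density threshold is also polygonized.
#'
#' @param ud A [kernel_ud()] result.
#' @param level Utilization level in (0, 1), e.g. 0.95, 0.75, 0.50.
#' @param bird_id Identifier carried into the estimate.
#' @return A `home_range_estimate` with `cells` (logical matrix of included
#'   cells), `threshold` (density), `polygons`, `area_ha`.
#' @export
ud_contour <- function(ud, level, bird_id = NA_character_) {
  stopifnot(inherits(ud, "utilization_distribution"), level > 0, level < 1)
  cellarea <- ud$cell_size^2
  o <- order(ud$density, decreasing = TRUE)
  mass <- cumsum(ud$density[o]) * cellarea
  ncells <- which(mass >= level)[1]
  if (is.na(ncells)) ncells <- length(o)
  sel <- o[seq_len(ncells)]
  thr <- ud$density[sel[ncells]]
  cells <- matrix(FALSE, nrow(ud$density), ncol(ud$density))
  cells[sel] <- TRUE
  gx <- ud$origin[1] + (seq_len(nrow(cells)) - 0.5) * ud$cell_size
  gy <- ud$origin[2] + (seq_len(ncol(cells)) - 0.5) * ud$cell_size
  if (diff(range(ud$density)) == 0) {
    # flat density: the isopleth is the full grid boundary
    x1 <- ud$origin[1] + nrow(cells) * ud$cell_size
    y1 <- ud$origin[2] + ncol(cells) * ud$cell_size
    polys <- list(cbind(x = c(ud$origin[1], x1, x1, ud$origin[1], ud$origin[1]),
                        y = c(ud$origin[2], ud$origin[2], y1, y1, ud$origin[2])))
  } else {
    cl <- grDevices::contourLines(gx, gy, ud$density, levels = thr)
    polys <- lapply(cl, function(p) {
      r <- cbind(x = p$x, y = p$y)
      rbind(r, r[1, , drop = FALSE])
    })
  }
  structure(list(
    bird_id = bird_id, estimator = paste0("K", round(100 * level)),
    polygons = polys, area_ha = ncells * cellarea / 1e4,
    level = level, threshold = thr, cells = cells,
    origin = ud$origin, cell_size = ud$cell_size, h = ud$h
  ), class = "home_range_estimate")
}

#' Home-range area accumulation curve
#'
#' Area of the MCP95 and K95 estimates on the first k observation days, for
#' k = 2..D: the standard check that the sample size suffices for a stable
#' home-range estimate. The curve is flagged saturated when the final-day
#' increment is below 5% of the final area for both estimators.
#'
#' @param traj A `trajectory` or fix data.frame with `timestamp`, `x`, `y`.
#' @param retention MCP retention fraction.
#' @param level Kernel utilization level.
#' @return Data.frame (`days`, `n_fixes`, `mcp_ha`, `kernel_ha`) with
#'   attribute `saturated` (logical).
#' @export
area_accumulation <- function(traj, retention = 0.95, level = 0.95) {
  fixes <- as_fix_frame(traj)
  day <- as.Date(fixes$timestamp)
  days <- sort(unique(day))
  if (length(days) < 2) stop("need fixes on at least 2 days")
  rows <- lapply(2:length(days), function(k) {
    sub <- fixes[day <= days[k], , drop = FALSE]
    m <- tryCatch(mcp(sub, retention)$area_ha, error = function(e) NA_real_)
    kh <- tryCatch({
      ud <- kernel_ud(sub, cell_size = NULL, max_cells = 1e4)
      ud_contour(ud, level)$area_ha
    }, error = function(e) NA_real_)
    data.frame(days = k, n_fixes = nrow(sub), mcp_ha = m, kernel_ha = kh)
  })
  out <- do.call(rbind, rows)
  sat <- FALSE
  if (nrow(out) >= 2) {
    last <- out[nrow(out), ]; prev <- out[nrow(out) - 1, ]
    sat <- isTRUE(abs(last$mcp_ha - prev$mcp_ha) < 0.05 * last$mcp_ha) &&
      isTRUE(abs(last$kernel_ha - prev$kernel_ha) < 0.05 * last$kernel_ha)
  }
  attr(out, "saturated") <- sat
  out
}

# accept trajectories or plain fix frames
as_fix_frame <- function(x) {
  if (inherits(x, "trajectory")) return(x$fixes)
  stopifnot(is.data.frame(x), all(c("x", "y") %in% names(x)))
  x
}
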