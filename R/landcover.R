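#' Land-cover class schema
#'
#' The eight land-cover classes recognised by the pipeline: the river (line
#' geometry), roads (lines), settlements (points/small polygons), three thicket
#' classes (pure indigenous thicket, mixed thicket of indigenous vegetation with
#' *Lantana camara*, and pure *L. camara* thicket), and two crop classes (low
#' growing crops up to ~80 cm, and taller crops such as maize).
#'
#' @return Character vector of class names.
#' @export
landcover_classes <- function() {
  c("river", "road", "settlement", "indigenous", "mixed", "lantana",
    "crops_low", "crops_high")
}

# classes carried as polygons on the grid
polygon_classes <- function() {
  c("indigenous", "mixed", "lantana", "crops_low", "crops_high", "settlement")
}

#' Construct a land-cover map
#'
#' A grid-backed land-cover map in a metric CRS: a class raster (one polygon
#' class per cell), the river as a polyline, and settlement points. The grid is
#' the canonical representation; vector polygons are derived on export.
#'
#' @param grid Integer matrix, `dim = c(nx, ny)`, with `grid[i, j]` the class
#'   index (into `class_levels`) of the cell whose centre is at
#'   `origin + (c(i, j) - 0.5) * cell_size`.
#' @param origin Numeric length-2, coordinates of the lower-left corner (m).
#' @param cell_size Cell edge length (m).
#' @param class_levels Character vector mapping class indices to class names.
#' @param river Matrix of polyline vertices (x, y) in metres.
#' @param settlements Matrix of settlement points (x, y), or NULL.
#' @param crs CRS label carried through to outputs (free-form, e.g. an EPSG code).
#' @return An object of class `landcover_map`.
#' @export
landcover_map <- function(grid, origin, cell_size, class_levels, river,
                          settlements = NULL, crs = "local-metric") {
  stopifnot(is.matrix(grid), cell_size > 0, length(origin) == 2)
  bad <- setdiff(class_levels, landcover_classes())
  if (length(bad))
    stop("unknown land-cover class(es): ", paste(bad, collapse = ", "))
  structure(list(
    grid = grid, origin = as.numeric(origin), cell_size = cell_size,
    class_levels = class_levels, river = river,
    settlements = settlements, crs = crs
  ), class = "landcover_map")
}

#' @export
print.landcover_map <- function(x, ...) {
  d <- dim(x$grid)
  cat("Land-cover map:", d[1], "x", d[2], "cells of", x$cell_size, "m\n")
  cat("  extent:", paste(round(map_extent(x), 1), collapse = " "), "(m)\n")
  tab <- table(factor(x$class_levels[x$grid], levels = x$class_levels))
  pct <- round(100 * tab / sum(tab), 1)
  cat("  classes:", paste(names(tab), paste0(pct, "%"), collapse = ", "), "\n")
  invisible(x)
}

# extent as c(xmin, xmax, ymin, ymax)
map_extent <- function(map) {
  d <- dim(map$grid)
  c(map$origin[1], map$origin[1] + d[1] * map$cell_size,
    map$origin[2], map$origin[2] + d[2] * map$cell_size)
}

# cell-centre coordinate vectors
grid_centers <- function(map) {
  d <- dim(map$grid)
  list(x = map$origin[1] + (seq_len(d[1]) - 0.5) * map$cell_size,
       y = map$origin[2] + (seq_len(d[2]) - 0.5) * map$cell_size)
}

# cell index (i, j) of points; NA outside the grid
cell_index <- function(map, x, y) {
  d <- dim(map$grid)
  i <- floor((x - map$origin[1]) / map$cell_size) + 1
  j <- floor((y - map$origin[2]) / map$cell_size) + 1
  i[i < 1 | i > d[1]] <- NA
  j[j < 1 | j > d[2]] <- NA
  cbind(i = as.integer(i), j = as.integer(j))
}

#' Land-cover class at point locations
#'
#' Point-in-polygon habitat assignment on the map grid: each point is assigned
#' the class of the grid cell containing it; points outside the mapped extent
#' are returned as `"unmapped"`.
#'
#' @param map A [landcover_map()].
#' @param x,y Point coordinates (m).
#' @return Character vector of class names.
#' @export
class_at <- function(map, x, y) {
  ij <- cell_index(map, x, y)
  out <- rep("unmapped", length(x))
  ok <- !is.na(ij[, 1]) & !is.na(ij[, 2])
  out[ok] <- map$class_levels[map$grid[ij[ok, , drop = FALSE]]]
  out
}

# Merge each class's cells into rectangles (greedy row-run + vertical merge)
# and return per-class lists of rectangular rings for GeoJSON export.
landcover_polygons <- function(map) {
  d <- dim(map$grid); cs <- map$cell_size; o <- map$origin
  out <- list()
  for (k in seq_along(map$class_levels)) {
    cls <- map$class_levels[k]
    if (!cls %in% polygon_classes()) next
    runs <- list()  # each: c(i0, i1, j0, j1) in cell indices
    open <- list()  # runs still growable vertically, keyed by "i0:i1"
    for (j in seq_len(d[2])) {
      col <- map$grid[, j] == k
      r <- rle(col)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      newopen <- list()
      for (q in which(r$values)) {
        key <- paste0(starts[q], ":", ends[q])
        if (!is.null(open[[key]]) && open[[key]][4] == j - 1) {
          open[[key]][4] <- j
          newopen[[key]] <- open[[key]]
          open[[key]] <- NULL
        } else {
          newopen[[key]] <- c(starts[q], ends[q], j, j)
        }
      }
      runs <- c(runs, open)
      open <- newopen
    }
    runs <- c(runs, open)
    rings <- lapply(runs, function(rr) {
      x0 <- o[1] + (rr[1] - 1) * cs; x1 <- o[1] + rr[2] * cs
      y0 <- o[2] + (rr[3] - 1) * cs; y1 <- o[2] + rr[4] * cs
      cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
    })
    if (length(rings)) out[[cls]] <- unname(rings)
  }
  out
}
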