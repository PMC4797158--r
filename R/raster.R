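#' Construct a multi-band raster stack
#'
#' A named stack of co-registered single-band grids sharing one origin, cell
#' size and CRS. Bands are numeric matrices with `dim = c(nx, ny)` indexed like
#' the land-cover grid; `NA` cells are nodata and propagate through band
#' arithmetic.
#'
#' @param bands Named list of numeric matrices, all with identical dimensions.
#' @param origin Numeric length-2, lower-left corner (m).
#' @param cell_size Cell edge length (m).
#' @param crs CRS label.
#' @return An object of class `raster_stack`.
#' @export
raster_stack <- function(bands, origin, cell_size, crs = "local-metric") {
  stopifnot(is.list(bands), length(bands) >= 1, !is.null(names(bands)))
  d <- dim(bands[[1]])
  for (b in bands) stopifnot(is.matrix(b), identical(dim(b), d))
  structure(list(bands = bands, origin = as.numeric(origin),
                 cell_size = cell_size, crs = crs),
            class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$bands[[1]])
  cat("Raster stack:", d[1], "x", d[2], "cells of", x$cell_size, "m;",
      length(x$bands), "band(s)\n")
  cat("  bands:", paste(names(x$bands), collapse = ", "), "\n")
  invisible(x)
}

raster_centers <- function(stack) {
  d <- dim(stack$bands[[1]])
  list(x = stack$origin[1] + (seq_len(d[1]) - 0.5) * stack$cell_size,
       y = stack$origin[2] + (seq_len(d[2]) - 0.5) * stack$cell_size)
}

raster_cell_index <- function(stack, x, y) {
  d <- dim(stack$bands[[1]])
  i <- floor((x - stack$origin[1]) / stack$cell_size) + 1
  j <- floor((y - stack$origin[2]) / stack$cell_size) + 1
  i[i < 1 | i > d[1]] <- NA
  j[j < 1 | j > d[2]] <- NA
  cbind(i = as.integer(i), j = as.integer(j))
}

# flat predictor matrix (cells x bands) for selected band names
raster_values <- function(stack, bands = names(stack$bands)) {
  vapply(bands, function(b) as.vector(stack$bands[[b]]),
         numeric(length(stack$bands[[1]])))
}
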