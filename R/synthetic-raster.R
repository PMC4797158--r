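#' Specify class-conditional band reflectances
#'
#' Mean top-of-atmosphere reflectance (unitless, 0-1) of each land-cover class
#' in the five multispectral channels (Blue 440-510 nm, Green 520-590 nm, Red
#' 630-685 nm, RedEdge 690-730 nm, NIR 760-850 nm), plus i.i.d. Gaussian cell
#' noise. Defaults sketch plausible signatures: dense green thicket with a
#' strong NIR plateau and red absorption, brighter sparse crops, bright
#' settlement soil/roofs; pure *L. camara* thicket is given a slightly
#' distinct red-edge/NIR signature so that a spectral sub-model can learn it.
#'
#' @param means Matrix of class-mean reflectances (rows = classes, columns =
#'   Blue, Green, Red, RedEdge, NIR), values in [0, 1].
#' @param noise_sd Per-cell Gaussian noise s.d. (same units).
#' @param seed Integer seed.
#' @return An object of class `spectral_spec`.
#' @export
spectral_spec <- function(means = default_spectra(), noise_sd = 0.02, seed = 1L) {
  stopifnot(is.matrix(means), ncol(means) == 5, noise_sd >= 0,
            all(means >= 0), all(means <= 1))
  colnames(means) <- c("Blue", "Green", "Red", "RedEdge", "NIR")
  structure(list(means = means, noise_sd = noise_sd, seed = seed),
            class = "spectral_spec")
}

#' Default class-mean spectra
#' @return Matrix of per-class band means in [0, 1].
#' @export
default_spectra <- function() {
  m <- rbind(
    indigenous = c(0.04, 0.07, 0.04, 0.18, 0.42),
    mixed      = c(0.05, 0.08, 0.05, 0.22, 0.46),
    lantana    = c(0.05, 0.10, 0.04, 0.30, 0.55),
    crops_low  = c(0.08, 0.14, 0.12, 0.24, 0.38),
    crops_high = c(0.07, 0.12, 0.10, 0.26, 0.44),
    settlement = c(0.18, 0.22, 0.24, 0.28, 0.32)
  )
  colnames(m) <- c("Blue", "Green", "Red", "RedEdge", "NIR")
  m
}

#' Generate a synthetic 5-band reflectance raster
#'
#' Each cell's band value is drawn from Normal(class mean, noise s.d.) and
#' truncated to [0, 1]; the grid is the land-cover grid.
#'
#' @param map A [landcover_map()].
#' @param spec A [spectral_spec()].
#' @return A [raster_stack()] with bands Blue, Green, Red, RedEdge, NIR.
#' @export
generate_raster <- function(map, spec) {
  stopifnot(inherits(map, "landcover_map"), inherits(spec, "spectral_spec"))
  miss <- setdiff(map$class_levels, rownames(spec$means))
  if (length(miss)) stop("spectral_spec lacks classes: ", paste(miss, collapse = ", "))
  d <- dim(map$grid)
  cls <- map$class_levels[map$grid]
  with_seed(spec$seed, {
    bands <- lapply(colnames(spec$means), function(b) {
      v <- spec$means[cls, b]
      if (spec$noise_sd > 0) v <- v + stats::rnorm(length(v), 0, spec$noise_sd)
      matrix(pmin(pmax(v, 0), 1), d[1], d[2])
    })
    names(bands) <- colnames(spec$means)
    raster_stack(bands, origin = map$origin, cell_size = map$cell_size,
                 crs = map$crs)
  })
}
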