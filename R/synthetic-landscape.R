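#' Specify a synthetic riparian landscape
#'
#' Parameters of the synthetic river-centred landscape mosaic: a meandering
#' river crossing the extent, thicket classes (indigenous, mixed, pure
#' *L. camara*) concentrated in a buffer along the river, two crop classes and
#' scattered settlements filling the remainder. Class area fractions are
#' targets; the remainder (1 - sum) is tall crops (`crops_high`), the
#' agricultural background matrix.
#'
#' @param extent Numeric length-4 `c(xmin, xmax, ymin, ymax)` in metres.
#' @param cell_size Grid cell edge (m).
#' @param class_mix Named numeric vector of target area fractions for (a subset
#'   of) `indigenous`, `mixed`, `lantana`, `crops_low`, `settlement`; must sum
#'   to at most 1.
#' @param buffer_width Width (m) of the river corridor in which thicket classes
#'   are concentrated.
#' @param n_patches Number of Voronoi seed patches tiling the extent.
#' @param river_amplitude,river_wavelength Shape of the meandering river (m).
#' @param seed Integer seed; same seed, same landscape.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(extent = c(0, 2000, 0, 2000),
                           cell_size = 10,
                           class_mix = c(indigenous = 0.01, mixed = 0.03,
                                         lantana = 0.13, crops_low = 0.09,
                                         settlement = 0.04),
                           buffer_width = 400,
                           n_patches = 180,
                           river_amplitude = NULL,
                           river_wavelength = NULL,
                           seed = 1L) {
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3],
            cell_size > 0, buffer_width > 0, n_patches >= 8)
  allowed <- c("indigenous", "mixed", "lantana", "crops_low", "settlement")
  bad <- setdiff(names(class_mix), allowed)
  if (length(bad)) stop("class_mix has unknown classes: ", paste(bad, collapse = ", "))
  if (any(class_mix < 0)) stop("class_mix fractions must be >= 0")
  if (sum(class_mix) > 1)
    stop("infeasible class_mix: fractions sum to ", round(sum(class_mix), 3),
         " > 1 (remainder must be left for crops_high)")
  if (is.null(river_amplitude)) river_amplitude <- 0.08 * (extent[4] - extent[3])
  if (is.null(river_wavelength)) river_wavelength <- 0.6 * (extent[2] - extent[1])
  structure(list(extent = extent, cell_size = cell_size, class_mix = class_mix,
                 buffer_width = buffer_width, n_patches = n_patches,
                 river_amplitude = river_amplitude,
                 river_wavelength = river_wavelength, seed = seed),
            class = "landscape_spec")
}

#' Generate a synthetic land-cover map
#'
#' Builds a river-hugging landscape mosaic: the extent is tiled by
#' Voronoi-seeded patches, patches are ranked by their mean distance to the
#' meandering river, and classes claim patches in priority order — pure
#' *L. camara* thicket, then mixed thicket, then indigenous thicket from the
#' river outwards (within the corridor), settlements from the far end, low
#' crops in between — until each target fraction is met; unclaimed patches
#' become tall crops.
#'
#' @param spec A [landscape_spec()].
#' @return A [landcover_map()].
#' @export
generate_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  with_seed(spec$seed, {
    ext <- spec$extent; cs <- spec$cell_size
    nx <- max(2L, floor((ext[2] - ext[1]) / cs))
    ny <- max(2L, floor((ext[4] - ext[3]) / cs))
    cx <- ext[1] + (seq_len(nx) - 0.5) * cs
    cy <- ext[3] + (seq_len(ny) - 0.5) * cs
    px <- rep(cx, times = ny); py <- rep(cy, each = nx)

    # meandering river west->east through the vertical midline
    rx <- seq(ext[1], ext[2], length.out = 120)
    ymid <- (ext[3] + ext[4]) / 2
    phase <- stats::runif(1, 0, 2 * pi)
    ry <- ymid + spec$river_amplitude * sin(2 * pi * rx / spec$river_wavelength + phase) +
      spec$river_amplitude * 0.3 * sin(4.7 * pi * rx / spec$river_wavelength + 2 * phase)
    ry <- pmin(pmax(ry, ext[3] + cs), ext[4] - cs)
    river <- cbind(x = rx, y = ry)

    d_river <- dist_to_polyline(px, py, river)

    # Voronoi patches: nearest of n_patches uniform seeds
    sx <- stats::runif(spec$n_patches, ext[1], ext[2])
    sy <- stats::runif(spec$n_patches, ext[3], ext[4])
    patch <- max.col(-(outer(px, sx, "-")^2 + outer(py, sy, "-")^2),
                     ties.method = "first")

    patch_dist <- tapply(d_river, patch, mean)
    patch_n <- tapply(rep(1, length(patch)), patch, sum)
    ids <- as.integer(names(patch_dist))
    ncell <- length(px)

    # claim patches for a class until its target fraction is reached
    assigned <- rep(NA_character_, length(ids))
    claim <- function(class, frac, order_ids, within = NULL) {
      if (is.na(frac) || frac <= 0) return(invisible(NULL))
      got <- sum(patch_n[which(assigned == class)])  # resume partial claims
      for (pid in order_ids) {
        k <- match(pid, ids)
        if (!is.na(assigned[k])) next
        if (!is.null(within) && !within[k]) next
        if (got >= frac * ncell) break
        # include the patch only if it moves the realized fraction closer
        if (abs(got + patch_n[k] - frac * ncell) <= abs(got - frac * ncell)) {
          assigned[k] <<- class
          got <- got + patch_n[k]
        } else break
      }
      invisible(NULL)
    }

    # claim a contiguous cluster of corridor patches around a random nucleus
    # (thickets form coherent multi-hectare bands along the river, large
    # enough to hold a bird's core area, interspersed with farm plots)
    claim_clustered <- function(class, frac, n_clusters, within) {
      if (is.na(frac) || frac <= 0) return(invisible(NULL))
      target <- frac * ncell
      total <- 0
      for (cl in seq_len(n_clusters)) {
        remaining <- target - total
        if (remaining <= 0) break
        per_cluster <- remaining / (n_clusters - cl + 1)
        open <- which(is.na(assigned) & within)
        if (!length(open)) break
        # pick a nucleus that does not overshoot the remaining quota
        cand <- if (length(open) == 1) open else sample(open)
        nucleus <- NA_integer_
        for (k in cand) {
          if (abs(total + patch_n[k] - target) <= abs(total - target)) {
            nucleus <- k
            break
          }
        }
        if (is.na(nucleus)) break
        members <- nucleus
        got <- patch_n[nucleus]
        assigned[nucleus] <<- class
        while (got < per_cluster) {
          open <- which(is.na(assigned) & within)
          if (!length(open)) break
          # nearest open patch to any cluster member
          dmin <- vapply(open, function(k)
            min((sx[ids[k]] - sx[ids[members]])^2 +
                (sy[ids[k]] - sy[ids[members]])^2), 0)
          k <- open[which.min(dmin)]
          if (abs(total + got + patch_n[k] - target) >
              abs(total + got - target))
            break
          assigned[k] <<- class
          members <- c(members, k)
          got <- got + patch_n[k]
        }
        total <- total + got
      }
      invisible(NULL)
    }

    near_order <- ids[order(patch_dist)]
    far_order <- ids[order(patch_dist, decreasing = TRUE)]
    in_corridor <- patch_dist <= spec$buffer_width
    mix <- spec$class_mix
    claim_clustered("lantana", mix["lantana"], 3, in_corridor)
    claim_clustered("mixed", mix["mixed"], 3, in_corridor)
    claim_clustered("indigenous", mix["indigenous"], 2, in_corridor)
    # spill-over if the corridor is full
    claim("lantana", mix["lantana"], near_order)
    claim("mixed", mix["mixed"], near_order)
    claim("indigenous", mix["indigenous"], near_order)
    claim("settlement", mix["settlement"], far_order)
    claim("crops_low", mix["crops_low"], sample(ids))
    assigned[is.na(assigned)] <- "crops_high"

    levels <- intersect(polygon_classes(), unique(assigned))
    grid <- matrix(match(assigned[match(patch, ids)], levels), nx, ny)

    settle <- which(assigned == "settlement")
    settlements <- if (length(settle)) {
      cbind(x = sx[ids[settle]], y = sy[ids[settle]])
    } else NULL

    landcover_map(grid, origin = c(ext[1], ext[3]), cell_size = cs,
                  class_levels = levels, river = river,
                  settlements = settlements)
  })
}
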