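#' Triangulate one pair of simultaneous bearings
#'
#' Locates a transmitter at the intersection of the two forward rays defined by
#' the observer positions and compass azimuths (degrees clockwise from grid
#' north). The intersection must lie on the forward half-line of both rays;
#' near-parallel bearings have no usable solution.
#'
#' @param a_pos,b_pos Numeric length-2 observer positions (m), distinct.
#' @param a_az,b_az Azimuths (degrees, clockwise from north).
#' @param tol Parallelism tolerance on |sin(azimuth difference)|.
#' @return Numeric length-2 position `c(x, y)`.
#' @export
triangulate <- function(a_pos, a_az, b_pos, b_az, tol = 1e-8) {
  stopifnot(length(a_pos) == 2, length(b_pos) == 2)
  if (all(a_pos == b_pos)) stop("observers must be at distinct positions")
  da <- as.numeric(az_vec(a_az)); db <- as.numeric(az_vec(b_az))
  denom <- da[1] * db[2] - da[2] * db[1]  # sin(a_az - b_az)
  if (abs(denom) < tol)
    stop("no solution: bearings are (near-)parallel")
  rx <- b_pos[1] - a_pos[1]; ry <- b_pos[2] - a_pos[2]
  t_a <- (rx * db[2] - ry * db[1]) / denom
  t_b <- (rx * da[2] - ry * da[1]) / denom
  if (t_a < 0 || t_b < 0)
    stop("back-bearing: intersection lies behind an observer")
  c(x = a_pos[1] + t_a * da[1], y = a_pos[2] + t_a * da[2])
}

#' Triangulate a table of paired bearings into fixes
#'
#' Vectorized triangulation over a bearings table (one row per simultaneous
#' pair, the layout written by [generate_bearings()] / read from the bearings
#' CSV). Rows whose rays are near-parallel or intersect behind an observer
#' yield invalid fixes (`NA` position) rather than errors.
#'
#' @param bearings Data.frame with columns `bird_id`, `timestamp`, `obs_a_x`,
#'   `obs_a_y`, `obs_a_az`, `obs_b_x`, `obs_b_y`, `obs_b_az`.
#' @param tol Parallelism tolerance.
#' @return Data.frame of fixes: `bird_id`, `timestamp`, `x`, `y`, `dist_a`,
#'   `dist_b`, `valid` (geometrically valid solution).
#' @export
triangulate_bearings <- function(bearings, tol = 1e-8) {
  need <- c("bird_id", "timestamp", "obs_a_x", "obs_a_y", "obs_a_az",
            "obs_b_x", "obs_b_y", "obs_b_az")
  miss <- setdiff(need, names(bearings))
  if (length(miss)) stop("bearings table lacks columns: ", paste(miss, collapse = ", "))
  da <- az_vec(bearings$obs_a_az); db <- az_vec(bearings$obs_b_az)
  denom <- da[, 1] * db[, 2] - da[, 2] * db[, 1]
  rx <- bearings$obs_b_x - bearings$obs_a_x
  ry <- bearings$obs_b_y - bearings$obs_a_y
  t_a <- (rx * db[, 2] - ry * db[, 1]) / denom
  t_b <- (rx * da[, 2] - ry * da[, 1]) / denom
  ok <- abs(denom) >= tol & t_a >= 0 & t_b >= 0
  x <- ifelse(ok, bearings$obs_a_x + t_a * da[, 1], NA_real_)
  y <- ifelse(ok, bearings$obs_a_y + t_a * da[, 2], NA_real_)
  data.frame(
    bird_id = bearings$bird_id, timestamp = bearings$timestamp,
    x = x, y = y,
    dist_a = sqrt((x - bearings$obs_a_x)^2 + (y - bearings$obs_a_y)^2),
    dist_b = sqrt((x - bearings$obs_b_x)^2 + (y - bearings$obs_b_y)^2),
    valid = ok
  )
}

#' Filter fixes by observer distance
#'
#' Drops fixes located more than `max_dist` metres from either observer
#' (potential tracking errors at long range); the rule is strict, so fixes at
#' exactly `max_dist` are retained. Invalid fixes (failed triangulation) are
#' dropped as well. Order is preserved and the number of removed fixes is
#' reported as an attribute and a message.
#'
#' @param fixes Data.frame with `dist_a`, `dist_b` (and optionally `valid`).
#' @param max_dist Distance cutoff (m).
#' @param quiet Suppress the removal message.
#' @return The retained rows, with attribute `n_removed`.
#' @export
filter_fixes <- function(fixes, max_dist = 1000, quiet = FALSE) {
  if (nrow(fixes) == 0) {
    attr(fixes, "n_removed") <- 0L
    return(fixes)
  }
  keep <- fixes$dist_a <= max_dist & fixes$dist_b <= max_dist
  if (!is.null(fixes$valid)) keep <- keep & fixes$valid
  keep[is.na(keep)] <- FALSE
  out <- fixes[keep, , drop = FALSE]
  n_rm <- sum(!keep)
  if (!quiet && n_rm > 0)
    message(n_rm, " fix(es) removed (> ", max_dist, " m from an observer or invalid)")
  attr(out, "n_removed") <- n_rm
  out
}

#' Build a trajectory from one bird's fixes
#'
#' Orders the fixes in time and derives the per-step quantities the downstream
#' analyses use: Euclidean step length (m), time gap (min), absolute heading
#' (degrees clockwise from north) and turning angle (change of heading,
#' degrees wrapped to (-180, 180], positive clockwise; defined from the second
#' step on).
#'
#' @param fixes Data.frame with `bird_id`, `timestamp`, `x`, `y` for a single
#'   individual; at least 2 fixes, strictly increasing timestamps.
#' @return An object of class `trajectory`: list with `bird_id`, `fixes`, and
#'   `steps` (`length`, `dt_min`, `heading`, `turn`).
#' @export
build_trajectory <- function(fixes) {
  stopifnot(nrow(fixes) >= 2)
  if (length(unique(fixes$bird_id)) > 1)
    stop("build_trajectory expects fixes of a single individual")
  o <- order(fixes$timestamp)
  fixes <- fixes[o, , drop = FALSE]
  if (any(duplicated(fixes$timestamp)))
    stop("duplicate timestamps in fixes")
  dx <- diff(fixes$x); dy <- diff(fixes$y)
  len <- sqrt(dx^2 + dy^2)
  dt <- as.numeric(difftime(fixes$timestamp[-1], fixes$timestamp[-nrow(fixes)],
                            units = "mins"))
  heading <- azimuth_deg(dx, dy)
  turn <- c(NA_real_, wrap_deg_180(diff(heading)))
  structure(list(
    bird_id = fixes$bird_id[1],
    fixes = fixes[, c("bird_id", "timestamp", "x", "y")],
    steps = data.frame(length = len, dt_min = dt, heading = heading, turn = turn)
  ), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Trajectory of", x$bird_id, "-", nrow(x$fixes), "fixes,",
      nrow(x$steps), "steps\n")
  cat("  median step:", round(stats::median(x$steps$length), 1), "m;",
      "median gap:", round(stats::median(x$steps$dt_min), 1), "min\n")
  invisible(x)
}
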