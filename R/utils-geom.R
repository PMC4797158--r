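# Internal planar-geometry helpers. All coordinates are metres in a projected CRS.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' @noRd
wrap_deg_360 <- function(a) {
  a <- a %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

# wrap to (-180, 180]
wrap_deg_180 <- function(a) {
  a <- (a + 180) %% 360 - 180
  a[a == -180] <- 180
  a
}

# azimuth (deg clockwise from grid north) of displacement (dx, dy)
azimuth_deg <- function(dx, dy) wrap_deg_360(rad2deg(atan2(dx, dy)))

# unit vector of an azimuth: east = sin, north = cos
az_vec <- function(az_deg) {
  a <- deg2rad(az_deg)
  cbind(sin(a), cos(a))
}

# signed shoelace area of a closed or open ring (matrix with x, y columns)
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  if (n < 3) return(0)
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1 }
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# convex hull of points as a counter-clockwise ring (closed)
convex_hull_ring <- function(x, y) {
  idx <- grDevices::chull(x, y)
  ring <- cbind(x = x[idx], y = y[idx])
  rbind(ring, ring[1, , drop = FALSE])
}

# points inside any of a list of rings (even-odd rule via mgcv::in.out)
points_in_rings <- function(rings, px, py) {
  if (is.matrix(rings)) rings <- list(rings)
  bnd <- do.call(rbind, lapply(rings, function(r) {
    r <- as.matrix(r[, 1:2, drop = FALSE])
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, , drop = FALSE])
    rbind(r, c(NA_real_, NA_real_))
  }))
  bnd <- bnd[-nrow(bnd), , drop = FALSE]
  mgcv::in.out(bnd, cbind(px, py))
}

# min distance from points (px, py) to a polyline (matrix of vertices)
dist_to_polyline <- function(px, py, line) {
  n <- nrow(line)
  stopifnot(n >= 2)
  best <- rep(Inf, length(px))
  for (i in seq_len(n - 1)) {
    best <- pmin(best, dist_to_segment(px, py, line[i, 1], line[i, 2],
                                       line[i + 1, 1], line[i + 1, 2]))
  }
  best
}

dist_to_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  l2 <- dx * dx + dy * dy
  if (l2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / l2))
  sqrt((px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2)
}

# min distance from points to a set of points (columns x, y), chunked
dist_to_points <- function(px, py, pts) {
  pts <- matrix(pts, ncol = 2)
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(pts))) {
    best <- pmin(best, sqrt((px - pts[i, 1])^2 + (py - pts[i, 2])^2))
  }
  best
}

# Exact Euclidean distance transform (Felzenszwalb & Huttenlocher) of a logical
# matrix: distance in grid units from every cell to the nearest TRUE cell.
distance_transform <- function(mask) {
  INF <- 1e15
  f <- matrix(INF, nrow(mask), ncol(mask))
  f[mask] <- 0
  d2 <- apply(f, 2, edt_1d)          # along rows (x index) per column
  d2 <- t(apply(d2, 1, edt_1d))      # then along columns per row
  sqrt(d2)
}

# 1-D squared distance transform of a vector of squared costs
edt_1d <- function(f) {
  n <- length(f)
  if (n < 2) return(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    s <- ((f[q] + q * q) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    while (s <= z[k]) {
      k <- k - 1L
      s <- ((f[q] + q * q) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}
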