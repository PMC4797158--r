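# Shared synthetic fixtures, built once per test run. Sizes are kept small:
# the default landscape is 2 x 2 km at 10 m cells, tracks are a few hundred
# fixes, which is enough for every statistical check here.

fixture_map <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_landscape(landscape_spec(seed = 7))
    val
  }
})

fixture_track <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- generate_track(fixture_map(),
                             movement_spec(n_fixes = 300, seed = 11), "T1")
    val
  }
})

# a tiny hand-built two-class map: west half lantana, east half crops_high,
# straight river along the southern edge
tiny_map <- function(nx = 20, ny = 20, cell = 10) {
  grid <- matrix(2L, nx, ny)
  grid[seq_len(nx / 2), ] <- 1L
  landcover_map(grid, origin = c(0, 0), cell_size = cell,
                class_levels = c("lantana", "crops_high"),
                river = cbind(x = c(0, nx * cell), y = c(0, 0)),
                settlements = cbind(x = 145, y = 145))  # on a cell centre
}

# deterministic uniform fixes in a box
uniform_fixes <- function(n, xmax = 1000, ymax = 1000, seed = 42) {
  withr::with_seed(seed, data.frame(
    bird_id = "U1",
    timestamp = as.POSIXct("2014-08-08 07:00:00", tz = "UTC") + 600 * seq_len(n),
    x = runif(n, 0, xmax), y = runif(n, 0, ymax)))
}

# shoelace area of a closed ring, written independently of the package
oracle_ring_area <- function(xs, ys) {
  n <- length(xs)
  s <- 0
  for (i in seq_len(n - 1)) s <- s + xs[i] * ys[i + 1] - xs[i + 1] * ys[i]
  abs(s) / 2
}
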