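# Seeded-randomness helpers. Every generator funnels its randomness through
# with_seed() so that a given seed yields bit-identical output and the caller's
# RNG stream is left untouched.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# derive a distinct 31-bit child seed from a parent seed and a stream label
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (c in utf8ToInt(as.character(stream))) h <- (h * 131 + c) %% 1e7
  as.integer((as.numeric(seed) * 7919 + h) %% (.Machine$integer.max - 1))
}

# von Mises sampler, Best & Fisher (1979) rejection algorithm.
# mu in radians, kappa >= 0; returns values wrapped to (-pi, pi].
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (kappa < 1e-9) {
    th <- stats::runif(n, -pi, pi) + mu
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    i <- 0L
    while (i < n) {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        i <- i + 1L
        th[i] <- mu + sign(u[3] - 0.5) * acos(f)
      }
    }
  }
  th <- (th + pi) %% (2 * pi) - pi
  th[th == -pi] <- pi
  th
}

# gamma draws parameterized by mean and coefficient of variation
rgamma_mean_cv <- function(n, mean, cv) {
  stopifnot(mean > 0)
  if (cv <= 0) return(rep(mean, n))
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}
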