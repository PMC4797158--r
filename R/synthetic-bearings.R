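#' Generate paired observer bearings for a track
#'
#' Emulates two observers taking simultaneous compass bearings on the tagged
#' bird at every fix: for each fix the true azimuth from each observer is
#' perturbed with Gaussian noise (in degrees) and wrapped to [0, 360).
#'
#' @param traj A `trajectory` (or a data.frame of fixes with `x`, `y`,
#'   `timestamp`, `bird_id`).
#' @param observer_a,observer_b Numeric length-2 observer positions (m); must
#'   not be co-located.
#' @param noise_sd_deg Standard deviation of bearing noise (degrees).
#' @param seed Integer seed.
#' @return A data.frame with one row per fix: `bird_id`, `timestamp`,
#'   `obs_a_x`, `obs_a_y`, `obs_a_az`, `obs_b_x`, `obs_b_y`, `obs_b_az`.
#' @export
generate_bearings <- function(traj, observer_a, observer_b,
                              noise_sd_deg = 0, seed = NULL) {
  fixes <- if (inherits(traj, "trajectory")) traj$fixes else traj
  stopifnot(length(observer_a) == 2, length(observer_b) == 2,
            noise_sd_deg >= 0)
  if (all(observer_a == observer_b))
    stop("observers must not be co-located")
  n <- nrow(fixes)
  with_seed(seed, {
    az_a <- azimuth_deg(fixes$x - observer_a[1], fixes$y - observer_a[2])
    az_b <- azimuth_deg(fixes$x - observer_b[1], fixes$y - observer_b[2])
    if (noise_sd_deg > 0) {
      az_a <- wrap_deg_360(az_a + stats::rnorm(n, 0, noise_sd_deg))
      az_b <- wrap_deg_360(az_b + stats::rnorm(n, 0, noise_sd_deg))
    }
    data.frame(
      bird_id = fixes$bird_id, timestamp = fixes$timestamp,
      obs_a_x = observer_a[1], obs_a_y = observer_a[2], obs_a_az = az_a,
      obs_b_x = observer_b[1], obs_b_y = observer_b[2], obs_b_az = az_b
    )
  })
}
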