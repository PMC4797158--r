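#' Random-walk null model for site fidelity
#'
#' Bootstrap null distribution of home-range size: each simulation resamples
#' the observed step lengths and turning angles (independently, with
#' replacement by default), rebuilds a path from the observed start point and
#' initial heading, and computes the home-range areas. Site fidelity is
#' flagged when the observed area lies below the 2.5th percentile of the
#' simulated areas (i.e. below the null model's 95% confidence interval).
#'
#' @param traj A `trajectory` with at least 10 steps.
#' @param n_sims Number of simulated paths (1000 in the field protocol).
#' @param seed Integer seed; same seed, same simulated-area vectors.
#' @param estimators Subset of `c("MCP95", "K75")` to evaluate.
#' @param replace Resample with replacement (bootstrap, default) or permute.
#' @param joint Resample (length, turn) jointly as observed pairs instead of
#'   independently.
#' @param kernel_cells Grid cell count cap for the per-simulation kernel UD.
#' @param keep_paths Also return the simulated paths (list of x/y matrices);
#'   intended for diagnostics.
#' @return Named list of `rwm_result` objects (one per estimator), each with
#'   `bird_id`, `estimator`, `observed_ha`, `sim_ha`, `ci` (2.5/97.5
#'   percentiles), `site_fidelity`, `n_sims`, `seed`.
#' @export
rwm_simulate <- function(traj, n_sims = 1000, seed = NULL,
                         estimators = c("MCP95", "K75"),
                         replace = TRUE, joint = FALSE,
                         kernel_cells = 4e3, keep_paths = FALSE) {
  stopifnot(inherits(traj, "trajectory"))
  estimators <- match.arg(estimators, several.ok = TRUE)
  st <- traj$steps
  if (nrow(st) < 10) stop("need at least 10 steps for the null model")
  if (stats::var(traj$fixes$x) + stats::var(traj$fixes$y) == 0)
    stop("degenerate trajectory: all fixes identical")
  lengths <- st$length
  turns <- st$turn[-1]          # first step anchors the heading
  h0 <- st$heading[1]
  x0 <- traj$fixes$x[1]; y0 <- traj$fixes$y[1]
  n_len <- length(lengths); n_turn <- length(turns)

  observed <- list(
    MCP95 = mcp(traj, 0.95)$area_ha,
    K75 = if ("K75" %in% estimators) {
      ud <- kernel_ud(traj, max_cells = kernel_cells)
      ud_contour(ud, 0.75)$area_ha
    } else NA_real_
  )

  paths <- if (keep_paths) vector("list", n_sims)
  sim_area <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      if (joint) {
        idx <- sample.int(n_turn, n_turn, replace = replace)
        L <- lengths[c(sample.int(n_len, 1), idx + 1)]
        A <- turns[idx]
      } else {
        L <- lengths[sample.int(n_len, n_len, replace = replace)]
        A <- turns[sample.int(n_turn, n_turn, replace = replace)]
      }
      head <- deg2rad(h0) + cumsum(c(0, deg2rad(A)))
      x <- x0 + cumsum(c(0, L * sin(head)))
      y <- y0 + cumsum(c(0, L * cos(head)))
      fx <- data.frame(x = x, y = y)
      if (keep_paths) paths[[s]] <<- cbind(x = x, y = y)
      out <- c(MCP95 = NA_real_, K75 = NA_real_)
      if ("MCP95" %in% estimators)
        out["MCP95"] <- tryCatch(mcp(fx, 0.95)$area_ha, error = function(e) NA_real_)
      if ("K75" %in% estimators)
        out["K75"] <- tryCatch({
          ud <- kernel_ud(fx, max_cells = kernel_cells)
          ud_contour(ud, 0.75)$area_ha
        }, error = function(e) NA_real_)
      out
    }, c(MCP95 = 0, K75 = 0))
  })

  res <- lapply(estimators, function(est) {
    sims <- sim_area[est, ]
    ci <- stats::quantile(sims, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
    structure(list(
      bird_id = traj$bird_id, estimator = est,
      observed_ha = observed[[est]], sim_ha = sims,
      ci = c(lower = ci[1], upper = ci[2]),
      site_fidelity = observed[[est]] < ci[1],
      n_sims = n_sims, seed = seed,
      paths = if (keep_paths) paths
    ), class = "rwm_result")
  })
  names(res) <- estimators
  res
}

#' @export
print.rwm_result <- function(x, ...) {
  cat("RWM null (", x$estimator, ", ", x$n_sims, " sims) for ", x$bird_id, ":\n",
      sep = "")
  cat("  observed ", round(x$observed_ha, 2), " ha; null 95% CI [",
      round(x$ci[1], 2), ", ", round(x$ci[2], 2), "] ha; site fidelity: ",
      x$site_fidelity, "\n", sep = "")
  invisible(x)
}

#' Summarize random-walk null results for a cohort
#'
#' @param results List of `rwm_result` objects (possibly nested lists as
#'   returned by [rwm_simulate()]).
#' @return Data.frame (`bird_id`, `estimator`, `observed_ha`, `ci_lo`,
#'   `ci_hi`, `site_fidelity`, `n_sims`) with attribute `fidelity_fraction`.
#' @export
rwm_report <- function(results) {
  if (inherits(results, "rwm_result")) results <- list(results)
  flat <- list()
  for (r in results) {
    if (inherits(r, "rwm_result")) flat <- c(flat, list(r))
    else flat <- c(flat, Filter(function(z) inherits(z, "rwm_result"), r))
  }
  if (!length(flat)) stop("no RWM results to report")
  out <- do.call(rbind, lapply(flat, function(r) data.frame(
    bird_id = r$bird_id, estimator = r$estimator,
    observed_ha = r$observed_ha, ci_lo = r$ci[1], ci_hi = r$ci[2],
    site_fidelity = r$site_fidelity, n_sims = r$n_sims, row.names = NULL
  )))
  attr(out, "fidelity_fraction") <- mean(out$site_fidelity)
  out
}
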