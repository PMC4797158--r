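#' Feature expansion for the maximum-entropy model
#'
#' Standardizes each predictor by its background mean and standard deviation
#' and expands it into the configured feature classes: linear (z), quadratic
#' (z^2), and pairwise products (z_j z_k). Predictors with zero background
#' spread are dropped. Features are computed identically for presence and
#' background points.
#'
#' @param background Numeric matrix (cells x predictors) with column names.
#' @param features Character subset of `c("linear", "quadratic", "product")`.
#' @return An object of class `feature_expansion` with `$expand(newdata)`.
#' @export
feature_expansion <- function(background,
                              features = c("linear", "quadratic", "product")) {
  features <- match.arg(features, several.ok = TRUE)
  background <- as.matrix(background)
  if (is.null(colnames(background)))
    colnames(background) <- paste0("V", seq_len(ncol(background)))
  mu <- colMeans(background)
  sd <- apply(background, 2, stats::sd)
  keep <- sd > 0
  # constant predictors carry no information; with none left the expansion is
  # empty and the fitted model is the uniform (maximum-entropy) density
  mu <- mu[keep]; sd <- sd[keep]
  nm <- names(mu)
  defs <- list()
  for (j in seq_along(nm))
    if ("linear" %in% features)
      defs[[length(defs) + 1]] <- list(type = "linear", vars = nm[j])
  for (j in seq_along(nm))
    if ("quadratic" %in% features)
      defs[[length(defs) + 1]] <- list(type = "quadratic", vars = nm[j])
  if ("product" %in% features && length(nm) > 1) {
    for (j in seq_len(length(nm) - 1))
      for (k in (j + 1):length(nm))
        defs[[length(defs) + 1]] <- list(type = "product", vars = c(nm[j], nm[k]))
  }
  obj <- list(mu = mu, sd = sd, defs = defs, predictors = nm)
  obj$feature_names <- vapply(defs, function(d)
    paste(c(d$type, d$vars), collapse = ":"), "")
  class(obj) <- "feature_expansion"
  obj
}

# feature matrix for new data (rows x features)
expand_features <- function(fx, newdata) {
  newdata <- as.matrix(newdata)
  z <- sweep(sweep(newdata[, fx$predictors, drop = FALSE], 2, fx$mu), 2, fx$sd, "/")
  out <- matrix(NA_real_, nrow(z), length(fx$defs))
  for (i in seq_along(fx$defs)) {
    d <- fx$defs[[i]]
    out[, i] <- switch(d$type,
      linear = z[, d$vars],
      quadratic = z[, d$vars]^2,
      product = z[, d$vars[1]] * z[, d$vars[2]])
  }
  colnames(out) <- fx$feature_names
  out
}

#' Fit a maximum-entropy presence-background model
#'
#' Fits the Gibbs density `q(x) = exp(lambda . f(x)) / Z` over the background
#' cells by minimizing the L1-regularized negative log-likelihood of the
#' presence points, using cyclic coordinate descent with a proximal Newton
#' step per feature (soft thresholding at zero). Per-feature penalties follow
#' the usual default: `reg * sd_bg(f) / sqrt(n_presences)`. The raw output
#' sums to one over the background; the logistic output applies the standard
#' transform with prevalence parameter 0.5 (`e^H q / (1 + e^H q)` with H the
#' entropy of the fitted density).
#'
#' The penalized-gain improvement of every coordinate update is attributed to
#' the feature's predictor(s) (split equally for product features); the
#' normalized shares are the per-variable percent contributions.
#'
#' @param presence Numeric matrix (points x predictors).
#' @param background Numeric matrix (cells x predictors), same columns.
#' @param reg Regularization multiplier (1 = tool default).
#' @param features Feature classes, see [feature_expansion()].
#' @param max_cycles,tol Optimizer control: full coordinate cycles and the
#'   convergence threshold on the largest coefficient change per cycle.
#' @param lambda_cap Cap on |lambda| guarding against complete separation
#'   (applied with a warning).
#' @return An object of class `maxent_model`.
#' @export
fit_maxent <- function(presence, background, reg = 1,
                       features = c("linear", "quadratic", "product"),
                       max_cycles = 100, tol = 1e-4, lambda_cap = 30) {
  presence <- as.matrix(presence); background <- as.matrix(background)
  if (nrow(presence) < 10) stop("need at least 10 presence points")
  fx <- feature_expansion(background, features)
  Fp <- expand_features(fx, presence)
  Fb <- expand_features(fx, background)
  if (any(!is.finite(Fp))) stop("non-finite predictor values in presence points")
  if (ncol(Fb)) {
    Fb <- Fb[stats::complete.cases(Fb), , drop = FALSE]
  }
  m <- nrow(Fp); N <- nrow(Fb); K <- ncol(Fb)
  beta <- if (K) reg * apply(Fb, 2, stats::sd) / sqrt(m) else numeric(0)
  beta[beta <= 0] <- reg * 1e-6

  lambda <- numeric(K)
  fbar <- colMeans(Fp)            # presence feature means
  eta <- numeric(N)               # background linear predictor
  w <- rep(1, N); S <- N
  mp <- 0                          # mean presence linear predictor
  gain_by_pred <- stats::setNames(numeric(length(fx$predictors)), fx$predictors)
  obj <- function() -mp + log(S / N) + sum(beta * abs(lambda))
  capped <- FALSE
  L_cur <- obj()
  # glmnet-style active set: full sweeps establish the set, inner cycles
  # iterate only over nonzero coefficients
  active <- seq_len(K)
  cyc <- 0L
  for (cyc in seq_len(if (K) max_cycles else 0L)) {
    full_sweep <- (cyc == 1) || (cyc %% 5 == 0)
    sweep_set <- if (full_sweep) seq_len(K) else active
    max_d <- 0
    for (k in sweep_set) {
      q <- w / S
      Eq <- sum(q * Fb[, k])
      Vq <- sum(q * Fb[, k]^2) - Eq^2
      if (Vq < 1e-10) next
      g <- Eq - fbar[k]
      lam_new <- soft_threshold(lambda[k] * Vq - g, beta[k]) / Vq
      if (abs(lam_new) > lambda_cap) {
        lam_new <- sign(lam_new) * lambda_cap
        capped <- TRUE
      }
      d <- lam_new - lambda[k]
      if (d == 0) next
      d <- sign(d) * min(abs(d), 2)   # damp large proximal steps
      lambda[k] <- lambda[k] + d
      eta <- eta + d * Fb[, k]
      em <- max(eta)
      w <- exp(eta - em); S <- sum(w)
      mp <- mp + d * fbar[k]
      L_new <- -mp + log(S / N) + em + sum(beta * abs(lambda))
      dL <- L_cur - L_new
      if (dL > 0) {
        vars <- fx$defs[[k]]$vars
        gain_by_pred[vars] <- gain_by_pred[vars] + dL / length(vars)
      }
      L_cur <- L_new
      max_d <- max(max_d, abs(d))
    }
    active <- which(lambda != 0)
    if (max_d < tol && full_sweep) break
  }
  if (capped) warning("separation detected: coefficients capped at |lambda| = ",
                      lambda_cap)
  em <- max(eta)
  q <- exp(eta - em); q <- q / sum(q)
  H <- -sum(q * log(pmax(q, 1e-300)))
  contrib <- if (sum(gain_by_pred) > 0)
    100 * gain_by_pred / sum(gain_by_pred) else gain_by_pred
  structure(list(
    expansion = fx, lambda = stats::setNames(lambda, fx$feature_names),
    reg = reg, beta = beta,
    log_z = log(sum(exp(eta - em))) + em,   # log sum over background
    entropy = H, n_presence = m, n_background = N,
    contributions = contrib, capped = capped, cycles = cyc
  ), class = "maxent_model")
}

soft_threshold <- function(z, t) sign(z) * max(abs(z) - t, 0)

#' Predict from a maximum-entropy model
#'
#' @param object A `maxent_model`.
#' @param newdata Numeric matrix (points x predictors).
#' @param type `"logistic"` (default), `"raw"` (sums to 1 over the training
#'   background), or `"link"` (the linear predictor).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.maxent_model <- function(object, newdata,
                                 type = c("logistic", "raw", "link"), ...) {
  type <- match.arg(type)
  Fm <- expand_features(object$expansion, as.matrix(newdata))
  eta <- as.vector(Fm %*% object$lambda)
  if (type == "link") return(eta)
  raw <- exp(eta - object$log_z)
  if (type == "raw") return(raw)
  eh <- exp(object$entropy)
  eh * raw / (1 + eh * raw)
}

#' @export
print.maxent_model <- function(x, ...) {
  nz <- sum(x$lambda != 0)
  cat("Maxent-style Gibbs model:", length(x$lambda), "features (", nz,
      "nonzero ),", x$n_presence, "presences over", x$n_background,
      "background cells\n")
  top <- sort(x$contributions, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top))
    cat("  top contributions:", paste(names(top)[seq_len(min(3, length(top)))],
        paste0(round(top[seq_len(min(3, length(top)))], 1), "%"), collapse = ", "), "\n")
  invisible(x)
}

#' Rank-based AUC of presence vs background scores
#'
#' Area under the ROC curve computed from the Mann-Whitney statistic: the
#' probability that a random presence scores above a random background point,
#' ties counted 1/2.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in [0, 1].
#' @export
evaluate_auc <- function(presence_scores, background_scores) {
  m <- length(presence_scores); n <- length(background_scores)
  stopifnot(m >= 1, n >= 1)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Training-omission threshold
#'
#' The `percentile`-training-omission threshold used to binarize suitability
#' maps: the largest prediction value t such that at least
#' `(100 - percentile)%` of the training-presence predictions are >= t.
#' A cell is classified present iff its prediction is >= t.
#'
#' @param training_predictions Predictions at the training presences.
#' @param percentile Omission percentile (default 10).
#' @return The threshold t.
#' @export
omission_threshold <- function(training_predictions, percentile = 10) {
  v <- sort(training_predictions)
  m <- length(v)
  stopifnot(m >= 1, percentile >= 0, percentile < 100)
  k <- m - ceiling((1 - percentile / 100) * m) + 1
  v[max(1, k)]
}
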