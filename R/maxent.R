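# Presence-only maximum-entropy habitat model ("maxent-lite"): linear +
# quadratic features, L1-regularised Gibbs distribution over all county
# cells as background, fitted by monotone proximal gradient descent, then
# thresholded to a binary range mask that clips the kriged density surface.

#' Build a standardized feature space from covariate rasters
#'
#' Each covariate contributes a linear and a squared term; circular
#' covariates (aspect, degrees) contribute a (sin, cos) pair instead. All
#' features are standardized to mean 0, sd 1 over the background (every
#' county cell), and the standardization statistics are stored so the same
#' transform can be reapplied. Constant covariates carry no information and
#' are dropped with a warning.
#'
#' @param covariates named list of [grid_raster()] on a shared grid.
#' @param circular names of covariates to encode as (sin, cos) of degrees
#'   (default `"aspect"`).
#' @return a `feature_space`: `F` (cells x features matrix), `center`,
#'   `scale`, `grid`.
#' @export
build_features <- function(covariates, circular = "aspect") {
  g <- covariates[[1]]$grid
  for (r in covariates) stop_if_grid_mismatch(g, r$grid, "covariates")
  raw <- list()
  for (nm in names(covariates)) {
    v <- covariates[[nm]]$values
    if (stats::sd(v) == 0) {
      warning("constant covariate '", nm, "' dropped from feature space")
      next
    }
    if (nm %in% circular) {
      rad <- v * pi / 180
      raw[[paste0(nm, "_sin")]] <- sin(rad)
      raw[[paste0(nm, "_cos")]] <- cos(rad)
    } else {
      raw[[nm]] <- v
      raw[[paste0(nm, "_sq")]] <- v^2
    }
  }
  if (!length(raw)) stop("no informative covariates")
  Fm <- do.call(cbind, raw)
  ctr <- colMeans(Fm)
  sc <- apply(Fm, 2L, stats::sd)
  keep <- sc > 0
  if (!all(keep)) warning("constant derived features dropped")
  Fm <- sweep(sweep(Fm[, keep, drop = FALSE], 2L, ctr[keep]), 2L, sc[keep], "/")
  structure(list(F = Fm, center = ctr[keep], scale = sc[keep], grid = g),
            class = "feature_space")
}

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

#' Fit the maximum-entropy habitat model
#'
#' Maximises the L1-penalised log-likelihood of the Gibbs distribution
#' `p(cell) = exp(coef . features) / Z` over the background cells, where the
#' likelihood term is the mean linear predictor at the presence cells minus
#' `log Z`. The problem is convex; it is solved by proximal gradient descent
#' with backtracking, so the penalised objective is non-increasing at every
#' iteration (the objective trace is returned). With `beta = 0` the fitted
#' distribution matches the presence feature means exactly (the defining
#' moment condition of maximum entropy).
#'
#' The effective penalty is `beta / sqrt(m)` per unit coefficient, with `m`
#' the number of presence cells: the presence feature means are estimated
#' with O(1/sqrt(m)) sampling error, so the regularisation is held
#' proportional to that noise (standardized features make one global weight
#' meaningful across features).
#'
#' @param presence integer cell indices with observed presences.
#' @param fs a [build_features()] feature space (background = all cells).
#' @param beta global L1 regularisation weight (default 0.5), applied as
#'   `beta / sqrt(length(presence))` per unit coefficient.
#' @param max_iter iteration cap (default 5000).
#' @param tol convergence tolerance: on the maximum presence-moment gap when
#'   `beta = 0`, on the objective decrease otherwise.
#' @return a `maxent_model`: `coefficients`, `p` (raw probabilities, summing
#'   to 1 over background), `suitability` ([grid_raster()], values in (0,1),
#'   monotone in the linear predictor), `eta`, `trace`, `norm_err`,
#'   `converged`, `beta`.
#' @export
fit_maxent <- function(presence, fs, beta = 0.5, max_iter = 5000L,
                       tol = 1e-7) {
  Fm <- fs$F
  N <- nrow(Fm)
  if (length(presence) < 1) stop("need at least one presence cell")
  if (any(presence < 1 | presence > N)) stop("presence index outside the grid")
  pbar <- colMeans(Fm[presence, , drop = FALSE])
  lam <- beta / sqrt(length(presence))  # penalty tracks moment sampling noise
  b <- numeric(ncol(Fm))
  gibbs <- function(b) {
    eta <- as.numeric(Fm %*% b)
    m <- max(eta)
    w <- exp(eta - m)
    list(eta = eta, p = w / sum(w), logZ = m + log(sum(w)))
  }
  smooth_obj <- function(st, b) -(sum(pbar * b) - st$logZ)
  st <- gibbs(b)
  f <- smooth_obj(st, b)
  trace <- f + lam * sum(abs(b))
  norm_err <- abs(sum(st$p) - 1)
  step <- 1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    grad <- -(pbar - as.numeric(crossprod(Fm, st$p)))
    repeat {
      b_new <- soft_threshold(b - step * grad, step * lam)
      st_new <- gibbs(b_new)
      f_new <- smooth_obj(st_new, b_new)
      dlt <- b_new - b
      if (f_new <= f + sum(grad * dlt) + sum(dlt^2) / (2 * step) + 1e-14 ||
          step < 1e-12) break
      step <- step / 2
    }
    b <- b_new; st <- st_new; f <- f_new
    step <- step * 1.5
    trace <- c(trace, f + lam * sum(abs(b)))
    norm_err <- max(norm_err, abs(sum(st$p) - 1))
    gap <- max(abs(pbar - as.numeric(crossprod(Fm, st$p))))
    if (beta == 0) {
      if (gap < tol) { converged <- TRUE; break }
    } else {
      k <- length(trace)
      if (k > 2 && trace[k - 1] - trace[k] < tol &&
          trace[k - 2] - trace[k - 1] < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "maxent did not converge in %d iterations (last objective %.8g)",
      max_iter, utils::tail(trace, 1)))
    err$trace <- trace
    stop(err)
  }
  r <- N * st$p  # relative occurrence rate; 1 under the uniform model
  structure(list(coefficients = stats::setNames(b, colnames(Fm)),
                 p = st$p, eta = st$eta,
                 suitability = grid_raster(fs$grid, r / (1 + r), "suitability"),
                 trace = trace, norm_err = norm_err, converged = converged,
                 beta = beta, presence = presence),
            class = "maxent_model")
}

#' @export
print.maxent_model <- function(x, ...) {
  cat(sprintf("maxent_model: %d features, beta=%g, %d iterations, objective %.6g\n",
              length(x$coefficients), x$beta, length(x$trace) - 1,
              utils::tail(x$trace, 1)))
  invisible(x)
}

#' Threshold a fitted suitability surface into a binary range mask
#'
#' The default rule takes the 10th percentile of suitability at the
#' presence cells (inverse-ECDF quantile, ties inclusive), so at least 90%
#' of presences fall inside the range by construction. A numeric `rule`
#' is used directly as the threshold.
#'
#' @param model a [fit_maxent()] model.
#' @param rule `"p10"` (default) or a numeric suitability threshold.
#' @return a `range_mask`: `mask` (0/1 [grid_raster()]), `rule`,
#'   `threshold`, `suitable_area_km2`.
#' @export
threshold_range <- function(model, rule = "p10") {
  s <- model$suitability$values
  thr <- if (is.numeric(rule)) rule
  else switch(rule,
              p10 = as.numeric(stats::quantile(s[model$presence], 0.10, type = 1)),
              stop("unknown threshold rule: ", rule))
  mask <- as.numeric(s >= thr)
  if (!any(mask == 1)) warning("empty range mask at threshold ", signif(thr, 4))
  g <- model$suitability$grid
  structure(list(mask = grid_raster(g, mask, "range_mask"),
                 rule = if (is.numeric(rule)) "fixed" else rule,
                 threshold = thr,
                 suitable_area_km2 = sum(mask) * g$cellsize^2),
            class = "range_mask")
}

#' @export
print.range_mask <- function(x, ...) {
  cat(sprintf("range_mask: rule %s, threshold %.4g, suitable area %.6g km2\n",
              x$rule, x$threshold, x$suitable_area_km2))
  invisible(x)
}

#' Clip a density surface by a binary range mask
#'
#' Density is set to zero outside the mask and left unchanged inside — no
#' renormalisation, so population totals are meaningful only after masking.
#' The total density removed is recorded in the `masked_out` attribute.
#'
#' @param density a [grid_raster()] of animals/km2.
#' @param mask a [threshold_range()] result (or a 0/1 [grid_raster()]).
#' @return the clipped [grid_raster()] with attribute `masked_out`
#'   (animals removed = clipped density integral).
#' @export
mask_density <- function(density, mask) {
  m <- if (inherits(mask, "range_mask")) mask$mask else mask
  stop_if_grid_mismatch(density$grid, m$grid, "density and mask")
  out <- density$values * (m$values > 0)
  res <- grid_raster(density$grid, out, density$name)
  attr(res, "masked_out") <- (sum(density$values) - sum(out)) *
    density$grid$cellsize^2
  res
}
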