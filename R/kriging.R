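# Ordinary kriging of point densities onto the county grid: empirical
# semivariogram (Matheron), bounded WLS model fit, moving-neighborhood OK
# solve in covariance form, and leave-one-out cross-validation.

#' Semivariogram model
#'
#' Isotropic models with nugget/partial-sill/range parameterisation. The
#' `exponential` and `gaussian` forms use the practical-range convention
#' (the model reaches ~95% of its sill at `range_km`); the `spherical` model
#' attains the sill exactly at `range_km`.
#'
#' @param model one of `"spherical"`, `"exponential"`, `"gaussian"`.
#' @param nugget non-negative nugget variance.
#' @param psill non-negative partial sill; total sill = `nugget + psill`.
#' @param range_km positive range parameter (km).
#' @return a `semivariogram` object.
#' @export
semivariogram <- function(model = c("spherical", "exponential", "gaussian"),
                          nugget = 0, psill = 1, range_km = 10) {
  model <- match.arg(model)
  if (nugget < 0 || psill < 0) stop("nugget and partial sill must be >= 0")
  if (range_km <= 0) stop("range must be > 0")
  structure(list(model = model, nugget = nugget, psill = psill,
                 range_km = range_km, sill = nugget + psill),
            class = "semivariogram")
}

#' @export
print.semivariogram <- function(x, ...) {
  cat(sprintf("semivariogram: %s(nugget=%.4g, psill=%.4g, range=%.4g km)\n",
              x$model, x$nugget, x$psill, x$range_km))
  invisible(x)
}

#' Evaluate a semivariogram at distances
#'
#' @param vg a [semivariogram()].
#' @param h non-negative distances (km).
#' @return semivariance values; `gamma(0) = 0`, and the nugget enters for
#'   any `h > 0` (the standard discontinuity-at-origin convention).
#' @export
semivariance <- function(vg, h) {
  u <- h / vg$range_km
  g <- switch(vg$model,
    spherical = ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3),
    exponential = 1 - exp(-3 * u),
    gaussian = 1 - exp(-3 * u^2))
  ifelse(h > 0, vg$nugget + vg$psill * g, 0)
}

#' Empirical semivariogram (Matheron estimator)
#'
#' Pairs of observations are binned by separation distance and each bin
#' receives `gamma_hat(h) = sum((z_i - z_j)^2) / (2 N(h))`. Bins with no
#' pairs are omitted.
#'
#' @param x,y point coordinates (km).
#' @param values observed values at the points.
#' @param lag_width bin width (km).
#' @param max_lag largest separation considered (km); default half the
#'   maximum pairwise distance.
#' @return data.frame with `lag` (bin centre), `gamma`, `npairs`.
#' @export
empirical_semivariogram <- function(x, y, values, lag_width = NULL,
                                    max_lag = NULL) {
  n <- length(values)
  if (n < 2) stop("need at least 2 points")
  d <- as.matrix(stats::dist(cbind(x, y)))
  dmax <- max(d)
  if (dmax == 0) stop("all points are coincident")
  if (is.null(max_lag)) max_lag <- dmax / 2
  if (is.null(lag_width)) lag_width <- max_lag / 15
  if (lag_width <= 0) stop("lag_width must be > 0")
  ut <- upper.tri(d)
  dij <- d[ut]
  sq <- (outer(values, values, "-")^2)[ut]
  keep <- dij > 0 & dij <= max_lag
  dij <- dij[keep]; sq <- sq[keep]
  bin <- floor(dij / lag_width)
  gamma <- tapply(sq, bin, function(v) sum(v) / (2 * length(v)))
  npairs <- tapply(sq, bin, length)
  centers <- (as.numeric(names(gamma)) + 0.5) * lag_width
  data.frame(lag = centers, gamma = as.numeric(gamma),
             npairs = as.numeric(npairs))
}

#' Fit a semivariogram model by weighted least squares
#'
#' Minimises `sum_k w_k (gamma_hat_k - gamma(h_k))^2` with the conventional
#' weights `w_k = N(h_k) / h_k^2`, over bounded (nugget, partial sill,
#' range) using multi-start L-BFGS-B.
#'
#' @param empirical output of [empirical_semivariogram()].
#' @param model model family, see [semivariogram()].
#' @return a [semivariogram()] with a `diagnostics` attribute: `wls`
#'   (attained objective), `converged`, and `range_identifiable` (FALSE for
#'   effectively pure-nugget data: either the fitted partial sill is a
#'   negligible share of the sill, or the structured model barely improves
#'   on the best flat fit, so the range carries no information).
#' @export
fit_semivariogram <- function(empirical,
                              model = c("spherical", "exponential", "gaussian")) {
  model <- match.arg(model)
  emp <- empirical[is.finite(empirical$gamma), , drop = FALSE]
  if (nrow(emp) < 3) stop("need at least 3 non-empty lag bins")
  w <- emp$npairs / emp$lag^2
  obj <- function(p) {
    vg <- semivariogram(model, nugget = p[1], psill = p[2], range_km = p[3])
    sum(w * (emp$gamma - semivariance(vg, emp$lag))^2)
  }
  gmax <- max(emp$gamma); hmax <- max(emp$lag)
  if (gmax <= 0) {  # constant field
    out <- semivariogram(model, 0, 0, hmax)
    attr(out, "diagnostics") <- list(wls = 0, converged = TRUE,
                                     range_identifiable = FALSE)
    return(out)
  }
  starts <- list(
    c(0, gmax, hmax / 2),
    c(min(emp$gamma), max(gmax - min(emp$gamma), gmax / 10), hmax / 3),
    c(gmax / 2, gmax / 2, hmax),
    c(0, gmax, hmax / 10))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, obj, method = "L-BFGS-B",
                   lower = c(0, 0, hmax * 1e-3),
                   upper = c(2 * gmax, 4 * gmax, 4 * hmax),
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    stop("semivariogram fit failed; residual scale ", signif(gmax, 4))
  p <- best$par
  out <- semivariogram(model, nugget = p[1], psill = p[2], range_km = p[3])
  # best range-free (flat) fit: weighted mean of the empirical semivariances
  flat <- sum(w * (emp$gamma - sum(w * emp$gamma) / sum(w))^2)
  attr(out, "diagnostics") <- list(
    wls = best$value, converged = best$convergence == 0,
    range_identifiable = p[2] > 0.1 * (p[1] + p[2]) &&
      best$value < 0.9 * flat)
  out
}

# Solve the ordinary-kriging system in covariance form for one target:
# [C 1; 1' 0] [lambda; mu] = [c0; 1], with C_ij = sill - gamma(d_ij).
ok_solve <- function(coords, values, vg, target) {
  n <- nrow(coords)
  sill <- if (vg$sill > 0) vg$sill else 1
  d <- as.matrix(stats::dist(rbind(coords, target)))
  Cm <- sill - semivariance(vg, d[seq_len(n), seq_len(n), drop = FALSE])
  c0 <- sill - semivariance(vg, d[seq_len(n), n + 1L])
  A <- rbind(cbind(Cm, 1), c(rep(1, n), 0))
  b <- c(c0, 1)
  sol <- tryCatch(solve(A, b), error = function(e) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8 * sill
    solve(A, b)
  })
  lambda <- unname(sol[seq_len(n)]); mu <- unname(sol[n + 1L])
  list(lambda = lambda, mu = mu,
       prediction = sum(lambda * values),
       variance = sill - sum(lambda * c0) - mu)
}

#' Ordinary-kriging weights for a single target location
#'
#' Exposes the per-target solve used by [krige()]: the ordinary-kriging
#' system in covariance form (`C = sill - gamma`) with a Lagrange
#' multiplier enforcing that the weights sum to one.
#'
#' @param x,y,values data points.
#' @param vg a [semivariogram()].
#' @param x0,y0 target location.
#' @param neighborhood number of nearest data points used (default all).
#' @return list with `lambda` (weights, summing to 1), `mu` (Lagrange
#'   multiplier), `prediction`, `variance`, and `index` (which data points
#'   entered the neighborhood).
#' @export
krige_weights <- function(x, y, values, vg, x0, y0, neighborhood = Inf) {
  n <- length(values)
  idx <- seq_len(n)
  if (is.finite(neighborhood) && neighborhood < n) {
    d0 <- sqrt((x - x0)^2 + (y - y0)^2)
    idx <- order(d0)[seq_len(neighborhood)]
  }
  sol <- ok_solve(cbind(x[idx], y[idx]), values[idx], vg, c(x0, y0))
  c(sol, list(index = idx))
}

#' Ordinary kriging onto a grid
#'
#' Predicts at every cell centre from the `neighborhood` nearest data
#' points (all points for small data sets), solving the ordinary-kriging
#' system per cell. Predictions are clamped at zero by default — abundance
#' densities cannot be negative — and the number of clamped cells is
#' recorded rather than hidden.
#'
#' @param x,y,values data points (km, value units).
#' @param vg a [semivariogram()], e.g. from [fit_semivariogram()].
#' @param grid target [county_grid()].
#' @param neighborhood nearest-point count per cell (default 16; use `Inf`
#'   for global kriging, sensible for n <= 200).
#' @param clamp_negative clamp negative predictions to 0 (default TRUE).
#' @return list of class `kriging_result`: `prediction` and `variance`
#'   ([grid_raster()]), `variogram`, `n_clamped`, `neighborhood`.
#' @export
krige <- function(x, y, values, vg, grid, neighborhood = 16L,
                  clamp_negative = TRUE) {
  n <- length(values)
  if (n < 1) stop("need at least one data point")
  ctr <- grid_centers(grid)
  pred <- numeric(nrow(ctr)); pvar <- numeric(nrow(ctr))
  if (n == 1) {
    pred[] <- values; pvar[] <- vg$sill
  } else {
    k <- min(neighborhood, n)
    # distances cells x points, in blocks to bound memory
    for (start in seq(1L, nrow(ctr), by = 2048L)) {
      rows <- start:min(start + 2047L, nrow(ctr))
      dx <- outer(ctr$x[rows], x, "-"); dy <- outer(ctr$y[rows], y, "-")
      dmat <- sqrt(dx^2 + dy^2)
      for (j in seq_along(rows)) {
        idx <- if (k < n) order(dmat[j, ])[seq_len(k)] else seq_len(n)
        sol <- ok_solve(cbind(x[idx], y[idx]), values[idx], vg,
                        c(ctr$x[rows[j]], ctr$y[rows[j]]))
        pred[rows[j]] <- sol$prediction
        pvar[rows[j]] <- sol$variance
      }
    }
  }
  n_clamped <- 0L
  if (clamp_negative) {
    n_clamped <- sum(pred < 0)
    pred[pred < 0] <- 0
  }
  pvar[pvar < 0 & pvar > -1e-9] <- 0  # tolerate tiny negative round-off
  structure(list(prediction = grid_raster(grid, pred, "ok_prediction"),
                 variance = grid_raster(grid, pvar, "ok_variance"),
                 variogram = vg, n_clamped = n_clamped,
                 neighborhood = neighborhood),
            class = "kriging_result")
}

#' @export
print.kriging_result <- function(x, ...) {
  cat("ordinary kriging result\n")
  print(x$variogram)
  print(x$prediction)
  cat(sprintf("  %d negative predictions clamped; neighborhood %s\n",
              x$n_clamped, format(x$neighborhood)))
  invisible(x)
}

#' Leave-one-out cross-validation of the kriging predictor
#'
#' @param x,y,values data points.
#' @param vg a [semivariogram()].
#' @param neighborhood nearest-point count (default all remaining points).
#' @return list with `rmse`, `me` (mean error), and the per-point
#'   `predicted` and `residual` vectors.
#' @export
cross_validate <- function(x, y, values, vg, neighborhood = Inf) {
  n <- length(values)
  if (n < 3) stop("need at least 3 points")
  predicted <- numeric(n)
  for (i in seq_len(n)) {
    predicted[i] <- krige_weights(x[-i], y[-i], values[-i], vg,
                                  x[i], y[i], neighborhood)$prediction
  }
  resid <- predicted - values
  list(rmse = sqrt(mean(resid^2)), me = mean(resid),
       predicted = predicted, residual = resid)
}
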