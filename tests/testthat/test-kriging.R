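test_that("semivariogram models are zero at origin, monotone, sill-bounded", {
  h <- seq(0, 50, by = 0.25)
  for (m in c("spherical", "exponential", "gaussian")) {
    vg <- semivariogram(m, nugget = 0.2, psill = 1.3, range_km = 12)
    g <- semivariance(vg, h)
    expect_equal(g[1], 0)
    expect_true(all(diff(g[-1]) >= -1e-12))
    expect_true(all(g <= vg$sill + 1e-9))
    # spherical attains the sill at the range
    if (m == "spherical") expect_equal(semivariance(vg, 12), 1.5)
  }
  expect_error(semivariogram("spherical", nugget = -1), ">= 0")
})

test_that("Matheron estimator matches hand computation and a pair-loop oracle", {
  # constant field: zero semivariance in every bin
  set.seed(1)
  x <- runif(10, 0, 50); y <- runif(10, 0, 50)
  emp <- empirical_semivariogram(x, y, rep(3, 10), lag_width = 5, max_lag = 50)
  expect_true(all(emp$gamma == 0))

  # two points, values 0 and 2 at distance 3: single bin, gamma = 2
  emp2 <- empirical_semivariogram(c(0, 3), c(0, 0), c(0, 2),
                                  lag_width = 5, max_lag = 10)
  expect_equal(nrow(emp2), 1L)
  expect_equal(emp2$gamma, 2)
  expect_equal(emp2$npairs, 1)

  # O(n^2) brute-force oracle on 20 random points, exact equality
  set.seed(2)
  n <- 20
  x <- runif(n, 0, 100); y <- runif(n, 0, 100); z <- rnorm(n)
  lw <- 10; ml <- 60
  acc <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d > 0 && d <= ml) {
      b <- floor(d / lw)
      acc[[length(acc) + 1]] <- c(b, (z[i] - z[j])^2)
    }
  }
  acc <- do.call(rbind, acc)
  oracle <- sapply(split(acc[, 2], acc[, 1]), function(v) sum(v) / (2 * length(v)))
  emp3 <- empirical_semivariogram(x, y, z, lag_width = lw, max_lag = ml)
  expect_equal(emp3$gamma, unname(oracle))

  expect_error(empirical_semivariogram(c(1, 1), c(2, 2), c(0, 1)),
               "coincident")
})

test_that("WLS fit recovers exact spherical parameters", {
  truth <- semivariogram("spherical", nugget = 0, psill = 1, range_km = 10)
  lags <- seq(0.5, 15, by = 0.5)
  emp <- data.frame(lag = lags, gamma = semivariance(truth, lags),
                    npairs = 100)
  fit <- fit_semivariogram(emp, "spherical")
  expect_equal(fit$nugget, 0, tolerance = 1e-3)
  expect_equal(fit$psill, 1, tolerance = 1e-3)
  expect_equal(fit$range_km, 10, tolerance = 1e-2)
  # fitted model is nondecreasing over the fitted lags
  g <- semivariance(fit, seq(0, 15, by = 0.1))
  expect_true(all(diff(g[-1]) >= -1e-12))
})

test_that("pure-nugget data are flagged and the sill tracks the variance", {
  set.seed(8)
  n <- 200
  x <- runif(n, 0, 100); y <- runif(n, 0, 100); z <- rnorm(n)
  emp <- empirical_semivariogram(x, y, z, lag_width = 5, max_lag = 60)
  fit <- fit_semivariogram(emp, "spherical")
  diag <- attr(fit, "diagnostics")
  expect_false(diag$range_identifiable)
  expect_equal(fit$sill, var(z), tolerance = 0.3)
})

test_that("kriging weights solve the augmented system (dense oracle)", {
  vg <- semivariogram("spherical", nugget = 0.3, psill = 1, range_km = 12)
  x <- c(0, 10, 0); y <- c(0, 0, 10); z <- c(1, 2, 3)
  x0 <- 3; y0 <- 4
  # independent dense solve, variogram form: [G 1; 1' 0] [l; m] = [g0; 1]
  d <- as.matrix(dist(cbind(c(x, x0), c(y, y0))))
  G <- matrix(0, 4, 4)
  G[1:3, 1:3] <- semivariance(vg, d[1:3, 1:3])
  G[4, 1:3] <- 1; G[1:3, 4] <- 1
  sol_v <- solve(G, c(semivariance(vg, d[1:3, 4]), 1))
  kw <- krige_weights(x, y, z, vg, x0, y0)
  expect_equal(kw$lambda, sol_v[1:3], tolerance = 1e-10)
  expect_equal(sum(kw$lambda), 1, tolerance = 1e-12)
  expect_equal(kw$prediction, sum(sol_v[1:3] * z), tolerance = 1e-10)
  # covariance-form variance equals the variogram-form variance
  var_v <- sum(sol_v[1:3] * semivariance(vg, d[1:3, 4])) + sol_v[4]
  expect_equal(kw$variance, var_v, tolerance = 1e-9)
})

test_that("moving-neighborhood grid predictions equal the dense solve", {
  set.seed(12)
  n <- 15
  x <- runif(n, 0, 40); y <- runif(n, 0, 40); z <- rpois(n, 4) / 2
  vg <- semivariogram("spherical", nugget = 0.1, psill = 0.8, range_km = 15)
  g <- tiny_grid(8)
  kr <- krige(x, y, z, vg, g, neighborhood = 16, clamp_negative = FALSE)
  ctr <- grid_centers(g)
  for (cell in c(1, 17, 40, 64)) {
    dd <- as.matrix(dist(rbind(cbind(x, y), c(ctr$x[cell], ctr$y[cell]))))
    A <- rbind(cbind(vg$sill - semivariance(vg, dd[1:n, 1:n]), 1),
               c(rep(1, n), 0))
    sol <- solve(A, c(vg$sill - semivariance(vg, dd[1:n, n + 1]), 1))
    expect_equal(kr$prediction$values[cell], sum(sol[1:n] * z),
                 tolerance = 1e-10)
  }
})

test_that("ordinary kriging is an exact interpolator with zero nugget", {
  vg <- semivariogram("spherical", nugget = 0, psill = 1, range_km = 20)
  g <- tiny_grid(4)
  ctr <- grid_centers(g)
  pts <- c(1, 6, 11, 16)
  z <- c(2, 0.5, 1.2, 3)
  kr <- krige(ctr$x[pts], ctr$y[pts], z, vg, g)
  expect_equal(kr$prediction$values[pts], z, tolerance = 1e-8)
  expect_true(all(kr$variance$values >= -1e-9))
  kw <- krige_weights(ctr$x[pts], ctr$y[pts], z, vg, ctr$x[1], ctr$y[1])
  expect_equal(max(abs(kw$lambda - c(1, 0, 0, 0))), 0, tolerance = 1e-8)
})

test_that("single data point predicts itself everywhere with unit weight", {
  vg <- semivariogram("spherical", 0, 1, 10)
  kr <- krige(5, 5, 4.2, vg, tiny_grid(3))
  expect_true(all(kr$prediction$values == 4.2))
  kw <- krige_weights(5, 5, 4.2, vg, 20, 20)
  expect_equal(kw$lambda, 1)
})

test_that("weights sum to one and variance is non-negative on random cases", {
  set.seed(14)
  vg <- semivariogram("exponential", nugget = 0.2, psill = 1, range_km = 25)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    x <- runif(n, 0, 80); y <- runif(n, 0, 80); z <- runif(n, 0, 5)
    kw <- krige_weights(x, y, z, vg, runif(1, 0, 80), runif(1, 0, 80),
                        neighborhood = 16)
    expect_equal(sum(kw$lambda), 1, tolerance = 1e-9)
    expect_gte(kw$variance, -1e-9)
  }
})

test_that("negative predictions are clamped and counted", {
  # a steep local trend drives extrapolated cells negative
  vg <- semivariogram("gaussian", nugget = 0, psill = 4, range_km = 30)
  x <- c(5, 10, 15); y <- c(20, 20, 20); z <- c(4, 2, 0.1)
  kr <- krige(x, y, z, vg, tiny_grid(8), neighborhood = 3)
  expect_true(all(kr$prediction$values >= 0))
  expect_gt(kr$n_clamped, 0)
})

test_that("leave-one-out cross-validation behaves like the noise model", {
  # constant field: perfect prediction
  set.seed(15)
  x <- runif(20, 0, 50); y <- runif(20, 0, 50)
  vg <- semivariogram("spherical", 0.5, 0.5, 10)
  expect_equal(cross_validate(x, y, rep(2, 20), vg)$rmse, 0, tolerance = 1e-9)

  # white noise: RMSE near the noise sd, mean error near zero
  n <- 200
  x <- runif(n, 0, 100); y <- runif(n, 0, 100); z <- rnorm(n)
  vgn <- semivariogram("spherical", nugget = 1, psill = 0, range_km = 10)
  cv <- cross_validate(x, y, z, vgn, neighborhood = 32)
  expect_equal(cv$rmse, 1, tolerance = 0.15)
  expect_lt(abs(cv$me), 3 * sd(cv$residual) / sqrt(n))
})

test_that("denser sampling of a smooth surface reduces kriging error", {
  f <- function(x, y) 3 + sin(x / 18) + cos(y / 23) + x / 80
  g <- county_grid(0, 0, 120, 120, 10)
  ctr <- grid_centers(g)
  truth <- f(ctr$x, ctr$y)
  rmse_at <- function(n, seed) {
    set.seed(seed)
    x <- runif(n, 0, 120); y <- runif(n, 0, 120); z <- f(x, y)
    emp <- empirical_semivariogram(x, y, z, lag_width = 8, max_lag = 70)
    vg <- fit_semivariogram(emp, "spherical")
    kr <- krige(x, y, z, vg, g, clamp_negative = FALSE)
    sqrt(mean((kr$prediction$values - truth)^2))
  }
  expect_lt(rmse_at(150, 16), rmse_at(40, 16))
})
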