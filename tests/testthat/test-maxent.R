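binary_fs <- function() {
  # four background cells, one binary feature marking two of them
  structure(list(F = matrix(c(1, 1, 0, 0), ncol = 1,
                            dimnames = list(NULL, "f1")),
                 center = 0, scale = 1,
                 grid = county_grid(0, 0, 10, 10, 5)),
            class = "feature_space")
}

test_that("feature space has the documented shape and standardization", {
  county <- tiny_county(seed = 17)
  fs <- build_features(county$covariates)
  # 4 plain covariates x (linear, square) + aspect (sin, cos)
  expect_equal(ncol(fs$F), 10L)
  expect_equal(unname(colMeans(fs$F)), rep(0, 10), tolerance = 1e-12)
  expect_equal(unname(apply(fs$F, 2, sd)), rep(1, 10), tolerance = 1e-12)
  # restandardizing the standardized features is the identity
  again <- sweep(sweep(fs$F, 2, colMeans(fs$F)), 2, apply(fs$F, 2, sd), "/")
  expect_equal(again, fs$F, tolerance = 1e-12)

  one <- build_features(county$covariates["elevation"])
  expect_equal(ncol(one$F), 2L)
  asp <- build_features(county$covariates["aspect"])
  expect_equal(colnames(asp$F), c("aspect_sin", "aspect_cos"))

  flat <- list(elevation = grid_raster(county$grid, 1),
               slope = county$covariates$slope)
  expect_warning(fs2 <- build_features(flat), "constant covariate")
  expect_equal(ncol(fs2$F), 2L)
})

test_that("maxent at beta = 0 matches presence moments and the grid oracle", {
  fs <- binary_fs()
  m <- fit_maxent(c(1, 2), fs, beta = 0, tol = 1e-7)
  fitted_expectation <- sum(m$p * fs$F[, 1])
  expect_equal(fitted_expectation, 1.0, tolerance = 1e-6)
  expect_equal(sum(m$p), 1, tolerance = 1e-9)
  expect_lt(m$norm_err, 1e-9)

  # brute-force line search over the single coefficient
  ll <- function(b) b * 1 - log(sum(exp(fs$F[, 1] * b)))
  grid_best <- max(vapply(seq(0, 40, by = 0.005), ll, numeric(1)))
  expect_gte(ll(m$coefficients), grid_best - 1e-6)
})

test_that("the penalised objective is monotone and the L1 limit is uniform", {
  county <- tiny_county(seed = 18)
  fs <- build_features(county$covariates)
  set.seed(18)
  presence <- sample(nrow(fs$F), 40)
  m <- fit_maxent(presence, fs, beta = 0.5)
  expect_true(all(diff(m$trace) <= 1e-10))
  expect_lt(m$norm_err, 1e-9)
  # suitability is monotone in the linear predictor
  o <- order(m$eta)
  expect_true(all(diff(m$suitability$values[o]) >= -1e-12))

  big <- fit_maxent(presence, fs, beta = 1e4)
  expect_equal(unname(big$coefficients), rep(0, ncol(fs$F)))
  expect_equal(big$p, rep(1 / nrow(fs$F), nrow(fs$F)))
  expect_equal(unique(round(big$suitability$values, 12)), 0.5)
})

test_that("non-convergence raises an error carrying the objective trace", {
  fs <- binary_fs()
  err <- tryCatch(fit_maxent(c(1, 2), fs, beta = 0, max_iter = 3L),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "converge")
  expect_true(is.numeric(err$trace) && length(err$trace) > 1)
})

test_that("range thresholding keeps >= 90% of presences and is monotone", {
  county <- tiny_county(seed = 19)
  fs <- build_features(county$covariates)
  set.seed(19)
  presence <- sample(nrow(fs$F), 60)
  m <- fit_maxent(presence, fs, beta = 0.5)

  rm10 <- threshold_range(m)
  inside <- rm10$mask$values[presence]
  expect_gte(mean(inside), 0.9)
  expect_equal(rm10$suitable_area_km2, sum(rm10$mask$values) * 25)

  # threshold 0: everything suitable, area = county area
  all_in <- threshold_range(m, rule = 0)
  expect_equal(all_in$suitable_area_km2, 80 * 80)

  # raising the threshold never increases the suitable area
  thr <- sort(runif(6, 0, 1))
  areas <- vapply(thr, function(t)
    suppressWarnings(threshold_range(m, rule = t))$suitable_area_km2,
    numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("masking clips density without renormalisation", {
  g <- tiny_grid(5)
  set.seed(20)
  dens <- grid_raster(g, rexp(25))
  ones <- grid_raster(g, 1)
  zeros <- grid_raster(g, 0)
  expect_equal(mask_density(dens, ones)$values, dens$values)
  expect_true(all(mask_density(dens, zeros)$values == 0))
  for (i in 1:10) {
    m <- grid_raster(g, rbinom(25, 1, 0.6))
    clipped <- mask_density(dens, m)
    expect_lte(raster_integral(clipped), raster_integral(dens))
    expect_equal(raster_integral(dens) - raster_integral(clipped),
                 attr(clipped, "masked_out"))
    # equality iff no positive density outside the mask
    if (all(dens$values[m$values == 0] == 0))
      expect_equal(raster_integral(clipped), raster_integral(dens))
  }
  wrong <- grid_raster(tiny_grid(4), 1)
  expect_error(mask_density(dens, wrong), "grid")
})

test_that("fitted suitability ranks a known logistic truth correctly", {
  county <- make_county(county_spec(seed = 23))
  zc <- lapply(county$covariates, function(r) {
    v <- r$values; (v - mean(v)) / sd(v)
  })
  eta <- 0.4 - 0.9 * zc$elevation - 0.8 * zc$slope + 0.6 * zc$precipitation
  prob <- plogis(eta)
  set.seed(23)
  presence <- unique(sample(length(prob), 300, replace = TRUE, prob = prob))
  fs <- build_features(county$covariates)
  m <- fit_maxent(presence, fs, beta = 0.5)
  expect_gt(cor(m$suitability$values, prob, method = "spearman"), 0.8)
})
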