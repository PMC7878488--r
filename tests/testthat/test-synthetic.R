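test_that("parcel tiling is an exact partition of the extent", {
  # single parcel: identity partition
  c1 <- make_county(county_spec(c(0, 0, 40, 40), 5, 1, 7))
  expect_equal(parcel_areas(c1$parcels), 1600)

  # default-sized county: areas conserve the extent exactly
  c27 <- make_county(county_spec(c(0, 0, 160, 160), 5, 27, 7))
  expect_equal(length(c27$parcels), 27L)
  expect_equal(sum(parcel_areas(c27$parcels)), 25600, tolerance = 1e-6)

  # interiors disjoint + union = extent: every cell centre in exactly one
  pid <- parcel_of_cell(c27$parcels, c27$grid)
  expect_false(any(is.na(pid)))
  expect_setequal(unique(pid), c27$parcels$id)
})

test_that("generators are deterministic in (config, seed)", {
  a <- make_county(county_spec(seed = 42))
  b <- make_county(county_spec(seed = 42))
  expect_identical(a$parcels$rings, b$parcels$rings)
  expect_identical(a$covariates$elevation$values, b$covariates$elevation$values)
  c2 <- make_county(county_spec(seed = 43))
  expect_false(identical(a$parcels$rings, c2$parcels$rings))
})

test_that("degenerate county specs are rejected", {
  expect_error(county_spec(c(0, 0, 0, 160)), "degenerate")
  expect_error(county_spec(n_parcels = 0), "n_parcels")
})

test_that("latent truth obeys the suitability and total-population contracts", {
  county <- tiny_county(seed = 9)
  params <- default_species_params()
  truth <- make_truth(county, params, seed = 9)
  for (id in names(truth)) {
    t <- truth[[id]]
    expect_true(all(t$density$values >= 0))
    expect_true(all(is.finite(t$density$values)))
    # density zero wherever suitability truth is zero
    expect_true(all(t$density$values[t$suitability$values == 0] == 0))
    # integral matches configured total
    expect_equal(raster_integral(t$density), params[[id]]$total,
                 tolerance = 0.01)
  }

  # unsuitable everywhere -> zero density
  p0 <- params
  p0$kiang$beta0 <- -1e6
  t0 <- make_truth(county, p0["kiang"], seed = 9)
  expect_true(all(t0$kiang$density$values == 0))

  # constant covariates -> constant suitability (no spatial signal)
  flat <- county
  flat$covariates <- lapply(county$covariates, function(r)
    grid_raster(r$grid, 1, r$name))
  tf <- make_truth(flat, params["kiang"], seed = 9)
  expect_length(unique(tf$kiang$suitability$values), 1L)
})

test_that("survey counts follow the Poisson strip observation model", {
  county <- tiny_county(seed = 21)
  truth <- make_truth(county, default_species_params(), seed = 21)
  design <- survey_design(n_transects = 100L)

  # zero detection -> zero counts
  d0 <- survey_design(n_transects = 50L, detection_prob = 0)
  s0 <- simulate_surveys(truth, d0, seed = 5)
  expect_true(all(s0$count == 0))

  # doubling density doubles expected total count (Poisson mean linearity)
  s1 <- simulate_surveys(truth, design, seed = 5)
  truth2 <- truth
  for (id in names(truth2))
    truth2[[id]]$density$values <- 2 * truth2[[id]]$density$values
  s2 <- simulate_surveys(truth2, design, seed = 5)
  expect_equal(sum(s2$count) / sum(s1$count), 2, tolerance = 0.05)

  # schema and revisit design
  expect_named(s1, c("transect_id", "species", "season", "count",
                     "length_km", "x", "y", "wkt_geometry"))
  expect_equal(sort(unique(s1$season)), c("summer", "winter"))
  one <- s1[s1$transect_id == 1, ]
  expect_length(unique(one$wkt_geometry), 1L)
})

test_that("livestock allocation conserves the county sheep-unit total", {
  county <- tiny_county(seed = 13, n_parcels = 9)
  stock <- simulate_livestock(county$parcels, seed = 2)
  rates <- livestock_rates()
  su <- sum(stock$cattle * rates["cattle"] + stock$sheep * rates["sheep"] +
              stock$horses * rates["horses"])
  expect_lt(abs(su - 338159), 9)  # within n_parcels of the configured total
  # sheep-unit mix close to 73/24/3
  expect_equal(sum(stock$cattle * rates["cattle"]) / su, 0.73,
               tolerance = 0.01)

  expect_equal(simulate_livestock(county$parcels, total_sheep_units = 0,
                                  seed = 2)[, c("cattle", "sheep", "horses")],
               data.frame(cattle = rep(0L, 9), sheep = rep(0L, 9),
                          horses = rep(0L, 9)))

  only_cattle <- simulate_livestock(county$parcels,
                                    mix = c(cattle = 1, sheep = 0, horses = 0),
                                    seed = 2)
  expect_true(all(only_cattle$sheep == 0) && all(only_cattle$horses == 0))
  expect_gt(sum(only_cattle$cattle), 0)

  expect_error(simulate_livestock(county$parcels, total_sheep_units = -1),
               ">= 0")
})

test_that("NDVI stack is bounded and the composite recovers the latent field", {
  g <- tiny_grid(10)
  nd <- simulate_ndvi(g, seed = 6)
  for (l in nd$layers) expect_true(all(l$values >= -1 & l$values <= 1))
  comp <- max_value_composite(nd$layers)
  expect_true(all(comp$values <= nd$latent$values + 1e-12))
  expect_gt(mean(comp$values == nd$latent$values), 0.9)
})
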