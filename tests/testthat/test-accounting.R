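test_that("zonal statistics conserve the county integral over the partition", {
  county <- tiny_county(seed = 25, n_parcels = 7)
  set.seed(25)
  r <- grid_raster(county$grid, rexp(county$grid$nrow * county$grid$ncol))
  z <- zonal_stats(r, county$parcels)
  expect_equal(sum(z$integral), raster_integral(r), tolerance = 1e-9)
  expect_equal(sum(z$n_cells), county$grid$nrow * county$grid$ncol)

  cst <- zonal_stats(grid_raster(county$grid, 3.5), county$parcels)
  expect_equal(cst$mean, rep(3.5, 7))
  expect_equal(cst$integral, cst$n_cells * 25 * 3.5)

  single <- make_county(county_spec(c(0, 0, 40, 40), 5, 1, 2))
  z1 <- zonal_stats(r <- grid_raster(single$grid, runif(64)), single$parcels)
  expect_equal(z1$integral, raster_integral(r))
})

test_that("wildlife offset is sum of density x area x conversion", {
  d <- data.frame(parcel_id = c(1, 1, 2), species = c("kiang", "gazelle", "kiang"),
                  density = c(0.5, 1.0, 0))
  areas <- c("1" = 100, "2" = 50)
  off <- wildlife_offset(d, areas)
  expect_equal(off$C_w, c(0.5 * 100 * 6 + 1.0 * 100 * 0.3, 0))
  expect_equal(attr(off, "county"), sum(off$C_w))

  # linearity: doubling densities doubles the offset
  d2 <- d; d2$density <- 2 * d2$density
  expect_equal(wildlife_offset(d2, areas)$C_w, 2 * off$C_w)

  expect_error(wildlife_offset(data.frame(parcel_id = 1, species = "yak",
                                          density = 1), areas), "yak")
})

test_that("ecological capacity subtracts the offset and flags deficits", {
  ec <- ecological_capacity(c(100, 50), c(0, 80))
  expect_equal(ec$C_t, c(100, -30))
  expect_equal(ec$wildlife_exceeds_forage, c(FALSE, TRUE))
  expect_error(ecological_capacity(1:3, 1:2), "mismatch")
})

test_that("actual load converts heads or passes sheep units through", {
  lv <- data.frame(parcel_id = 1:2, cattle = c(10, 0), sheep = c(100, 0),
                   horses = c(2, 0))
  al <- actual_load(lv)
  expect_equal(al$actual_su, c(10 * 4.5 + 100 + 2 * 6, 0))

  pass <- actual_load(data.frame(parcel_id = 1, sheep_units = 338159))
  expect_equal(pass$actual_su, 338159)

  expect_equal(actual_load(data.frame(parcel_id = 1, sheep = 100))$actual_su,
               100)
  expect_error(actual_load(data.frame(parcel_id = 1, camels = 3)), "camels")
})

test_that("residual capacity applies the strict overload rule and adds up", {
  rc <- residual_capacity(c(100, 50, 80), c(100, 70, 10))
  expect_equal(rc$RCC, c(0, -20, 70))
  expect_equal(rc$overloaded, c(FALSE, TRUE, FALSE))  # tie is at capacity
  expect_equal(attr(rc, "county"), sum(rc$RCC))
  expect_error(residual_capacity(1:2, 1:3), "mismatch")
})

test_that("parcel accounts satisfy the exact ledger identities", {
  county <- tiny_county(seed = 26, n_parcels = 5)
  g <- county$grid
  set.seed(26)
  ctp <- zonal_stats(grid_raster(g, runif(256, 5, 40)), county$parcels)
  dz <- list(kiang = zonal_stats(grid_raster(g, rexp(256, 2)), county$parcels),
             gazelle = zonal_stats(grid_raster(g, rexp(256, 8)), county$parcels))
  lv <- data.frame(parcel_id = 1:5, cattle = rpois(5, 300),
                   sheep = rpois(5, 800), horses = rpois(5, 20))
  acc <- parcel_accounts(county$parcels, ctp, dz, lv)
  expect_equal(acc$C_t + acc$C_w, acc$C_tp, tolerance = 1e-9)
  expect_equal(acc$RCC + acc$actual_su, acc$C_t, tolerance = 1e-9)
  expect_true(all(acc$C_w >= 0))
  expect_equal(acc$overloaded, acc$RCC < 0)

  # increasing a species density weakly decreases every parcel's RCC
  dz2 <- dz
  dz2$kiang$mean <- dz2$kiang$mean * 2
  acc2 <- parcel_accounts(county$parcels, ctp, dz2, lv)
  expect_true(all(acc2$RCC <= acc$RCC))
})

test_that("county ledger reproduces the published worked example", {
  led <- county_ledger(grass_yield_t = 1293500,
                       populations = c(kiang = 11397, gazelle = 1545),
                       actual_su = 338159)
  expect_equal(led$C_tp, 1293500 * 1000 * 0.85 * 0.65 / (4 * 365))
  expect_equal(led$C_w, 11397 * 6 + 1545 * 0.3)
  expect_equal(led$C_t, led$C_tp - led$C_w)
  expect_equal(led$RCC, led$C_t - 338159)
  expect_error(county_ledger(1000, c(yak = 5), 0), "yak")
})
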