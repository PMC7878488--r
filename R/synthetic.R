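# Synthetic county generator: parcels, covariates, latent wildlife truths,
# transect surveys, NDVI stack and livestock table with the statistical
# structure the downstream analysis assumes. Every generator is a pure
# function of (config, seed).

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)

#' Specification of a synthetic county
#'
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` in projected km
#'   (default a 160 x 160 km square, close to the ~25,300 km2 of an alpine
#'   county-scale study region).
#' @param cell_size grid cell edge (km), default 5.
#' @param n_parcels number of grazing-management parcels, default 27.
#' @param seed integer RNG seed; every derived artifact is a deterministic
#'   function of this spec.
#' @return a `county_spec` object.
#' @export
county_spec <- function(extent = c(0, 0, 160, 160), cell_size = 5,
                        n_parcels = 27, seed = 1L) {
  if (length(extent) != 4 || extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("degenerate extent: need xmax > xmin and ymax > ymin")
  if (n_parcels < 1) stop("n_parcels must be >= 1")
  g <- county_grid(extent[1], extent[2], extent[3], extent[4], cell_size)
  if (n_parcels > g$nrow * g$ncol) stop("more parcels than grid cells")
  structure(list(extent = extent, cell_size = cell_size,
                 n_parcels = as.integer(n_parcels), seed = as.integer(seed),
                 grid = g),
            class = "county_spec")
}

# Smooth stationary Gaussian random field by random Fourier features
# (squared-exponential covariance, practical range ~ range_km).
gaussian_field <- function(grid, range_km = 40, sd = 1, mean = 0,
                           n_features = 256L) {
  ctr <- grid_centers(grid)
  ell <- range_km / 2
  omega <- matrix(stats::rnorm(2L * n_features, sd = 1 / ell), ncol = 2L)
  phi <- stats::runif(n_features, 0, 2 * pi)
  proj <- cbind(ctr$x, ctr$y) %*% t(omega)
  vals <- mean + sd * sqrt(2 / n_features) *
    rowSums(cos(sweep(proj, 2L, phi, "+")))
  grid_raster(grid, vals)
}

# Recursive grid-aligned rectangular tiling: repeatedly split the largest
# remaining rectangle along its longer axis at a random interior grid line.
# Exact partition (union = extent, disjoint interiors), deterministic by seed.
tile_rectangles <- function(grid, n, seed) {
  with_seed(seed, {
    rects <- list(c(0L, grid$ncol, 0L, grid$nrow))  # c0, c1, r0, r1 (cells)
    while (length(rects) < n) {
      sizes <- vapply(rects, function(r) (r[2] - r[1]) * (r[4] - r[3]), numeric(1))
      splittable <- vapply(rects, function(r)
        (r[2] - r[1]) > 1L || (r[4] - r[3]) > 1L, logical(1))
      if (!any(splittable)) stop("cannot split further: too many parcels")
      k <- which(splittable)[which.max(sizes[splittable])]
      r <- rects[[k]]
      w <- r[2] - r[1]; h <- r[4] - r[3]
      if (w >= h) {
        cut <- r[1] + sample.int(w - 1L, 1L)
        new <- list(c(r[1], cut, r[3], r[4]), c(cut, r[2], r[3], r[4]))
      } else {
        cut <- r[3] + sample.int(h - 1L, 1L)
        new <- list(c(r[1], r[2], r[3], cut), c(r[1], r[2], cut, r[4]))
      }
      rects <- c(rects[-k], new)
    }
    cs <- grid$cellsize
    rings <- lapply(rects, function(r) {
      x0 <- grid$xmin + r[1] * cs; x1 <- grid$xmin + r[2] * cs
      y0 <- grid$ymax - r[4] * cs; y1 <- grid$ymax - r[3] * cs
      cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y0))
    })
    parcel_set(seq_along(rings), rings)
  })
}

#' Generate a synthetic county: parcels and environmental covariates
#'
#' Builds the shared analysis grid, an exact parcel tiling, and five
#' covariate surfaces: elevation (m), slope (degrees) and aspect (degrees
#' clockwise from north) derived from the elevation field, plus mean annual
#' temperature (degC) and annual precipitation (mm) with elevation lapse and
#' independent smooth anomalies. All surfaces share one grid and are
#' bit-identical for a fixed seed.
#'
#' @param spec a [county_spec()].
#' @return a list with `grid`, `parcels` ([parcel_set()]) and `covariates`
#'   (named list of [grid_raster()]: elevation, slope, aspect, temperature,
#'   precipitation).
#' @export
make_county <- function(spec) {
  stopifnot(inherits(spec, "county_spec"))
  g <- spec$grid
  parcels <- tile_rectangles(g, spec$n_parcels, sub_seed(spec$seed, 1L))
  covs <- with_seed(sub_seed(spec$seed, 2L), {
    elev <- gaussian_field(g, range_km = 60, sd = 150, mean = 4500)
    zm <- matrix(elev$values, g$nrow, g$ncol, byrow = TRUE)
    # central differences (m per km), one-sided at borders
    ddx <- t(apply(zm, 1L, function(r) {
      n <- length(r)
      c(r[2] - r[1], (r[3:n] - r[1:(n - 2)]) / 2, r[n] - r[n - 1]) / g$cellsize
    }))
    ddy <- apply(zm, 2L, function(col) {
      n <- length(col)
      # row index increases southward, so negate for northward gradient
      -c(col[2] - col[1], (col[3:n] - col[1:(n - 2)]) / 2, col[n] - col[n - 1]) / g$cellsize
    })
    slope <- atan(sqrt(ddx^2 + ddy^2) / 1000) * 180 / pi
    aspect <- (atan2(ddx, ddy) * 180 / pi) %% 360  # downslope direction from N
    temp <- grid_raster(g, -3.8 - 0.0065 * (elev$values - 4500) +
                          gaussian_field(g, range_km = 80, sd = 0.8)$values,
                        name = "temperature")
    prec <- grid_raster(g, pmax(50, 304 + gaussian_field(g, range_km = 70,
                                                         sd = 45)$values),
                        name = "precipitation")
    list(elevation = grid_raster(g, elev$values, "elevation"),
         slope = grid_raster(g, as.numeric(t(slope)), "slope"),
         aspect = grid_raster(g, as.numeric(t(aspect)), "aspect"),
         temperature = temp, precipitation = prec)
  })
  list(grid = g, parcels = parcels, covariates = covs)
}

#' Default latent-truth parameters for the two study species
#'
#' Two wild ungulates with distinct habitat preferences and abundances:
#' `kiang` (large equid, converted at 6 sheep units per head) and
#' `gazelle` (small bovid, 0.3 sheep units per head). Total populations
#' default to values consistent with county-wide mean discovery rates of
#' 1.33 and 0.49 animals per km of transect per season under the default
#' [survey_design()] (3 km effective strip, full detection, 25,600 km2).
#'
#' @return named list of per-species parameter lists with fields `total`
#'   (county population), `beta0` and `beta` (logistic suitability
#'   coefficients on standardized covariates), `range_km` and `sdlog`
#'   (log-density field smoothness and spread).
#' @export
default_species_params <- function() {
  list(
    kiang = list(
      total = 11349,
      beta0 = 0.35,
      beta = c(elevation = -0.8, slope = -1.0, temperature = 0.5,
               precipitation = 0.3),
      range_km = 40, sdlog = 0.6
    ),
    gazelle = list(
      total = 4181,
      beta0 = -0.25,
      beta = c(elevation = 0.4, slope = -0.6, temperature = 0.2,
               precipitation = 0.8),
      range_km = 30, sdlog = 0.6
    )
  )
}

std01 <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
}

#' Generate latent species truths on the county grid
#'
#' For each species, habitat suitability truth is a deterministic logistic
#' function of the standardized covariates thresholded at probability 0.5,
#' and the latent density is a log-Gaussian random field restricted to
#' suitable cells and rescaled so that density times cell area integrates to
#' the configured total population. Density is therefore zero wherever the
#' suitability truth is zero, and non-negative and finite everywhere.
#'
#' @param county output of [make_county()].
#' @param species_params named list as [default_species_params()].
#' @param seed integer seed.
#' @return named list per species with `density` and `suitability`
#'   ([grid_raster()]; suitability is 0/1), `total` and `species_id`.
#' @export
make_truth <- function(county, species_params = default_species_params(),
                       seed = 1L) {
  g <- county$grid
  zc <- lapply(county$covariates, function(r) std01(r$values))
  out <- list()
  for (i in seq_along(species_params)) {
    sp <- species_params[[i]]
    id <- names(species_params)[i]
    eta <- sp$beta0
    for (nm in names(sp$beta)) {
      if (is.null(zc[[nm]])) stop("unknown covariate in species params: ", nm)
      eta <- eta + sp$beta[[nm]] * zc[[nm]]
    }
    suit <- as.numeric(stats::plogis(eta) >= 0.5)
    dens <- with_seed(sub_seed(seed, 100L + i), {
      f <- gaussian_field(g, range_km = sp$range_km, sd = sp$sdlog)
      exp(f$values) * suit
    })
    tot <- sum(dens) * g$cellsize^2
    dens <- if (tot > 0) dens * sp$total / tot else dens
    out[[id]] <- list(species_id = id,
                      density = grid_raster(g, dens, paste0("density_", id)),
                      suitability = grid_raster(g, suit, paste0("suit_", id)),
                      total = if (tot > 0) sp$total else 0)
  }
  out
}

#' Line-transect survey design
#'
#' @param n_transects transect lines per season (default 250; with the
#'   default two seasons this yields 500 survey lines).
#' @param seasons character vector of season labels.
#' @param transect_length_km length of each line (km).
#' @param halfwidth_km effective strip half-width (km); the counted strip is
#'   `2 * halfwidth * length`. Default 1.5 km, appropriate for large-bodied
#'   ungulates visible at distance on open steppe.
#' @param detection_prob probability that an animal inside the strip is
#'   recorded, in (0, 1].
#' @return a `survey_design` object.
#' @export
survey_design <- function(n_transects = 250L, seasons = c("summer", "winter"),
                          transect_length_km = 10, halfwidth_km = 1.5,
                          detection_prob = 1) {
  if (transect_length_km <= 0) stop("transect length must be > 0")
  if (halfwidth_km <= 0) stop("halfwidth must be > 0")
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must be in [0, 1]")
  structure(list(n_transects = as.integer(n_transects), seasons = seasons,
                 transect_length_km = transect_length_km,
                 halfwidth_km = halfwidth_km, detection_prob = detection_prob),
            class = "survey_design")
}

#' Simulate line-transect surveys over latent truths
#'
#' Transect lines are placed uniformly at random (uniform random orientation;
#' midpoint uniform over the subset of the extent that keeps the whole line
#' inside) and revisited in every season. Each line is surveyed once per
#' season for every species; the recorded count is Poisson with mean equal
#' to the mean latent density along the line (the strip-integrated density)
#' times the strip area times the detection probability, independently
#' across seasons.
#'
#' @param truth output of [make_truth()].
#' @param design a [survey_design()].
#' @param seed integer seed.
#' @return data.frame with columns `transect_id`, `species`, `season`,
#'   `count`, `length_km`, `x`, `y` (midpoint) and `wkt_geometry`
#'   (LINESTRING in km coordinates).
#' @export
simulate_surveys <- function(truth, design, seed = 1L) {
  g <- truth[[1]]$density$grid
  L <- design$transect_length_km
  strip <- 2 * design$halfwidth_km * L * design$detection_prob
  with_seed(sub_seed(seed, 300L), {
    n <- design$n_transects
    theta <- stats::runif(n, 0, pi)
    dx <- abs(L / 2 * cos(theta)); dy <- abs(L / 2 * sin(theta))
    xm <- stats::runif(n, g$xmin + dx, g$xmax - dx)
    ym <- stats::runif(n, g$ymin + dy, g$ymax - dy)
    # density integrated along each line: sample at ~1 km steps
    frac <- seq(-0.5, 0.5, length.out = max(2L, ceiling(L)) + 1L)
    line_cells <- lapply(seq_len(n), function(j)
      cell_at(g, xm[j] + frac * L * cos(theta[j]),
              ym[j] + frac * L * sin(theta[j])))
    wkt <- sprintf("LINESTRING (%.6f %.6f, %.6f %.6f)",
                   xm - L / 2 * cos(theta), ym - L / 2 * sin(theta),
                   xm + L / 2 * cos(theta), ym + L / 2 * sin(theta))
    rows <- list()
    for (season in design$seasons) {
      for (id in names(truth)) {
        dvals <- truth[[id]]$density$values
        lambda <- vapply(line_cells, function(cc)
          mean(dvals[cc], na.rm = TRUE), numeric(1)) * strip
        rows[[length(rows) + 1L]] <- data.frame(
          transect_id = seq_len(n), species = id, season = season,
          count = stats::rpois(n, lambda), length_km = L,
          x = xm, y = ym, wkt_geometry = wkt, stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    df[order(df$transect_id, df$species, df$season), ]
  })
}

#' Simulate a per-parcel livestock table
#'
#' Sheep units are allocated to parcels proportionally to parcel area times
#' a lognormal heterogeneity factor, split across classes by the configured
#' sheep-unit mix, and converted to integer head counts. Cattle and horse
#' heads are rounded from their sheep-unit shares; the sheep class (rate 1
#' SU/head) absorbs the residual, so each parcel's sheep-unit total is
#' within 0.5 SU of its allocation and the county total is within
#' `n_parcels / 2` SU of `total_sheep_units` whenever the mix includes sheep.
#'
#' @param parcels a [parcel_set()].
#' @param total_sheep_units county-wide livestock total in sheep units
#'   (default 338,159, a published county total for the study system).
#' @param mix named sheep-unit fractions `c(cattle=, sheep=, horses=)`
#'   summing to 1 (default 73/24/3 percent).
#' @param rates sheep units per head by class (sheep fixed at 1).
#' @param heterogeneity lognormal sd of the per-parcel allocation factor.
#' @param seed integer seed.
#' @return data.frame with columns `parcel_id`, `cattle`, `sheep`, `horses`.
#' @export
simulate_livestock <- function(parcels, total_sheep_units = 338159,
                               mix = c(cattle = 0.73, sheep = 0.24, horses = 0.03),
                               rates = c(cattle = 4.5, sheep = 1, horses = 6),
                               heterogeneity = 0.4, seed = 1L) {
  if (total_sheep_units < 0) stop("total_sheep_units must be >= 0")
  if (abs(sum(mix) - 1) > 1e-9) stop("mix fractions must sum to 1")
  areas <- parcel_areas(parcels)
  with_seed(sub_seed(seed, 400L), {
    w <- areas * exp(stats::rnorm(length(areas), 0, heterogeneity))
    su <- total_sheep_units * w / sum(w)
    cattle <- round(mix[["cattle"]] * su / rates[["cattle"]])
    horses <- round(mix[["horses"]] * su / rates[["horses"]])
    sheep <- if (mix[["sheep"]] > 0)
      pmax(0, round(su - rates[["cattle"]] * cattle - rates[["horses"]] * horses))
    else rep(0, length(su))
    data.frame(parcel_id = parcels$id, cattle = as.integer(cattle),
               sheep = as.integer(sheep), horses = as.integer(horses))
  })
}

#' Simulate an NDVI acquisition stack
#'
#' A smooth latent greenness field (values typical of alpine steppe and
#' meadow in mid growing season) observed on several acquisition dates, each
#' degraded by multiplicative cloud/atmospheric low-bias patches. The
#' per-cell maximum over the stack recovers the latent field, which is the
#' rationale of the maximal-value composite.
#'
#' @param grid a [county_grid()].
#' @param n_layers number of acquisitions (default 4).
#' @param mean,sd mean and spatial sd of the latent NDVI field
#'   (defaults 0.22 and 0.10).
#' @param cloud_frac expected fraction of cells degraded per acquisition.
#' @param seed integer seed.
#' @return list with `layers` (list of [grid_raster()], labelled) and
#'   `latent` (the clean field).
#' @export
simulate_ndvi <- function(grid, n_layers = 4L, mean = 0.22, sd = 0.10,
                          cloud_frac = 0.3, seed = 1L) {
  if (n_layers < 1) stop("need at least one layer")
  with_seed(sub_seed(seed, 500L), {
    latent <- pmin(0.9, pmax(-0.1, gaussian_field(grid, range_km = 50,
                                                  sd = sd, mean = mean)$values))
    layers <- lapply(seq_len(n_layers), function(k) {
      cloudy <- stats::runif(length(latent)) < cloud_frac
      obs <- latent
      obs[cloudy] <- obs[cloudy] * stats::runif(sum(cloudy), 0.2, 0.8)
      grid_raster(grid, obs, sprintf("ndvi_%02d", k))
    })
    list(layers = layers, latent = grid_raster(grid, latent, "ndvi_latent"))
  })
}
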