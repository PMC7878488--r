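# NDVI maximal-value composite, NDVI-to-grass-yield conversion, and
# theoretical livestock carrying capacity per unit area.

#' NDVI-to-yield conversion parameters
#'
#' Grass yield is a linear function of composite NDVI,
#' `Y = intercept + slope * NDVI`, with published coefficients for alpine
#' grassland (-47.021 and 440.21). The literature source of the regression
#' does not state its output unit, so the unit is explicit configuration
#' carried through every total rather than an assumption.
#'
#' @param intercept,slope regression coefficients (slope > 0).
#' @param unit yield unit of `Y`: one of `"kg/ha"` (default), `"g/m2"`,
#'   `"t/km2"`, `"kg/km2"`.
#' @param clamp_negative clamp negative yields (NDVI below the
#'   zero-crossing, about 0.107) to zero, counting the clamped cells.
#' @return a `yield_params` object.
#' @export
yield_params <- function(intercept = -47.021, slope = 440.21,
                         unit = c("kg/ha", "g/m2", "t/km2", "kg/km2"),
                         clamp_negative = TRUE) {
  unit <- match.arg(unit)
  if (slope <= 0) stop("slope must be > 0")
  structure(list(intercept = intercept, slope = slope, unit = unit,
                 clamp_negative = clamp_negative),
            class = "yield_params")
}

# kg per km2 represented by one unit of yield value
yield_unit_kg_km2 <- function(unit) {
  switch(unit, "kg/ha" = 100, "g/m2" = 1000, "t/km2" = 1000, "kg/km2" = 1,
         stop("unknown yield unit: ", unit))
}

#' Carrying-capacity parameters
#'
#' The standard rangeland stocking-rate constants: theoretical carrying
#' capacity per unit area is `C_tp = (Y * E * U) / (I * T)` where `Y` is
#' grass yield per unit area, `E` the edible forage ratio, `U` the grazing
#' utilization rate, `I` the daily intake per sheep unit (kg/day) and `T`
#' the number of grazing days.
#'
#' @param E edible forage ratio in (0, 1], default 0.85.
#' @param U grazing utilization rate in (0, 1], default 0.65.
#' @param I daily intake per sheep unit (kg/day), default 4.0.
#' @param T_days grazing days per year, default 365.
#' @return a `capacity_params` object.
#' @export
capacity_params <- function(E = 0.85, U = 0.65, I = 4.0, T_days = 365) {
  if (E <= 0 || E > 1) stop("E must be in (0, 1]")
  if (U <= 0 || U > 1) stop("U must be in (0, 1]")
  if (I <= 0) stop("daily intake I must be > 0")
  if (T_days <= 0) stop("grazing days T must be > 0")
  structure(list(E = E, U = U, I = I, T_days = T_days),
            class = "capacity_params")
}

#' Maximal-value composite of an NDVI stack
#'
#' Per-cell maximum over the acquisition layers, the standard device for
#' suppressing cloud and atmospheric low-bias in NDVI time series. Nodata
#' is ignored per layer; a composite cell is nodata only when every layer
#' is nodata there.
#'
#' @param layers list of NDVI [grid_raster()] on a shared grid, values in
#'   `[-1, 1]`.
#' @return composite [grid_raster()].
#' @export
max_value_composite <- function(layers) {
  if (length(layers) < 1) stop("empty NDVI stack")
  g <- layers[[1]]$grid
  vals <- sapply(layers, function(r) {
    stop_if_grid_mismatch(g, r$grid, "NDVI layers")
    r$values
  })
  vals <- matrix(vals, ncol = length(layers))
  out <- apply(vals, 1L, function(v) if (all(is.na(v))) NA_real_ else
    max(v, na.rm = TRUE))
  grid_raster(g, out, "ndvi_composite")
}

#' Convert composite NDVI to grass yield
#'
#' Applies the affine model `Y = intercept + slope * NDVI` cell-wise. With
#' `clamp_negative` (default) yields below zero — NDVI under the
#' zero-crossing `-intercept/slope` — are set to 0 and counted in the
#' `n_clamped` attribute.
#'
#' @param ndvi composite NDVI [grid_raster()], values in `[-1, 1]`.
#' @param params a [yield_params()].
#' @return yield [grid_raster()] in `params$unit`, with attribute
#'   `n_clamped`.
#' @export
ndvi_to_yield <- function(ndvi, params = yield_params()) {
  v <- ndvi$values
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("NDVI values outside [-1, 1]")
  y <- params$intercept + params$slope * v
  n_clamped <- 0L
  if (params$clamp_negative) {
    n_clamped <- sum(y < 0, na.rm = TRUE)
    y[y < 0] <- 0
  }
  out <- grid_raster(ndvi$grid, y, "grass_yield")
  attr(out, "unit") <- params$unit
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Theoretical carrying capacity per unit area
#'
#' `C_tp = (Y * E * U) / (I * T)` in sheep units per km2, with the yield
#' converted from its configured unit to kg/km2 first.
#'
#' @param yield yield [grid_raster()] from [ndvi_to_yield()], or a numeric
#'   vector of yields.
#' @param cp a [capacity_params()].
#' @param unit yield unit; defaults to the raster's `unit` attribute.
#' @return [grid_raster()] (or numeric) of sheep units per km2.
#' @export
theoretical_capacity_per_area <- function(yield, cp = capacity_params(),
                                          unit = NULL) {
  is_raster <- inherits(yield, "grid_raster")
  if (is.null(unit)) unit <- if (is_raster) attr(yield, "unit") else "kg/ha"
  if (is.null(unit)) unit <- "kg/ha"
  v <- if (is_raster) yield$values else yield
  if (any(v < 0, na.rm = TRUE)) stop("yield must be >= 0")
  ykg <- v * yield_unit_kg_km2(unit)
  ctp <- ykg * cp$E * cp$U / (cp$I * cp$T_days)
  if (is_raster) grid_raster(yield$grid, ctp, "C_tp_per_km2") else ctp
}

#' County-total theoretical carrying capacity from a total yield
#'
#' Sheep units supportable by a total annual grass yield:
#' `total_yield_kg * E * U / (I * T)`. This is the county-scale form of the
#' per-area relation, used when the total yield is known directly.
#'
#' @param total_yield_kg total annual grass yield in kg.
#' @param cp a [capacity_params()].
#' @return total carrying capacity in sheep units.
#' @export
theoretical_capacity_total <- function(total_yield_kg, cp = capacity_params()) {
  if (total_yield_kg < 0) stop("total yield must be >= 0")
  total_yield_kg * cp$E * cp$U / (cp$I * cp$T_days)
}
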