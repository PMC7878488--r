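# Per-parcel coexistence accounting: zonal aggregation, wildlife grazing
# offset, ecological carrying capacity, actual livestock load and residual
# carrying capacity (RCC), all in sheep units.

#' Default wild-ungulate sheep-unit conversion rates
#'
#' A kiang is equivalent to 6 sheep units; a Tibetan gazelle (average body
#' mass ~14 kg) to 0.3 sheep units.
#'
#' @return named numeric vector of sheep units per animal.
#' @export
species_conversions <- function() c(kiang = 6, gazelle = 0.3)

#' Default livestock sheep-unit rates per head
#'
#' Sheep are the unit (1 SU/head) by definition; cattle (yak) and horse
#' rates follow common Chinese rangeland practice and are configurable.
#'
#' @return named numeric vector of sheep units per head.
#' @export
livestock_rates <- function() c(cattle = 4.5, sheep = 1, horses = 6)

#' Zonal mean and integral of a surface over parcels
#'
#' Cells are assigned to parcels by cell-centre containment (each boundary
#' cell belongs to exactly one parcel); the parcel integral is the sum of
#' cell value times cell area, so parcel integrals sum exactly to the
#' county integral when the parcels tile the extent.
#'
#' @param x a [grid_raster()].
#' @param parcels a [parcel_set()] sharing the raster's coordinate system.
#' @return data.frame `parcel_id`, `n_cells`, `mean`, `integral` (value
#'   unit x km2). Parcels containing no cell centre get `NA` with a warning.
#' @export
zonal_stats <- function(x, parcels) {
  pid <- parcel_of_cell(parcels, x$grid)
  area <- x$grid$cellsize^2
  out <- data.frame(parcel_id = parcels$id, n_cells = 0L,
                    mean = NA_real_, integral = NA_real_)
  for (k in seq_along(parcels$id)) {
    sel <- which(pid == parcels$id[k])
    out$n_cells[k] <- length(sel)
    if (length(sel)) {
      out$mean[k] <- mean(x$values[sel])
      out$integral[k] <- sum(x$values[sel]) * area
    }
  }
  if (any(out$n_cells == 0))
    warning("parcel(s) with no contained cell centre: ",
            paste(out$parcel_id[out$n_cells == 0], collapse = ", "))
  out
}

#' Wildlife grazing offset per parcel
#'
#' `C_w = sum_i D_i * S_i * K_i` over species i: mean density times parcel
#' area times the species sheep-unit rate, summed over species.
#'
#' @param densities data.frame with columns `parcel_id`, `species`,
#'   `density` (animals/km2, the parcel mean).
#' @param areas named numeric vector of parcel areas (km2), names =
#'   parcel ids.
#' @param conversions named sheep-unit rates per animal,
#'   see [species_conversions()].
#' @return data.frame `parcel_id`, `C_w` (sheep units), one row per parcel
#'   present in `densities`, plus the county total as attribute `county`.
#' @export
wildlife_offset <- function(densities, areas,
                            conversions = species_conversions()) {
  missing <- setdiff(unique(densities$species), names(conversions))
  if (length(missing))
    stop("no sheep-unit conversion for species: ",
         paste(missing, collapse = ", "))
  s <- areas[as.character(densities$parcel_id)]
  if (any(is.na(s))) stop("missing parcel area for some densities")
  su <- densities$density * s * conversions[densities$species]
  agg <- tapply(su, densities$parcel_id, sum)
  out <- data.frame(parcel_id = as.integer(names(agg)),
                    C_w = as.numeric(agg))
  out <- out[order(out$parcel_id), ]
  rownames(out) <- NULL
  attr(out, "county") <- sum(out$C_w)
  out
}

#' Ecological carrying capacity
#'
#' `C_t = C_tp_total - C_w`: the sheep units left for livestock after the
#' wild ungulates' forage demand. Negative values are permitted (wildlife
#' demand exceeds the parcel's usable forage) and flagged.
#'
#' @param C_tp_total theoretical carrying capacity per parcel (sheep units).
#' @param C_w wildlife offset per parcel (sheep units).
#' @return data.frame `C_t`, `wildlife_exceeds_forage` (logical).
#' @export
ecological_capacity <- function(C_tp_total, C_w) {
  if (length(C_tp_total) != length(C_w)) stop("length mismatch")
  ct <- C_tp_total - C_w
  data.frame(C_t = ct, wildlife_exceeds_forage = ct < 0)
}

#' Actual livestock load in sheep units
#'
#' Converts per-parcel head counts to sheep units (`sum(heads * rate)`), or
#' passes through a table already expressed in sheep units (column
#' `sheep_units`).
#'
#' @param livestock data.frame with `parcel_id` and either head-count
#'   columns named in `rates`, or a `sheep_units` column (passthrough).
#' @param rates named sheep-unit rates per head, see [livestock_rates()].
#' @return data.frame `parcel_id`, `actual_su`.
#' @export
actual_load <- function(livestock, rates = livestock_rates()) {
  if ("sheep_units" %in% names(livestock)) {
    out <- data.frame(parcel_id = livestock$parcel_id,
                      actual_su = as.numeric(livestock$sheep_units))
  } else {
    classes <- setdiff(names(livestock), "parcel_id")
    unknown <- setdiff(classes, names(rates))
    if (length(unknown))
      stop("no sheep-unit rate for livestock class: ",
           paste(unknown, collapse = ", "))
    su <- rep(0, nrow(livestock))
    for (cl in classes) su <- su + livestock[[cl]] * rates[[cl]]
    out <- data.frame(parcel_id = livestock$parcel_id, actual_su = su)
  }
  out[order(out$parcel_id), , drop = FALSE]
}

#' Residual carrying capacity
#'
#' `RCC = C_t - actual` per parcel; a parcel is overloaded iff its RCC is
#' strictly negative (RCC = 0 counts as exactly at capacity). The county
#' RCC is the exact sum over parcels.
#'
#' @param C_t ecological carrying capacity per parcel (sheep units).
#' @param actual actual livestock load per parcel (sheep units).
#' @param parcel_id optional parcel ids (defaults to positions).
#' @return data.frame `parcel_id`, `RCC`, `overloaded`, with the county
#'   total as attribute `county`.
#' @export
residual_capacity <- function(C_t, actual, parcel_id = seq_along(C_t)) {
  if (length(C_t) != length(actual)) stop("parcel mismatch: lengths differ")
  rcc <- C_t - actual
  out <- data.frame(parcel_id = parcel_id, RCC = rcc, overloaded = rcc < 0)
  attr(out, "county") <- sum(rcc)
  out
}

#' Close the full per-parcel carrying-capacity ledger
#'
#' Joins the per-parcel theoretical capacity, wildlife densities, livestock
#' load and parcel geometry into one account per parcel, enforcing the
#' exact ledger identities `C_t = C_tp_total - C_w` and
#' `RCC = C_t - actual`.
#'
#' @param parcels a [parcel_set()].
#' @param ctp_zonal [zonal_stats()] of the per-area theoretical capacity
#'   surface (integral = sheep units per parcel).
#' @param density_zonal named list (by species) of [zonal_stats()] of the
#'   masked density surfaces.
#' @param livestock livestock table for [actual_load()].
#' @param conversions species sheep-unit rates.
#' @param rates livestock sheep-unit rates.
#' @return data.frame with one row per parcel: `parcel_id`, `area_km2`,
#'   one `<species>_density` column per species, `C_w`, `C_tp`, `C_t`,
#'   `actual_su`, `RCC`, `overloaded`.
#' @export
parcel_accounts <- function(parcels, ctp_zonal, density_zonal, livestock,
                            conversions = species_conversions(),
                            rates = livestock_rates()) {
  areas <- stats::setNames(parcel_areas(parcels), parcels$id)
  dens <- do.call(rbind, lapply(names(density_zonal), function(sp)
    data.frame(parcel_id = density_zonal[[sp]]$parcel_id, species = sp,
               density = ifelse(is.na(density_zonal[[sp]]$mean), 0,
                                density_zonal[[sp]]$mean))))
  cw <- wildlife_offset(dens, areas, conversions)
  act <- actual_load(livestock, rates)
  ord <- order(parcels$id)
  acc <- data.frame(parcel_id = parcels$id[ord],
                    area_km2 = as.numeric(areas[ord]))
  for (sp in names(density_zonal)) {
    z <- density_zonal[[sp]]
    acc[[paste0(sp, "_density")]] <-
      ifelse(is.na(z$mean), 0, z$mean)[match(acc$parcel_id, z$parcel_id)]
  }
  acc$C_w <- cw$C_w[match(acc$parcel_id, cw$parcel_id)]
  ctp <- ifelse(is.na(ctp_zonal$integral), 0, ctp_zonal$integral)
  acc$C_tp <- ctp[match(acc$parcel_id, ctp_zonal$parcel_id)]
  ec <- ecological_capacity(acc$C_tp, acc$C_w)
  acc$C_t <- ec$C_t
  acc$actual_su <- act$actual_su[match(acc$parcel_id, act$parcel_id)]
  if (any(is.na(acc$actual_su))) stop("livestock table missing parcels")
  rc <- residual_capacity(acc$C_t, acc$actual_su, acc$parcel_id)
  acc$RCC <- rc$RCC
  acc$overloaded <- rc$overloaded
  acc
}

#' County-scale worked ledger from aggregate inputs
#'
#' The county-total form of the accounting chain, for use when the inputs
#' are published aggregates rather than surfaces: total grass yield (tons)
#' gives the theoretical capacity; county populations times sheep-unit
#' rates give the wildlife offset; their difference is the ecological
#' capacity; subtracting the actual livestock load gives the county RCC.
#'
#' @param grass_yield_t total annual grass yield in tons.
#' @param populations named county populations per species (heads).
#' @param actual_su actual livestock load (sheep units).
#' @param cp a [capacity_params()].
#' @param conversions species sheep-unit rates.
#' @return list with `C_tp`, `C_w`, `C_t`, `RCC` (sheep units).
#' @export
county_ledger <- function(grass_yield_t, populations, actual_su,
                          cp = capacity_params(),
                          conversions = species_conversions()) {
  missing <- setdiff(names(populations), names(conversions))
  if (length(missing))
    stop("no conversion for species: ", paste(missing, collapse = ", "))
  c_tp <- theoretical_capacity_total(grass_yield_t * 1000, cp)
  c_w <- sum(populations * conversions[names(populations)])
  c_t <- c_tp - c_w
  list(C_tp = c_tp, C_w = c_w, C_t = c_t, RCC = c_t - actual_su)
}
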