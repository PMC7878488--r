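# Strip-transect abundance density and discovery-rate summaries.

#' Species abundance density from strip-transect counts
#'
#' Converts per-line counts to animals per km2 with the strip-transect
#' estimator: `sad = count / (2 * halfwidth * length)`. The representative
#' location of each density value is the line midpoint, which is what the
#' spatial interpolation consumes.
#'
#' @param records data.frame of survey lines with columns `transect_id`,
#'   `species`, `season`, `count`, `length_km`, and either `x`/`y` midpoint
#'   columns or a `wkt_geometry` LINESTRING column.
#' @param halfwidth_km effective strip half-width (km), > 0. Default 0.5 km,
#'   a conventional strip half-width; it is deliberately the one tunable of
#'   this estimator and must match how the counts were collected.
#' @return data.frame `transect_id`, `species`, `season`, `sad`
#'   (animals/km2), `x`, `y`.
#' @export
estimate_sad <- function(records, halfwidth_km = 0.5) {
  if (halfwidth_km <= 0) stop("halfwidth must be > 0")
  if (any(records$length_km <= 0) || any(!is.finite(records$length_km)))
    stop("transect lengths must be finite and > 0")
  if (any(records$count < 0)) stop("counts must be >= 0")
  xy <- transect_midpoints(records)
  data.frame(transect_id = records$transect_id, species = records$species,
             season = records$season,
             sad = records$count / (2 * halfwidth_km * records$length_km),
             x = xy$x, y = xy$y, stringsAsFactors = FALSE)
}

transect_midpoints <- function(records) {
  if (all(c("x", "y") %in% names(records)))
    return(data.frame(x = records$x, y = records$y))
  if (!"wkt_geometry" %in% names(records))
    stop("records need x/y columns or a wkt_geometry column")
  coords <- regmatches(records$wkt_geometry,
                       gregexpr("-?[0-9]+\\.?[0-9]*", records$wkt_geometry))
  mid <- t(vapply(coords, function(cc) {
    v <- as.numeric(cc)
    c((v[1] + v[3]) / 2, (v[2] + v[4]) / 2)
  }, numeric(2)))
  data.frame(x = mid[, 1], y = mid[, 2])
}

#' Mean discovery rate (animals per km of transect)
#'
#' Total animals counted divided by total line length for one species,
#' either per season or averaged over seasons. This is the raw survey
#' summary a field campaign reports (e.g. "1.33 animals per km per season").
#'
#' @param records survey data.frame as in [estimate_sad()].
#' @param species species identifier to summarize.
#' @param season a season label, or `NULL` (default) for the unweighted mean
#'   of per-season rates.
#' @return a single rate in animals/km.
#' @export
discovery_rate <- function(records, species, season = NULL) {
  sel <- records[records$species == species &
                   (is.null(season) | records$season %in% season), , drop = FALSE]
  if (nrow(sel) == 0) stop("no records for species '", species, "'",
                           if (!is.null(season)) paste0(" in season '", season, "'"))
  if (is.null(season)) {
    rates <- vapply(split(sel, sel$season),
                    function(d) sum(d$count) / sum(d$length_km), numeric(1))
    mean(rates)
  } else {
    sum(sel$count) / sum(sel$length_km)
  }
}

#' Merge per-season densities into one surface input per species
#'
#' Seasonal survey campaigns revisit the same lines; their per-line
#' densities are combined at matched locations before interpolation. The
#' default rule is the arithmetic mean over seasons; `max` keeps the larger
#' seasonal value; `none` passes seasons through unchanged.
#'
#' @param densities output of [estimate_sad()] (all seasons stacked).
#' @param rule one of `"mean"`, `"max"`, `"none"`.
#' @return data.frame `transect_id`, `species`, `sad`, `x`, `y` (plus
#'   `season` when `rule = "none"`).
#' @export
seasonal_merge <- function(densities, rule = c("mean", "max", "none")) {
  rule <- match.arg(rule)
  if (rule == "none") return(densities)
  agg <- switch(rule, mean = mean, max = max)
  out <- list()
  for (sp in unique(densities$species)) {
    d <- densities[densities$species == sp, , drop = FALSE]
    by_id <- split(d, d$transect_id)
    merged <- lapply(by_id, function(g) {
      if (nrow(g) > 1 && max(stats::dist(cbind(g$x, g$y))) > 1e-6)
        stop("mismatched locations for transect ", g$transect_id[1])
      data.frame(transect_id = g$transect_id[1], species = sp,
                 sad = agg(g$sad), x = g$x[1], y = g$y[1],
                 stringsAsFactors = FALSE)
    })
    out[[sp]] <- do.call(rbind, merged)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
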