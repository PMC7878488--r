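#' Land-parcel set
#'
#' Parcels are the grazing-management accounting units: simple polygons that
#' tile the county extent exactly (union = extent, pairwise-disjoint
#' interiors). A `parcel_set` stores one closed ring per parcel in projected
#' km coordinates.
#'
#' @param ids integer parcel identifiers.
#' @param rings list of closed two-column matrices (x, y), one per parcel,
#'   first vertex repeated last.
#' @param properties optional data.frame of per-parcel attributes.
#' @return a `parcel_set` object.
#' @export
parcel_set <- function(ids, rings, properties = NULL) {
  ids <- as.integer(ids)
  if (length(ids) != length(rings)) stop("ids and rings differ in length")
  ok <- vapply(rings, function(r) is.matrix(r) && ncol(r) == 2 && nrow(r) >= 4 &&
                 all(r[1, ] == r[nrow(r), ]), logical(1))
  if (!all(ok)) stop("each ring must be a closed 2-column matrix")
  structure(list(id = ids, rings = rings, properties = properties),
            class = "parcel_set")
}

#' @export
print.parcel_set <- function(x, ...) {
  a <- parcel_areas(x)
  cat(sprintf("parcel_set: %d parcels, total area %.6g km2 (min %.4g, max %.4g)\n",
              length(x$id), sum(a), min(a), max(a)))
  invisible(x)
}

#' @export
length.parcel_set <- function(x) length(x$id)

shoelace <- function(ring) {
  n <- nrow(ring)
  x <- ring[-n, 1]; y <- ring[-n, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Parcel areas by the shoelace formula
#'
#' @param parcels a [parcel_set()].
#' @return numeric vector of areas (km^2), in parcel order.
#' @export
parcel_areas <- function(parcels) vapply(parcels$rings, shoelace, numeric(1))

# Even-odd ray casting; points exactly on an edge are resolved by the
# half-open rule below, which is consistent for grid-aligned tilings because
# cell centres never lie on parcel boundaries there.
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Assign grid cells to parcels by cell-centre containment
#'
#' Each cell belongs to the parcel containing its centre; with parcels that
#' tile the extent and grid-aligned boundaries this assignment is exact and
#' every cell lands in exactly one parcel.
#'
#' @param parcels a [parcel_set()].
#' @param grid a [county_grid()].
#' @return integer vector of parcel ids per cell (storage order); `NA` where
#'   no parcel contains the cell centre.
#' @export
parcel_of_cell <- function(parcels, grid) {
  ctr <- grid_centers(grid)
  out <- rep(NA_integer_, nrow(ctr))
  for (k in seq_along(parcels$id)) {
    hit <- is.na(out) & point_in_ring(ctr$x, ctr$y, parcels$rings[[k]])
    out[hit] <- parcels$id[k]
  }
  out
}

# ---- GeoJSON interchange ---------------------------------------------------

#' Write parcels as GeoJSON
#'
#' One Feature per parcel with a `parcel_id` property (plus any columns of
#' `properties`), geometry type Polygon, coordinates in the package's
#' projected km system.
#'
#' @param parcels a [parcel_set()].
#' @param path output file path.
#' @param properties optional data.frame of extra per-parcel properties
#'   (overrides any stored in the object).
#' @return `path`, invisibly.
#' @export
write_parcels_geojson <- function(parcels, path, properties = NULL) {
  props <- if (!is.null(properties)) properties else parcels$properties
  features <- lapply(seq_along(parcels$id), function(k) {
    p <- list(parcel_id = parcels$id[k])
    if (!is.null(props)) for (nm in names(props)) p[[nm]] <- props[[nm]][k]
    ring <- parcels$rings[[k]]
    coords <- lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
    list(type = "Feature", properties = p,
         geometry = list(type = "Polygon", coordinates = list(coords)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Read parcels from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of Polygon features carrying a
#'   `parcel_id` property.
#' @return a [parcel_set()]; extra properties are kept in `$properties`.
#' @export
read_parcels_geojson <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$features)) stop("not a FeatureCollection: ", path)
  ids <- integer(0); rings <- list(); props <- list()
  for (f in fc$features) {
    if (f$geometry$type != "Polygon") stop("unsupported geometry: ", f$geometry$type)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], unlist))
    ids <- c(ids, as.integer(f$properties$parcel_id))
    rings <- c(rings, list(ring))
    props <- c(props, list(f$properties))
  }
  extra <- unique(unlist(lapply(props, names)))
  extra <- setdiff(extra, "parcel_id")
  pdf <- NULL
  if (length(extra)) {
    pdf <- as.data.frame(lapply(extra, function(nm)
      vapply(props, function(p) if (is.null(p[[nm]])) NA_real_ else as.numeric(p[[nm]]),
             numeric(1))))
    names(pdf) <- extra
  }
  parcel_set(ids, rings, properties = pdf)
}
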