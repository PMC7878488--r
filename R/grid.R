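#' Regular analysis grid in projected planar coordinates
#'
#' All surfaces in rangecap live on one shared regular grid in projected
#' planar coordinates measured in kilometres. Cells are registered at their
#' centres, stored row-major from the north-west corner (row 1 is the
#' northernmost row), matching the convention of GIS raster formats.
#'
#' @param xmin,ymin south-west corner of the extent (km).
#' @param xmax,ymax north-east corner of the extent (km).
#' @param cellsize cell edge length (km); the extent must be an integer
#'   number of cells in each direction.
#' @return an object of class `county_grid` with fields `nrow`, `ncol`,
#'   `xmin`, `ymin`, `xmax`, `ymax`, `cellsize` and `crs` (a free-text tag,
#'   `"local-km"` by default).
#' @examples
#' g <- county_grid(0, 0, 160, 160, cellsize = 5)
#' g$nrow * g$ncol   # 1024 cells
#' @export
county_grid <- function(xmin, ymin, xmax, ymax, cellsize = 5) {
  if (!is.finite(xmin) || !is.finite(ymin) || !is.finite(xmax) ||
      !is.finite(ymax) || xmax <= xmin || ymax <= ymin)
    stop("degenerate extent: require xmax > xmin and ymax > ymin")
  if (cellsize <= 0) stop("cellsize must be > 0")
  nx <- (xmax - xmin) / cellsize
  ny <- (ymax - ymin) / cellsize
  if (abs(nx - round(nx)) > 1e-8 || abs(ny - round(ny)) > 1e-8)
    stop("extent is not an integer number of cells")
  structure(list(
    nrow = as.integer(round(ny)), ncol = as.integer(round(nx)),
    xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax,
    cellsize = cellsize, crs = "local-km"
  ), class = "county_grid")
}

#' @export
print.county_grid <- function(x, ...) {
  cat(sprintf("county_grid: %d x %d cells of %g km, extent [%g,%g] x [%g,%g] km (%s)\n",
              x$nrow, x$ncol, x$cellsize, x$xmin, x$xmax, x$ymin, x$ymax, x$crs))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("nrow", "ncol", "xmin", "ymin", "cellsize")],
                   unclass(b)[c("nrow", "ncol", "xmin", "ymin", "cellsize")],
                   tolerance = 1e-9))
}

stop_if_grid_mismatch <- function(a, b, what = "rasters") {
  if (!grid_equal(a, b)) stop(sprintf("%s do not share the same grid", what))
  invisible(TRUE)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid a [county_grid()].
#' @return a data.frame with one row per cell in storage order (row-major
#'   from the north-west corner): `cell`, `row`, `col`, `x`, `y`.
#' @export
grid_centers <- function(grid) {
  rows <- rep(seq_len(grid$nrow), each = grid$ncol)
  cols <- rep(seq_len(grid$ncol), times = grid$nrow)
  data.frame(
    cell = seq_len(grid$nrow * grid$ncol), row = rows, col = cols,
    x = grid$xmin + (cols - 0.5) * grid$cellsize,
    y = grid$ymax - (rows - 0.5) * grid$cellsize
  )
}

#' Locate points on a grid
#'
#' @param grid a [county_grid()].
#' @param x,y point coordinates (km).
#' @return integer cell indices in storage order; `NA` for points outside
#'   the extent. Points on an interior cell edge belong to the cell to the
#'   north-west of the edge, so every in-extent point maps to exactly one cell.
#' @export
cell_at <- function(grid, x, y) {
  col <- pmin(floor((x - grid$xmin) / grid$cellsize) + 1L, grid$ncol)
  row <- pmin(floor((grid$ymax - y) / grid$cellsize) + 1L, grid$nrow)
  out <- (row - 1L) * grid$ncol + col
  out[x < grid$xmin | x > grid$xmax | y < grid$ymin | y > grid$ymax] <- NA_integer_
  as.integer(out)
}

#' Gridded surface (single-band raster)
#'
#' A `grid_raster` couples a numeric vector of cell values (storage order of
#' [grid_centers()]) with its [county_grid()]. `NA` encodes nodata.
#'
#' @param grid a [county_grid()].
#' @param values numeric vector of length `nrow * ncol`, or a single value
#'   to be recycled.
#' @param name band name used in printing and file output.
#' @return a `grid_raster` object.
#' @export
grid_raster <- function(grid, values = NA_real_, name = "band1") {
  n <- grid$nrow * grid$ncol
  if (length(values) == 1L) values <- rep(as.numeric(values), n)
  if (length(values) != n)
    stop(sprintf("values has length %d; grid has %d cells", length(values), n))
  structure(list(grid = grid, values = as.numeric(values), name = name),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("grid_raster '%s' (%d x %d): min %.4g, mean %.4g, max %.4g, %d nodata\n",
              x$name, x$grid$nrow, x$grid$ncol,
              if (length(v)) min(v) else NA, if (length(v)) mean(v) else NA,
              if (length(v)) max(v) else NA, sum(!is.finite(x$values))))
  invisible(x)
}

#' Matrix view of a grid_raster
#'
#' @param x a [grid_raster()].
#' @param ... unused.
#' @return a `nrow x ncol` matrix, row 1 = northernmost row.
#' @export
as.matrix.grid_raster <- function(x, ...) {
  matrix(x$values, nrow = x$grid$nrow, ncol = x$grid$ncol, byrow = TRUE)
}

#' Integrate a surface over its extent
#'
#' @param x a [grid_raster()].
#' @param na.rm drop nodata cells before summing.
#' @return sum of cell values times cell area (value-unit x km^2).
#' @export
raster_integral <- function(x, na.rm = TRUE) {
  sum(x$values, na.rm = na.rm) * x$grid$cellsize^2
}

# ---- ESRI ASCII grid I/O ---------------------------------------------------
# Plain-text single-band raster interchange; nodata is -9999 on disk.

#' Write a surface as an ESRI ASCII grid
#'
#' The ESRI ASCII grid (`.asc`) format is a plain-text single-band raster:
#' a six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
#' NODATA_value) followed by rows of cell values from north to south. It is
#' readable by all mainstream GIS software.
#'
#' @param x a [grid_raster()].
#' @param path output file path.
#' @param nodata value written for `NA` cells (default -9999).
#' @param digits significant digits for cell values.
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, nodata = -9999, digits = 10) {
  g <- x$grid
  header <- c(
    sprintf("ncols %d", g$ncol), sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin), sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize), sprintf("NODATA_value %g", nodata)
  )
  m <- as.matrix(x)
  m[!is.finite(m)] <- nodata
  rows <- apply(m, 1L, function(r) paste(formatC(r, digits = digits, format = "g"),
                                         collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_asc()] or any GIS exporting `.asc`.
#' @param name band name to attach.
#' @return a [grid_raster()]; nodata cells become `NA`.
#' @export
read_asc <- function(path, name = sub("\\.asc$", "", basename(path))) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed .asc header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = numeric(), quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows)
    stop("cell count does not match header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals[vals == nodata] <- NA_real_
  g <- county_grid(hdr$xllcorner, hdr$yllcorner,
                   hdr$xllcorner + hdr$ncols * hdr$cellsize,
                   hdr$yllcorner + hdr$nrows * hdr$cellsize,
                   cellsize = hdr$cellsize)
  grid_raster(g, vals, name = name)
}
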