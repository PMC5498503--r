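#' Grid geometry for regular latitude-longitude rasters
#'
#' Describes a regular grid of square cells in geographic coordinates.  Row 1
#' is the northernmost row (the usual raster convention); columns run west to
#' east.  All layered objects in the package (climate normals, anomaly grids,
#' bioclim grids, probability surfaces) share one `grid_geometry`.
#'
#' @param nrow,ncol Grid dimensions (cells); must be >= 1.
#' @param xmin,ymin Coordinates of the lower-left corner, decimal degrees.
#' @param cellsize Cell edge length, decimal degrees.
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(nrow, ncol, xmin = -120, ymin = 40, cellsize = 0.1) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  if (is.na(nrow) || is.na(ncol) || nrow < 1L || ncol < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("cellsize must be positive", call. = FALSE)
  structure(
    list(nrow = nrow, ncol = ncol, xmin = xmin, ymin = ymin,
         cellsize = cellsize),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d cells, cellsize %g deg\n",
              x$nrow, x$ncol, x$cellsize))
  cat(sprintf("  x: [%g, %g]  y: [%g, %g]\n", x$xmin, xmax(x), x$ymin, ymax(x)))
  invisible(x)
}

xmax <- function(geom) geom$xmin + geom$ncol * geom$cellsize
ymax <- function(geom) geom$ymin + geom$nrow * geom$cellsize

#' Test whether two geometries are identical
#'
#' @param a,b `grid_geometry` objects (or objects carrying a `$geom`).
#' @param tol Numerical tolerance on origin and cell size.
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-9) {
  a <- as_geometry(a); b <- as_geometry(b)
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$xmin - b$xmin) < tol && abs(a$ymin - b$ymin) < tol &&
    abs(a$cellsize - b$cellsize) < tol
}

as_geometry <- function(x) {
  if (inherits(x, "grid_geometry")) return(x)
  if (!is.null(x$geom)) return(x$geom)
  stop("cannot extract a grid_geometry from this object", call. = FALSE)
}

#' Single-variable georeferenced raster
#'
#' A matrix of cell values plus a [grid_geometry()].  `NA` marks nodata.
#'
#' @param values Numeric matrix, `geom$nrow` x `geom$ncol`.
#' @param geom A [grid_geometry()].
#' @param name Optional variable name.
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, geom, name = NULL) {
  stopifnot(inherits(geom, "grid_geometry"))
  values <- as.matrix(values)
  if (nrow(values) != geom$nrow || ncol(values) != geom$ncol)
    stop("values matrix does not match geometry", call. = FALSE)
  structure(list(values = values, geom = geom, name = name),
            class = "raster_grid")
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_grid%s> %d x %d, %d nodata cells\n",
              if (is.null(x$name)) "" else paste0(" ", x$name),
              x$geom$nrow, x$geom$ncol, sum(is.na(x$values))))
  if (length(v))
    cat(sprintf("  range [%g, %g], mean %g\n", min(v), max(v), mean(v)))
  invisible(x)
}

#' Cell-centre coordinates
#'
#' @param geom A [grid_geometry()].
#' @param row,col Cell indices (vectors of equal length, recycled).
#' @return Data frame with columns `lon`, `lat`.
#' @export
cell_centers <- function(geom, row, col) {
  data.frame(lon = geom$xmin + (col - 0.5) * geom$cellsize,
             lat = ymax(geom) - (row - 0.5) * geom$cellsize)
}

#' Cell indices containing given coordinates
#'
#' Points outside the grid extent get `NA` indices.
#'
#' @param geom A [grid_geometry()].
#' @param lon,lat Coordinate vectors.
#' @return Data frame with columns `row`, `col` (`NA` outside the extent).
#' @export
cell_at_xy <- function(geom, lon, lat) {
  col <- floor((lon - geom$xmin) / geom$cellsize) + 1
  row <- floor((ymax(geom) - lat) / geom$cellsize) + 1
  # points exactly on the east/north edge belong to the last cell
  col[lon == xmax(geom)] <- geom$ncol
  row[lat == geom$ymin] <- geom$nrow
  bad <- !is.finite(col) | !is.finite(row) |
    col < 1 | col > geom$ncol | row < 1 | row > geom$nrow
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at coordinates
#'
#' @param grid A [raster_grid()].
#' @param lon,lat Coordinate vectors.
#' @return Numeric vector; `NA` for points outside the extent or on nodata.
#' @export
values_at_xy <- function(grid, lon, lat) {
  idx <- cell_at_xy(grid$geom, lon, lat)
  out <- rep(NA_real_, length(lon))
  ok <- !is.na(idx$row)
  out[ok] <- grid$values[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text single-band raster interchange format (`.asc`), readable by
#' standard GIS software.
#'
#' @param grid A [raster_grid()].
#' @param path Output file path.
#' @param nodata Value written for `NA` cells.
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  g <- grid$geom
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", g$ymin),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %g", nodata)), con)
  v <- grid$values
  v[is.na(v)] <- nodata
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @param name Optional variable name attached to the result.
#' @return A [raster_grid()].
#' @export
read_ascii_grid <- function(path, name = NULL) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  geom <- grid_geometry(val["nrows"], val["ncols"],
                        xmin = val["xllcorner"], ymin = val["yllcorner"],
                        cellsize = val["cellsize"])
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val["nodata_value"]] <- NA_real_
  raster_grid(v, geom, name = name)
}
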