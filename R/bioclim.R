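#' @title Bioclimatic variables from monthly climate normals
#' @description
#' Derivation of the biologically relevant climate variables used throughout
#' the package from 36 monthly normals (12 Tmin, 12 Tmax, 12 precipitation):
#'
#' * `DD5`  growing degree-days above 5 degrees C
#' * `DD0`  chilling degree-days below 0 degrees C
#' * `MWMT` mean warmest month temperature (degrees C)
#' * `MCMT` mean coldest month temperature (degrees C)
#' * `TD`   continentality, MWMT - MCMT (degrees C)
#' * `MAT`  mean annual temperature (degrees C, month-length weighted)
#' * `MAP`  mean annual precipitation (mm)
#' * `MSP`  April-September growing-season precipitation (mm)
#' * `MWP`  November-February winter precipitation (mm)
#' * `PAS`  precipitation as snow (mm; months with mean temperature <= 0)
#' * `NFFD` number of frost-free days (days with interpolated Tmin > 0)
#'
#' Degree-days and frost-free days use a 365-day non-leap calendar: monthly
#' values are interpolated piecewise-linearly between month midpoints
#' (wrapping December to January) to a daily series, which is then truncated
#' and summed.
#' @name bioclim
NULL

#' Month lengths of the 365-day working calendar
#' @export
MONTH_LENGTHS <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

BIOCLIM_VARS <- c("DD5", "DD0", "MWMT", "MCMT", "TD", "MAT",
                  "MAP", "MSP", "MWP", "PAS", "NFFD")

# 365 x 12 matrix of interpolation weights: daily[d] = W[d, ] %*% monthly.
# Each day lies between two month midpoints (December wraps to January);
# weights are the piecewise-linear interpolation coefficients.  Because the
# weights do not depend on the data, whole grids interpolate as one matrix
# product.
daily_weights <- function(month_lengths = MONTH_LENGTHS) {
  stopifnot(length(month_lengths) == 12)
  starts <- cumsum(c(1, month_lengths[-12]))
  mids <- starts + (month_lengths - 1) / 2
  ndays <- sum(month_lengths)
  # extended knots: December of the previous year, Jan..Dec, January of next
  xs <- c(mids[12] - ndays, mids, mids[1] + ndays)
  mo <- c(12L, 1:12, 1L)
  W <- matrix(0, ndays, 12)
  seg <- findInterval(seq_len(ndays), xs, rightmost.closed = FALSE)
  for (d in seq_len(ndays)) {
    i <- seg[d]
    w <- (d - xs[i]) / (xs[i + 1] - xs[i])
    W[d, mo[i]] <- W[d, mo[i]] + (1 - w)
    W[d, mo[i + 1]] <- W[d, mo[i + 1]] + w
  }
  W
}

.W365 <- daily_weights()

#' Interpolate 12 monthly values to a 365-day series
#'
#' Piecewise-linear interpolation between month midpoints, wrapping December
#' to January, on the fixed 365-day calendar.  A constant monthly series maps
#' to a constant daily series; monthly means of the interpolant reproduce the
#' inputs up to the curvature of the series.
#'
#' @param values 12 monthly values.
#' @param month_lengths Days per month (default [MONTH_LENGTHS]).
#' @return Numeric vector of length `sum(month_lengths)` (365 by default).
#' @export
monthly_to_daily <- function(values, month_lengths = MONTH_LENGTHS) {
  if (length(values) != 12) stop("need 12 monthly values", call. = FALSE)
  W <- if (identical(month_lengths, MONTH_LENGTHS)) .W365
       else daily_weights(month_lengths)
  as.numeric(W %*% values)
}

#' Degree-days above or below a base temperature
#'
#' Interpolates the monthly mean temperatures to daily values and sums the
#' daily truncated excess `max(0, T_d - base)` (direction `"above"`) or
#' deficit `max(0, base - T_d)` (direction `"below"`).
#'
#' @param tmean 12 monthly mean temperatures (degrees C).
#' @param base Base temperature (degrees C).
#' @param direction `"above"` (growing) or `"below"` (chilling).
#' @return Degree-days (non-negative scalar).
#' @export
degree_days <- function(tmean, base, direction = c("above", "below")) {
  direction <- match.arg(direction)
  daily <- monthly_to_daily(tmean)
  if (direction == "above") sum(pmax(daily - base, 0))
  else sum(pmax(base - daily, 0))
}

#' Annual temperature summaries
#'
#' @param tmean 12 monthly mean temperatures (degrees C).
#' @return Named vector: `MWMT` (warmest month mean), `MCMT` (coldest month
#'   mean), `MAT` (month-length-weighted annual mean), `TD` (continentality,
#'   `MWMT - MCMT`).
#' @export
temperature_summaries <- function(tmean) {
  if (length(tmean) != 12) stop("need 12 monthly values", call. = FALSE)
  mwmt <- max(tmean); mcmt <- min(tmean)
  c(MWMT = mwmt, MCMT = mcmt,
    MAT = sum(MONTH_LENGTHS * tmean) / sum(MONTH_LENGTHS),
    TD = mwmt - mcmt)
}

#' Annual and seasonal precipitation sums
#'
#' @param precip 12 monthly precipitation normals (mm), non-negative.
#' @return Named vector: `MAP` (annual), `MSP` (April-September), `MWP`
#'   (November-February, wrapping the year boundary).
#' @export
precipitation_summaries <- function(precip) {
  if (length(precip) != 12) stop("need 12 monthly values", call. = FALSE)
  if (any(precip < 0)) stop("precipitation must be non-negative", call. = FALSE)
  c(MAP = sum(precip), MSP = sum(precip[4:9]),
    MWP = sum(precip[c(11, 12, 1, 2)]))
}

#' Frost-free days and precipitation as snow
#'
#' `NFFD` counts days of the interpolated daily Tmin series strictly above
#' 0 degrees C.  `PAS` sums precipitation of months whose mean temperature is
#' at or below 0 degrees C.
#'
#' @param tmin 12 monthly minimum temperatures (degrees C).
#' @param tmean 12 monthly mean temperatures (degrees C).
#' @param precip 12 monthly precipitation normals (mm).
#' @return Named vector `c(NFFD = , PAS = )`.
#' @export
frost_and_snow <- function(tmin, tmean, precip) {
  stopifnot(length(tmin) == 12, length(tmean) == 12, length(precip) == 12)
  c(NFFD = sum(monthly_to_daily(tmin) > 0),
    PAS = sum(precip[tmean <= 0]))
}

#' Full bioclimatic vector for one location
#'
#' @param tmin,tmax,precip Monthly normals (12 values each).
#' @return Named vector of the 11 bioclim variables (see [bioclim]).
#' @export
bioclim_point <- function(tmin, tmax, precip) {
  m <- bioclim_from_matrices(matrix(tmin, 1), matrix(tmax, 1), matrix(precip, 1))
  stats::setNames(as.numeric(m[1, ]), colnames(m))
}

# Vectorised core: rows are locations, columns months.  Returns an
# n x 11 matrix with BIOCLIM_VARS columns.  Rows with any NA input give all
# NA outputs (nodata propagation).
bioclim_from_matrices <- function(tmin, tmax, prec) {
  n <- nrow(tmin)
  tmean <- (tmin + tmax) / 2
  out <- matrix(NA_real_, n, length(BIOCLIM_VARS),
                dimnames = list(NULL, BIOCLIM_VARS))
  ok <- stats::complete.cases(tmin) & stats::complete.cases(tmax) &
    stats::complete.cases(prec)
  if (!any(ok)) return(out)
  tm <- tmean[ok, , drop = FALSE]
  tn <- tmin[ok, , drop = FALSE]
  pr <- prec[ok, , drop = FALSE]

  daily_tm <- tm %*% t(.W365)
  daily_tn <- tn %*% t(.W365)
  out[ok, "DD5"] <- rowSums(pmax(daily_tm - 5, 0))
  out[ok, "DD0"] <- rowSums(pmax(-daily_tm, 0))
  out[ok, "MWMT"] <- apply(tm, 1, max)
  out[ok, "MCMT"] <- apply(tm, 1, min)
  out[ok, "TD"] <- out[ok, "MWMT"] - out[ok, "MCMT"]
  out[ok, "MAT"] <- as.numeric(tm %*% (MONTH_LENGTHS / 365))
  out[ok, "MAP"] <- rowSums(pr)
  out[ok, "MSP"] <- rowSums(pr[, 4:9, drop = FALSE])
  out[ok, "MWP"] <- rowSums(pr[, c(11, 12, 1, 2), drop = FALSE])
  out[ok, "PAS"] <- rowSums(pr * (tm <= 0))
  out[ok, "NFFD"] <- rowSums(daily_tn > 0)
  out
}

#' Derive the bioclim grid from monthly climate normals
#'
#' Applies the scalar derivations of [bioclim] to every cell of a 36-layer
#' [make_climate_grid()] object (or any `climate_normals`).  Nodata in any
#' input layer propagates to all output layers at that cell; the grid
#' geometry is preserved.
#'
#' @param normals A `climate_normals` object (`tmin`, `tmax`, `prec` arrays
#'   of dimension `nrow x ncol x 12` plus a `geom`).
#' @return An object of class `bioclim_grid`: list with `values` (array
#'   `nrow x ncol x 11`, third dimension named by variable) and `geom`.
#' @export
derive_bioclim <- function(normals) {
  g <- normals$geom
  dims <- c(g$nrow, g$ncol, 12L)
  if (!identical(dim(normals$tmin), dims) ||
      !identical(dim(normals$tmax), dims) ||
      !identical(dim(normals$prec), dims))
    stop("input layers are not co-registered with the geometry", call. = FALSE)
  n <- g$nrow * g$ncol
  flat <- function(a) matrix(a, n, 12)   # cells in column-major cell order
  m <- bioclim_from_matrices(flat(normals$tmin), flat(normals$tmax),
                             flat(normals$prec))
  vals <- array(m, c(g$nrow, g$ncol, length(BIOCLIM_VARS)),
                dimnames = list(NULL, NULL, BIOCLIM_VARS))
  structure(list(values = vals, geom = g), class = "bioclim_grid")
}

#' @export
print.bioclim_grid <- function(x, ...) {
  cat(sprintf("<bioclim_grid> %d x %d cells, %d variables: %s\n",
              x$geom$nrow, x$geom$ncol, dim(x$values)[3],
              paste(dimnames(x$values)[[3]], collapse = " ")))
  invisible(x)
}

#' Extract one bioclim variable as a raster
#'
#' @param bioclim A [derive_bioclim()] result.
#' @param var Variable name (one of the 11 in [bioclim]).
#' @return A [raster_grid()].
#' @export
bioclim_layer <- function(bioclim, var) {
  if (!var %in% dimnames(bioclim$values)[[3]])
    stop(sprintf("unknown bioclim variable '%s'", var), call. = FALSE)
  raster_grid(bioclim$values[, , var], bioclim$geom, name = var)
}
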