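#' Bilinear interpolation of a coarse raster at arbitrary points
#'
#' Interpolates between cell centres; points in the half-cell margin between
#' the outermost centres and the grid edge are linearly extrapolated from the
#' nearest pair of centres, so planar fields are reproduced exactly
#' everywhere inside the grid bounds.  Points outside the bounds are an
#' error.
#'
#' @param values Matrix of cell values (row 1 = north).
#' @param geom The source [grid_geometry()].
#' @param lon,lat Target coordinate vectors.
#' @return Interpolated values.
#' @keywords internal
bilinear_at <- function(values, geom, lon, lat) {
  eps <- 1e-9
  if (any(lon < geom$xmin - eps | lon > xmax(geom) + eps |
          lat < geom$ymin - eps | lat > ymax(geom) + eps))
    stop("target extent lies outside the anomaly coverage", call. = FALSE)
  # fractional indices in cell-centre space
  fc <- (lon - geom$xmin) / geom$cellsize + 0.5
  fr <- (ymax(geom) - lat) / geom$cellsize + 0.5
  c0 <- pmin(pmax(floor(fc), 1), max(geom$ncol - 1, 1))
  r0 <- pmin(pmax(floor(fr), 1), max(geom$nrow - 1, 1))
  wc <- if (geom$ncol == 1) rep(0, length(fc)) else fc - c0
  wr <- if (geom$nrow == 1) rep(0, length(fr)) else fr - r0
  c1 <- pmin(c0 + 1, geom$ncol); r1 <- pmin(r0 + 1, geom$nrow)
  v00 <- values[cbind(r0, c0)]; v01 <- values[cbind(r0, c1)]
  v10 <- values[cbind(r1, c0)]; v11 <- values[cbind(r1, c1)]
  (1 - wr) * ((1 - wc) * v00 + wc * v01) + wr * ((1 - wc) * v10 + wc * v11)
}

#' Regrid an anomaly to a target geometry
#'
#' Bilinearly interpolates each of the 24 anomaly layers to the target cell
#' centres.  Constant fields map to constant fields and planar fields are
#' reproduced exactly.  If the geometries are already identical the input is
#' returned unchanged.
#'
#' @param anomaly An [anomaly_grid()].
#' @param geom Target [grid_geometry()]; its extent must be covered by the
#'   anomaly grid.
#' @return An [anomaly_grid()] at the target geometry.
#' @export
regrid_anomaly <- function(anomaly, geom) {
  stopifnot(inherits(anomaly, "anomaly_grid"), inherits(geom, "grid_geometry"))
  if (same_geometry(anomaly$geom, geom)) return(anomaly)
  ctr <- cell_centers(geom, rep(seq_len(geom$nrow), geom$ncol),
                      rep(seq_len(geom$ncol), each = geom$nrow))
  dt <- pf <- array(NA_real_, c(geom$nrow, geom$ncol, 12L))
  for (m in 1:12) {
    dt[, , m] <- matrix(bilinear_at(anomaly$dt[, , m], anomaly$geom,
                                    ctr$lon, ctr$lat), geom$nrow, geom$ncol)
    pf[, , m] <- matrix(bilinear_at(anomaly$p_factor[, , m], anomaly$geom,
                                    ctr$lon, ctr$lat), geom$nrow, geom$ncol)
  }
  pf[pf <= 0] <- .Machine$double.eps   # guard against extrapolation overshoot
  anomaly_grid(dt, pf, geom, period = anomaly$period)
}

#' Overlay climate anomalies on baseline normals (delta method)
#'
#' Applies a co-registered anomaly to baseline monthly normals: temperature
#' anomalies are additive on both Tmin and Tmax; precipitation anomalies are
#' multiplicative ratios (standard delta-method practice, which keeps
#' precipitation non-negative).  An additive precipitation mode clamped at
#' zero is available behind `precip_mode`.  Nodata in the baseline
#' propagates.  Feeding the result to [derive_bioclim()] yields the
#' palaeoclimate bioclim grid.
#'
#' @param baseline A `climate_normals` object.
#' @param anomaly An [anomaly_grid()] at the baseline geometry (use
#'   [regrid_anomaly()] first for coarse anomalies).
#' @param precip_mode `"multiplicative"` (default) or `"additive"` (anomaly
#'   `p_factor` interpreted as mm offsets, result clamped at 0).
#' @return A `climate_normals` object for the anomaly's period.
#' @export
apply_delta <- function(baseline, anomaly,
                        precip_mode = c("multiplicative", "additive")) {
  precip_mode <- match.arg(precip_mode)
  stopifnot(inherits(anomaly, "anomaly_grid"))
  if (!same_geometry(baseline$geom, anomaly$geom))
    stop("baseline and anomaly geometries differ; regrid the anomaly first",
         call. = FALSE)
  prec <- if (precip_mode == "multiplicative")
    baseline$prec * anomaly$p_factor
  else pmax(baseline$prec + anomaly$p_factor, 0)
  structure(list(tmin = baseline$tmin + anomaly$dt,
                 tmax = baseline$tmax + anomaly$dt,
                 prec = prec,
                 geom = baseline$geom,
                 config = baseline$config,
                 period = anomaly$period),
            class = "climate_normals")
}

#' Exact inverse of an anomaly
#'
#' Negates the temperature layers and reciprocates the precipitation
#' factors, so `apply_delta(apply_delta(x, a), inverse_anomaly(a))`
#' round-trips to the baseline up to floating point.
#'
#' @param anomaly An [anomaly_grid()].
#' @return An [anomaly_grid()].
#' @export
inverse_anomaly <- function(anomaly) {
  anomaly_grid(-anomaly$dt, 1 / anomaly$p_factor, anomaly$geom,
               period = paste0(anomaly$period, "-inverse"))
}
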