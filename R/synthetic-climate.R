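#' Configuration for synthetic climate-normal grids
#'
#' Defines a landscape whose monthly climate normals combine a smooth
#' north-south temperature gradient (cold in the north, row 1), a seasonal
#' temperature cycle peaking in July, a fixed diurnal range separating Tmax
#' from Tmin, and a seeded, spatially autocorrelated "elevation-like" noise
#' field.  Precipitation follows a 12-value monthly profile modulated by a
#' positive lognormal spatial field.
#'
#' @param grid_rows,grid_cols Grid dimensions in cells (>= 1).
#' @param cell_size Cell edge, decimal degrees.
#' @param lapse Latitudinal temperature lapse, degrees C per row (southward
#'   warming per row).
#' @param noise_amplitude Standard deviation (degrees C) of the correlated
#'   temperature noise field.
#' @param temp_amplitude Half-amplitude (degrees C) of the seasonal cycle of
#'   monthly mean temperature.
#' @param mean_temp Annual mean temperature (degrees C) at the grid's central
#'   row, before noise.
#' @param diurnal_range Constant Tmax - Tmin separation, degrees C (> 0 keeps
#'   Tmax >= Tmin everywhere by construction).
#' @param precip_profile 12 non-negative monthly precipitation normals (mm).
#' @param precip_noise_sd Log-scale standard deviation of the multiplicative
#'   precipitation field (0 disables spatial precipitation variation).
#' @param noise_correlation Correlation length of the spatial noise, in cells
#'   (Gaussian smoothing kernel standard deviation).
#' @param xmin,ymin Lower-left corner of the grid, decimal degrees.
#' @param seed Integer seed; mandatory.  Identical config + seed reproduces
#'   identical grids bit for bit.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_rows = 50, grid_cols = 50, cell_size = 0.1,
                             lapse = 0.5, noise_amplitude = 1,
                             temp_amplitude = 15, mean_temp = 5,
                             diurnal_range = 8,
                             precip_profile = c(30, 25, 30, 35, 45, 60,
                                                70, 65, 45, 35, 32, 30),
                             precip_noise_sd = 0.3, noise_correlation = 3,
                             xmin = -120, ymin = 40, seed) {
  if (missing(seed) || is.null(seed))
    stop("seed is mandatory in a synthetic_config", call. = FALSE)
  if (grid_rows < 1 || grid_cols < 1)
    stop("grid dimensions must be >= 1", call. = FALSE)
  if (length(precip_profile) != 12 || any(precip_profile < 0))
    stop("precip_profile must be 12 non-negative values", call. = FALSE)
  if (diurnal_range < 0)
    stop("diurnal_range must be non-negative", call. = FALSE)
  structure(
    list(grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
         cell_size = cell_size, lapse = lapse,
         noise_amplitude = noise_amplitude, temp_amplitude = temp_amplitude,
         mean_temp = mean_temp, diurnal_range = diurnal_range,
         precip_profile = as.numeric(precip_profile),
         precip_noise_sd = precip_noise_sd,
         noise_correlation = noise_correlation,
         xmin = xmin, ymin = ymin, seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Read a synthetic configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; `seed` is mandatory.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$seed))
    stop("config file must set a seed", call. = FALSE)
  do.call(synthetic_config, vals)
}

geom_of_config <- function(config) {
  grid_geometry(config$grid_rows, config$grid_cols,
                xmin = config$xmin, ymin = config$ymin,
                cellsize = config$cell_size)
}

# Spatially autocorrelated standard field: seeded white noise smoothed with a
# separable Gaussian kernel (circular convolution, so the field is
# stationary), scaled so each cell has unit variance.  corlen 0 returns the
# raw white noise.
smooth_noise_field <- function(nrow, ncol, corlen) {
  z <- matrix(stats::rnorm(nrow * ncol), nrow, ncol)
  if (corlen <= 0) return(z)
  half <- max(1L, ceiling(3 * corlen))
  k <- stats::dnorm(seq(-half, half), sd = corlen)
  k <- k / sqrt(sum(k^2))          # unit variance after each 1-D pass
  conv1 <- function(v) {
    n <- length(v)
    idx <- outer(seq_len(n), seq(-half, half), function(i, o) ((i + o - 1) %% n) + 1)
    as.numeric(matrix(v[idx], n) %*% k)
  }
  z <- apply(z, 2, conv1)          # along rows (columns of matrix)
  t(apply(z, 1, conv1))            # along columns
}

#' Generate synthetic monthly climate normals
#'
#' Produces the 36 co-registered monthly layers (12 Tmin, 12 Tmax, 12
#' precipitation) the rest of the pipeline consumes, from a
#' [synthetic_config()].  The monthly mean temperature of cell (r, c) in
#' month m is
#' `mean_temp + lapse * (r - (nrow+1)/2) + temp_amplitude * cos(2*pi*(m-7)/12)
#'  + noise(r, c)`, with Tmin/Tmax offset by half the diurnal range, so
#' `Tmax >= Tmin` holds cellwise by construction.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `climate_normals`: a list with `tmin`, `tmax`,
#'   `prec` (arrays `nrow x ncol x 12`), `geom`, and the generating `config`.
#' @export
make_climate_grid <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  geom <- geom_of_config(config)
  nr <- geom$nrow; nc <- geom$ncol
  set.seed(config$seed)
  tnoise <- config$noise_amplitude *
    smooth_noise_field(nr, nc, config$noise_correlation)
  pnoise <- smooth_noise_field(nr, nc, config$noise_correlation)

  ramp <- config$mean_temp + config$lapse * (seq_len(nr) - (nr + 1) / 2)
  base <- matrix(ramp, nr, nc) + tnoise
  cyc <- config$temp_amplitude * cos(2 * pi * ((1:12) - 7) / 12)

  tmin <- tmax <- prec <- array(NA_real_, c(nr, nc, 12))
  pfield <- if (config$precip_noise_sd > 0)
    exp(config$precip_noise_sd * pnoise - config$precip_noise_sd^2 / 2)
  else matrix(1, nr, nc)
  for (m in 1:12) {
    tm <- base + cyc[m]
    tmin[, , m] <- tm - config$diurnal_range / 2
    tmax[, , m] <- tm + config$diurnal_range / 2
    prec[, , m] <- config$precip_profile[m] * pfield
  }
  structure(list(tmin = tmin, tmax = tmax, prec = prec,
                 geom = geom, config = config),
            class = "climate_normals")
}

#' @export
print.climate_normals <- function(x, ...) {
  cat(sprintf("<climate_normals> %d x %d cells, 36 monthly layers\n",
              x$geom$nrow, x$geom$ncol))
  invisible(x)
}

# Period presets: mean annual cooling (degrees C, additive) and mean
# precipitation ratio (multiplicative) relative to the modern baseline.
# Magnitudes follow the usual late-Pleistocene/Holocene anomaly ordering:
# strongest cooling and drying at the Last Glacial Maximum (21k), relaxing
# toward the mid-Holocene (6k).
PERIOD_PRESETS <- list(
  "modern" = list(dt = 0,    pf = 1.00),
  "6k"     = list(dt = -1.5, pf = 0.95),
  "11k"    = list(dt = -3,   pf = 0.90),
  "14k"    = list(dt = -5,   pf = 0.85),
  "21k"    = list(dt = -8,   pf = 0.75))

#' Construct an anomaly grid from layer arrays
#'
#' Low-level constructor used by [make_anomaly_grid()] and by code that needs
#' a bespoke anomaly (e.g. an exact inverse for round-trip checks).
#'
#' @param dt Array `nrow x ncol x 12` of additive temperature anomalies
#'   (degrees C).
#' @param p_factor Array `nrow x ncol x 12` of multiplicative precipitation
#'   factors; must be strictly positive.
#' @param geom The anomaly grid's [grid_geometry()].
#' @param period Period tag (e.g. `"21k"`).
#' @return An object of class `anomaly_grid`.
#' @export
anomaly_grid <- function(dt, p_factor, geom, period = "custom") {
  stopifnot(inherits(geom, "grid_geometry"),
            identical(dim(dt), c(geom$nrow, geom$ncol, 12L)),
            identical(dim(p_factor), c(geom$nrow, geom$ncol, 12L)))
  if (any(p_factor <= 0, na.rm = TRUE))
    stop("precipitation factors must be strictly positive", call. = FALSE)
  structure(list(dt = dt, p_factor = p_factor, geom = geom, period = period),
            class = "anomaly_grid")
}

#' @export
print.anomaly_grid <- function(x, ...) {
  cat(sprintf("<anomaly_grid> period %s, %d x %d cells, mean dT %.2f C, mean P factor %.2f\n",
              x$period, x$geom$nrow, x$geom$ncol,
              mean(x$dt), mean(x$p_factor)))
  invisible(x)
}

#' Generate a synthetic coarse-resolution palaeoclimate anomaly grid
#'
#' Emulates GCM output for a named period: additive monthly temperature
#' anomalies and multiplicative monthly precipitation factors on a grid
#' `coarsening_factor` times coarser than the baseline, covering the full
#' baseline extent.  Cooling is modulated seasonally (stronger in winter) and
#' perturbed by a seeded correlated spatial field; precipitation factors are
#' lognormal around the period mean, hence strictly positive.
#'
#' @param config The [synthetic_config()] of the baseline grid.
#' @param period One of `"modern"`, `"6k"`, `"11k"`, `"14k"`, `"21k"`
#'   (thousands of years before present), or `"custom"` with explicit means.
#' @param coarsening_factor Integer >= 1; ratio of anomaly to baseline cell
#'   size.
#' @param dt_mean,p_factor_mean Override the period-preset mean temperature
#'   anomaly (degrees C) and precipitation factor.
#' @param dt_sd Cellwise standard deviation of the temperature-anomaly noise
#'   field (degrees C).
#' @param pf_sd Log-scale standard deviation of the precipitation-factor
#'   field.
#' @param seasonal_amplitude Relative winter amplification of the temperature
#'   anomaly (0 = uniform across months).
#' @return An [anomaly_grid()].
#' @export
make_anomaly_grid <- function(config, period, coarsening_factor = 4,
                              dt_mean = NULL, p_factor_mean = NULL,
                              dt_sd = 0.5, pf_sd = 0.05,
                              seasonal_amplitude = 0.25) {
  stopifnot(inherits(config, "synthetic_config"))
  if (coarsening_factor < 1)
    stop("coarsening_factor must be >= 1", call. = FALSE)
  known <- period %in% names(PERIOD_PRESETS)
  if (!known && (is.null(dt_mean) || is.null(p_factor_mean)))
    stop(sprintf("unknown period tag '%s' (and no explicit anomaly means given)",
                 period), call. = FALSE)
  preset <- if (known) PERIOD_PRESETS[[period]] else list(dt = NA, pf = NA)
  if (is.null(dt_mean)) dt_mean <- preset$dt
  if (is.null(p_factor_mean)) p_factor_mean <- preset$pf
  if (p_factor_mean <= 0)
    stop("p_factor_mean must be strictly positive", call. = FALSE)

  f <- as.integer(coarsening_factor)
  nr <- as.integer(ceiling(config$grid_rows / f))
  nc <- as.integer(ceiling(config$grid_cols / f))
  # coarse grid shares the baseline's lower-left x corner and upper y edge,
  # so its extent always covers the baseline extent
  base_ymax <- config$ymin + config$grid_rows * config$cell_size
  cs <- config$cell_size * f
  geom <- grid_geometry(nr, nc, xmin = config$xmin,
                        ymin = base_ymax - nr * cs, cellsize = cs)

  # seed derived from the config seed and the period tag so different
  # periods get independent, reproducible fields
  set.seed((config$seed + sum(utf8ToInt(period)) * 1009L) %% .Machine$integer.max)
  season <- 1 + seasonal_amplitude * cos(2 * pi * ((1:12) - 1) / 12)
  dt <- pf <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) {
    fld_t <- if (dt_sd > 0) smooth_noise_field(nr, nc, 1) else matrix(0, nr, nc)
    fld_p <- if (pf_sd > 0) smooth_noise_field(nr, nc, 1) else matrix(0, nr, nc)
    dt[, , m] <- dt_mean * season[m] + dt_sd * fld_t
    pf[, , m] <- exp(log(p_factor_mean) + pf_sd * fld_p)
  }
  anomaly_grid(dt, pf, geom, period = period)
}
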