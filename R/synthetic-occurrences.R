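#' Sample presence/absence occurrences from a known niche
#'
#' Emulates a dense plot network: cells are sampled uniformly from the
#' non-nodata part of the grid (with replacement by default) and each record
#' receives a Bernoulli presence label with success probability given by the
#' niche function at that cell's bioclim values.  The true probability is
#' kept with each record so downstream recovery can be tested.
#'
#' @param bioclim A [derive_bioclim()] result.
#' @param niche A [niche] function.
#' @param n Number of records (>= 1).
#' @param seed Integer seed.
#' @param replace Sample cells with replacement (default `TRUE`).
#' @return Data frame with columns `lon`, `lat`, `row`, `col`, `label`
#'   (0/1 integer) and `true_prob`.
#' @export
sample_occurrences <- function(bioclim, niche, n, seed, replace = TRUE) {
  stopifnot(n >= 1)
  g <- bioclim$geom
  ncell <- g$nrow * g$ncol
  ok <- which(stats::complete.cases(matrix(bioclim$values, ncell,
                                           dim(bioclim$values)[3])))
  if (!length(ok)) stop("bioclim grid has no usable cells", call. = FALSE)
  if (!replace && n > length(ok))
    stop(sprintf("cannot sample %d cells without replacement from %d available",
                 n, length(ok)), call. = FALSE)
  set.seed(seed)
  cells <- if (replace) ok[sample.int(length(ok), n, replace = TRUE)]
           else ok[sample.int(length(ok), n)]
  row <- ((cells - 1) %% g$nrow) + 1
  col <- ((cells - 1) %/% g$nrow) + 1
  x <- as.data.frame(matrix(bioclim$values, ncell, dim(bioclim$values)[3],
                            dimnames = list(NULL, dimnames(bioclim$values)[[3]])))
  p <- niche(x[cells, , drop = FALSE])
  if (any(p < 0 | p > 1)) stop("niche returned probabilities outside [0, 1]",
                               call. = FALSE)
  xy <- cell_centers(g, row, col)
  data.frame(lon = xy$lon, lat = xy$lat, row = row, col = col,
             label = stats::rbinom(n, 1L, p), true_prob = p)
}

#' Generate fossil-type presence records with taphonomic noise
#'
#' True occupancy at a sampled cell is defined by thresholding the true
#' probability-of-presence surface.  The recorded label then flips the true
#' occupancy with probability `fp_rate` at unoccupied sites (false positives,
#' e.g. long-distance pollen transport into lake sediments) and `fn_rate` at
#' occupied sites (false negatives, e.g. fragile pollen failing to preserve).
#' The truth is retained per record so flips are exactly recoverable.
#'
#' @param true_prob A [raster_grid()] of true probability of presence (e.g.
#'   from [niche_probability()] on a palaeoclimate bioclim grid).
#' @param period Period tag attached to every record.
#' @param n Number of records.
#' @param occupancy_threshold Probability threshold in `(0, 1)` defining true
#'   occupancy.
#' @param fp_rate,fn_rate False-positive / false-negative rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame with columns `lon`, `lat`, `period`, `label` (0/1),
#'   `true_occupied` (0/1) and `class` (`"synthetic"`).
#' @export
make_fossil_records <- function(true_prob, period, n,
                                occupancy_threshold = 0.5,
                                fp_rate = 0, fn_rate = 0, seed) {
  stopifnot(fp_rate >= 0, fp_rate <= 1, fn_rate >= 0, fn_rate <= 1)
  if (occupancy_threshold <= 0 || occupancy_threshold >= 1)
    stop("occupancy_threshold must lie in (0, 1)", call. = FALSE)
  g <- true_prob$geom
  ok <- which(!is.na(true_prob$values))
  if (!length(ok)) stop("true probability surface is all nodata", call. = FALSE)
  set.seed(seed)
  cells <- ok[sample.int(length(ok), n, replace = TRUE)]
  row <- ((cells - 1) %% g$nrow) + 1
  col <- ((cells - 1) %/% g$nrow) + 1
  occ <- as.integer(true_prob$values[cells] >= occupancy_threshold)
  flip_p <- ifelse(occ == 1L, fn_rate, fp_rate)
  flip <- stats::rbinom(n, 1L, flip_p)
  label <- ifelse(flip == 1L, 1L - occ, occ)
  xy <- cell_centers(g, row, col)
  data.frame(lon = xy$lon, lat = xy$lat, period = period,
             label = as.integer(label), true_occupied = occ,
             class = "synthetic")
}

#' Read an occurrence table from CSV
#'
#' Expects at least `lon`, `lat`, `label` columns with binary labels.
#'
#' @param path CSV path.
#' @return Data frame of occurrences.
#' @export
read_occurrence_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("lon", "lat", "label")
  if (!all(need %in% names(x)))
    stop("occurrence CSV needs columns lon, lat, label", call. = FALSE)
  if (!all(x$label %in% c(0, 1)))
    stop("occurrence labels must be binary 0/1", call. = FALSE)
  x
}

#' Read a fossil-record table from CSV
#'
#' Expects `lon`, `lat`, `period`, `label` columns; labels must be explicit
#' binary 0/1 (no absence inference is performed).
#'
#' @param path CSV path.
#' @return Data frame of fossil records.
#' @export
read_fossil_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("lon", "lat", "period", "label")
  if (!all(need %in% names(x)))
    stop("fossil CSV needs columns lon, lat, period, label", call. = FALSE)
  if (!all(x$label %in% c(0, 1)))
    stop("fossil labels must be explicit binary 0/1", call. = FALSE)
  x
}
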