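#' Habitat-stability surface across the glacial cycle
#'
#' Cellwise product of two probability-of-presence surfaces — conventionally
#' the modern baseline and the Last Glacial Maximum hindcast — interpreted
#' as the probability that a location stayed within the species' climatic
#' tolerances through the glacial cycle.  The product is bounded above by
#' the smaller of the two inputs, so stable habitat requires suitability in
#' both periods.  Nodata in either input propagates.
#'
#' @param p_now,p_lgm Co-registered probability surfaces
#'   ([predict_surface()] results or any probability [raster_grid()]s).
#' @return A [raster_grid()] of stability values in `[0, 1]`, with attribute
#'   `periods` recording the source pair.
#' @export
stability_map <- function(p_now, p_lgm) {
  if (!same_geometry(p_now$geom, p_lgm$geom))
    stop("probability surfaces are not co-registered", call. = FALSE)
  rng <- range(c(p_now$values, p_lgm$values), na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1)
    stop("input surfaces must hold probabilities in [0, 1]", call. = FALSE)
  out <- raster_grid(p_now$values * p_lgm$values, p_now$geom,
                     name = "stability")
  attr(out, "periods") <- c(attr(p_now, "period") %||% "now",
                            attr(p_lgm, "period") %||% "lgm")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify a stability surface into persistence categories
#'
#' Cells are labelled `low` (below `t_mod`), `moderate` (`[t_mod, t_high)`)
#' or `high` (at or above `t_high`); nodata cells stay unclassified.  The
#' summary reports cell counts and area per class (area in squared degrees,
#' cells times `cellsize^2`).
#'
#' @param surface A [stability_map()] result.
#' @param thresholds Numeric `c(t_mod, t_high)` with `0 < t_mod < t_high < 1`.
#' @return List with `categories` (a [raster_grid()] coded 1 = low,
#'   2 = moderate, 3 = high) and `summary` (data frame: class, n_cells,
#'   area).
#' @export
classify_stability <- function(surface, thresholds = c(0.25, 0.5)) {
  t_mod <- thresholds[1]; t_high <- thresholds[2]
  if (!(t_mod > 0 && t_mod < t_high && t_high < 1))
    stop("thresholds must satisfy 0 < t_mod < t_high < 1", call. = FALSE)
  v <- surface$values
  cat_code <- ifelse(is.na(v), NA_real_,
                     ifelse(v >= t_high, 3, ifelse(v >= t_mod, 2, 1)))
  counts <- c(low = sum(cat_code == 1, na.rm = TRUE),
              moderate = sum(cat_code == 2, na.rm = TRUE),
              high = sum(cat_code == 3, na.rm = TRUE))
  cs <- surface$geom$cellsize
  list(categories = raster_grid(cat_code, surface$geom, name = "stability_class"),
       summary = data.frame(class = names(counts),
                            n_cells = as.integer(counts),
                            area = as.numeric(counts) * cs^2))
}
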