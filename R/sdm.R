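#' Default SDM covariate set
#'
#' The six low-collinearity bioclim variables used to fit the species
#' distribution model: growing degree-days (DD5), mean warmest month
#' temperature (MWMT), continentality (TD), and annual, growing-season and
#' winter precipitation (MAP, MSP, MWP).  The full 11-variable set can be
#' passed to [extract_covariates()] for sensitivity runs.
#'
#' @export
SDM_DEFAULT_VARS <- c("DD5", "MWMT", "TD", "MAP", "MSP", "MWP")

#' Build the SDM design table from occurrences and a bioclim grid
#'
#' Looks up the covariate values at the grid cell containing each record.
#' Records falling outside the grid or on nodata cells are dropped and
#' counted (attribute `n_dropped`).
#'
#' @param occurrences Data frame with `lon`, `lat`, `label` (0/1), e.g. from
#'   [sample_occurrences()] or [read_occurrence_csv()].
#' @param bioclim A [derive_bioclim()] result.
#' @param vars Covariate subset (default [SDM_DEFAULT_VARS]).
#' @return Data frame with column `label` plus one column per covariate;
#'   attribute `n_dropped` counts removed records.
#' @export
extract_covariates <- function(occurrences, bioclim,
                               vars = SDM_DEFAULT_VARS) {
  avail <- dimnames(bioclim$values)[[3]]
  if (!all(vars %in% avail))
    stop(sprintf("unknown bioclim variable(s): %s",
                 paste(setdiff(vars, avail), collapse = ", ")), call. = FALSE)
  X <- vapply(vars, function(v)
    values_at_xy(bioclim_layer(bioclim, v),
                 occurrences$lon, occurrences$lat),
    numeric(nrow(occurrences)))
  X <- matrix(X, nrow(occurrences), length(vars),
              dimnames = list(NULL, vars))
  keep <- stats::complete.cases(X)
  if (!any(keep))
    stop("no occurrence records remain after dropping nodata cells",
         call. = FALSE)
  out <- data.frame(label = as.integer(occurrences$label[keep]),
                    X[keep, , drop = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Fit the ensemble-classifier species distribution model
#'
#' Bagged classification-tree ensemble (random forest) relating binary
#' presence/absence labels to climate covariates.  Probability of presence
#' is the fraction of tree votes for presence; out-of-bag vote fractions are
#' stored for every training record, giving an internal validation set.
#' The fit is deterministic given the seed.
#'
#' @param design Design table from [extract_covariates()] (column `label`
#'   plus covariates).
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed.
#' @param balance If `TRUE`, each tree samples equal numbers of presences
#'   and absences (useful for absence-heavy real data).
#' @return An object of class `sdm_model`: the fitted forest plus covariate
#'   names, training metadata and out-of-bag vote fractions.
#' @export
fit_sdm <- function(design, n_trees = 500, seed = 1, balance = FALSE) {
  vars <- setdiff(names(design), "label")
  y <- factor(design$label, levels = c(0, 1))
  if (length(unique(design$label)) < 2)
    stop("both presence and absence records are required to fit the SDM",
         call. = FALSE)
  set.seed(seed)
  args <- list(x = design[, vars, drop = FALSE], y = y, ntree = n_trees,
               importance = FALSE)
  if (balance) {
    m <- min(table(y))
    args$sampsize <- c(m, m)
    args$strata <- y
  }
  rf <- do.call(randomForest::randomForest, args)
  structure(list(forest = rf, covariates = vars, n_trees = n_trees,
                 seed = seed, balance = balance,
                 labels = design$label,
                 oob_votes = unname(rf$votes[, "1"]),
                 class_balance = as.integer(table(y))),
            class = "sdm_model")
}

#' @export
print.sdm_model <- function(x, ...) {
  cat(sprintf("<sdm_model> %d trees on %d records (%d absent / %d present)\n",
              x$n_trees, length(x$labels),
              x$class_balance[1], x$class_balance[2]))
  cat(sprintf("  covariates: %s\n  seed %d, out-of-bag AUC %.3f\n",
              paste(x$covariates, collapse = " "), x$seed, oob_auc(x)))
  invisible(x)
}

#' Out-of-bag AUC of a fitted SDM
#'
#' Area under the ROC curve of out-of-bag vote fractions against the
#' training labels (see [auc()]).
#'
#' @param model An [fit_sdm()] result.
#' @return AUC in `[0, 1]`.
#' @export
oob_auc <- function(model) {
  stopifnot(inherits(model, "sdm_model"))
  auc(model$oob_votes, model$labels)
}

#' Predict a probability-of-presence surface
#'
#' Applies the fitted ensemble to every usable cell of a bioclim grid.
#' Nodata cells, and cells flagged in the optional ice mask, become nodata
#' in the output.
#'
#' @param model An [fit_sdm()] result.
#' @param bioclim A [derive_bioclim()] result supplying all model
#'   covariates (baseline or palaeoclimate).
#' @param period Period tag stored with the surface.
#' @param mask Optional [raster_grid()]; cells with value 1 (e.g. ice sheet)
#'   are forced to nodata before prediction.
#' @return A [raster_grid()] of probabilities in `[0, 1]` with attributes
#'   `period` and `n_predicted`.
#' @export
predict_surface <- function(model, bioclim, period = "modern", mask = NULL) {
  stopifnot(inherits(model, "sdm_model"))
  avail <- dimnames(bioclim$values)[[3]]
  if (!all(model$covariates %in% avail))
    stop(sprintf("bioclim grid lacks model covariate(s): %s",
                 paste(setdiff(model$covariates, avail), collapse = ", ")),
         call. = FALSE)
  g <- bioclim$geom
  n <- g$nrow * g$ncol
  X <- as.data.frame(matrix(bioclim$values, n, dim(bioclim$values)[3],
                            dimnames = list(NULL, avail)))[model$covariates]
  ok <- stats::complete.cases(X)
  if (!is.null(mask)) {
    if (!same_geometry(mask$geom, g))
      stop("mask geometry differs from the bioclim grid", call. = FALSE)
    ok <- ok & !is.na(mask$values) & mask$values == 0
  }
  p <- rep(NA_real_, n)
  if (any(ok))
    p[ok] <- stats::predict(model$forest, newdata = X[ok, , drop = FALSE],
                            type = "prob")[, "1"]
  out <- raster_grid(matrix(p, g$nrow, g$ncol), g,
                     name = paste0("p_presence_", period))
  attr(out, "period") <- period
  attr(out, "n_predicted") <- sum(ok)
  out
}
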