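#' Niche response functions
#'
#' A niche function maps a table of bioclim covariates to a true probability
#' of presence in `[0, 1]`.  These are the ground truth for synthetic
#' occurrence sampling and for hindcast validation: the realised niche of the
#' simulated species is known exactly, so model recovery can be measured.
#'
#' * `niche_gaussian()` — product of independent Gaussian response curves,
#'   one per variable: `p = scale * prod_v exp(-0.5 ((x_v - opt_v)/breadth_v)^2)`.
#' * `niche_step()` — a separable step response on a single variable:
#'   probability `p_in` on one side of a threshold, `p_out` on the other.
#' * `niche_constant()` — constant probability (degenerate niche, useful for
#'   calibration checks).
#'
#' @param optima Named vector of response-curve optima (names are bioclim
#'   variables).
#' @param breadths Named vector of response breadths (same names, > 0).
#' @param scale Maximum probability at the joint optimum, in `(0, 1]`.
#' @return A function of class `niche_function` taking a data frame or
#'   matrix with the named variables and returning probabilities in `[0, 1]`.
#' @name niche
#' @export
niche_gaussian <- function(optima, breadths, scale = 1) {
  stopifnot(length(optima) == length(breadths),
            all(names(optima) %in% names(breadths)),
            all(breadths > 0), scale > 0, scale <= 1)
  vars <- names(optima)
  f <- function(x) {
    x <- as.data.frame(x)
    p <- rep(scale, nrow(x))
    for (v in vars)
      p <- p * exp(-0.5 * ((x[[v]] - optima[[v]]) / breadths[[v]])^2)
    p
  }
  structure(f, class = c("niche_function", "function"), vars = vars)
}

#' @rdname niche
#' @param variable Bioclim variable the step responds to.
#' @param threshold Step location (variable units).
#' @param above If `TRUE`, probability is `p_in` where the variable exceeds
#'   the threshold.
#' @param p_in,p_out Probabilities inside / outside the suitable side.
#' @export
niche_step <- function(variable, threshold, above = TRUE,
                       p_in = 1, p_out = 0) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1)
  f <- function(x) {
    x <- as.data.frame(x)
    hi <- x[[variable]] > threshold
    ifelse(if (above) hi else !hi, p_in, p_out)
  }
  structure(f, class = c("niche_function", "function"), vars = variable)
}

#' @rdname niche
#' @param p Constant probability in `[0, 1]`.
#' @export
niche_constant <- function(p) {
  stopifnot(p >= 0, p <= 1)
  f <- function(x) rep(p, nrow(as.data.frame(x)))
  structure(f, class = c("niche_function", "function"), vars = character())
}

#' Evaluate a niche function over a bioclim grid
#'
#' @param niche A [niche] function.
#' @param bioclim A [derive_bioclim()] result.
#' @return A [raster_grid()] of true probability of presence (`NA` where the
#'   bioclim grid has nodata).
#' @export
niche_probability <- function(niche, bioclim) {
  g <- bioclim$geom
  n <- g$nrow * g$ncol
  x <- as.data.frame(matrix(bioclim$values, n, dim(bioclim$values)[3],
                            dimnames = list(NULL, dimnames(bioclim$values)[[3]])))
  p <- rep(NA_real_, n)
  ok <- stats::complete.cases(x)
  if (any(ok)) p[ok] <- niche(x[ok, , drop = FALSE])
  raster_grid(matrix(p, g$nrow, g$ncol), g, name = "true_prob")
}
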