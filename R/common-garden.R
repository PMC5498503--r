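#' Estimate variance components of a provenance trial by REML
#'
#' Fits the all-random trial model
#' `Y = mu + P + S + PxS + B(S) + PxB(S) + e`
#' to one trait by restricted maximum likelihood, with non-negativity
#' enforced at the boundary.  For single-site data (`multi_site = FALSE`,
#' auto-detected by default) the site and provenance-by-site terms drop and
#' block-within-site becomes a simple block effect.  Random terms with fewer
#' than two levels in the data are dropped automatically.
#'
#' Standard errors are the asymptotic SEs from the inverse of the REML
#' information matrix evaluated at the estimates,
#' `I[c,d] = tr(P G_c P G_d) / 2` with `G_c` the covariance-structure
#' derivative of component `c` and `P` the REML projection matrix — the
#' classical likelihood-based SE of a variance component.  SEs are reported
#' as `NA` for components estimated at the zero boundary, where the
#' asymptotic approximation does not hold.
#'
#' @param table Long phenotype data frame (`provenance`, `site`, `block`,
#'   `trait`, `value`; see [simulate_trial()]).
#' @param trait Trait name to fit (required if the table holds several).
#' @param multi_site `TRUE`/`FALSE`/`NULL`; `NULL` detects from the number
#'   of sites present.
#' @param se Compute standard errors (moderately expensive: builds an
#'   n-by-n covariance matrix).
#' @return An object of class `variance_components`: named estimate and SE
#'   vectors (`provenance`, `site`, `provenance:site`, `block`,
#'   `provenance:block`, `residual`), grand mean `mu`, `converged` flag,
#'   record count `n` and the fitted `lme4` model.
#' @export
fit_variance_model <- function(table, trait = NULL, multi_site = NULL,
                               se = TRUE) {
  if (!is.null(trait)) {
    if (!"trait" %in% names(table))
      stop("table has no trait column", call. = FALSE)
    table <- table[table$trait == trait, ]
  } else if ("trait" %in% names(table)) {
    tr <- unique(table$trait)
    if (length(tr) > 1)
      stop("table holds several traits; pass trait = ", call. = FALSE)
    trait <- tr
  }
  if (!nrow(table)) stop("no records to fit", call. = FALSE)
  d <- data.frame(value = table$value,
                  provenance = factor(table$provenance),
                  site = factor(table$site),
                  block = factor(table$block))
  if (is.null(multi_site)) multi_site <- nlevels(d$site) > 1
  if (multi_site && nlevels(d$site) < 2)
    stop("multi-site model requested but only one site present", call. = FALSE)
  if (stats::var(d$value) == 0) {
    canon0 <- if (multi_site)
      c("provenance", "site", "provenance:site", "block",
        "provenance:block", "residual")
    else c("provenance", "block", "provenance:block", "residual")
    zero <- stats::setNames(rep(0, length(canon0)), canon0)
    return(structure(list(components = zero,
                          se = stats::setNames(rep(NA_real_, length(canon0)),
                                               canon0),
                          mu = d$value[1], converged = TRUE, n = nrow(d),
                          trait = trait, multi_site = multi_site,
                          model = NULL),
                     class = "variance_components"))
  }

  if (multi_site) {
    d$blk <- interaction(d$site, d$block, drop = TRUE)        # B(S)
    d$ps <- interaction(d$provenance, d$site, drop = TRUE)    # PxS
    d$pblk <- interaction(d$provenance, d$blk, drop = TRUE)   # PxB(S)
    terms <- c(provenance = "provenance", site = "site",
               "provenance:site" = "ps", block = "blk",
               "provenance:block" = "pblk")
  } else {
    d$blk <- factor(d$block)
    d$pblk <- interaction(d$provenance, d$blk, drop = TRUE)
    terms <- c(provenance = "provenance", block = "blk",
               "provenance:block" = "pblk")
  }
  if (max(table(d$pblk)) < 2)
    stop("degenerate design: no replication within plots", call. = FALSE)
  # drop unidentifiable terms: <2 levels, or as many levels as observations
  # (confounded with the residual)
  keep <- vapply(terms, function(v)
    nlevels(d[[v]]) >= 2 && nlevels(d[[v]]) < nrow(d), TRUE)
  terms <- terms[keep]
  # drop terms whose grouping partition duplicates an earlier term's
  # (e.g. provenance-by-block collapses onto provenance with a single block)
  if (length(terms) > 1) {
    dup <- rep(FALSE, length(terms))
    for (a in seq_along(terms)[-1]) for (b in seq_len(a - 1)) {
      if (dup[b]) next
      fa <- d[[terms[a]]]; fb <- d[[terms[b]]]
      if (nlevels(fa) == nlevels(fb) &&
          nlevels(interaction(fa, fb, drop = TRUE)) == nlevels(fa))
        dup[a] <- TRUE
    }
    terms <- terms[!dup]
  }
  if (!length(terms))
    stop("degenerate design: no random term has replication", call. = FALSE)

  form <- stats::as.formula(paste(
    "value ~ 1 +", paste(sprintf("(1 | %s)", terms), collapse = " + ")))
  fit <- withCallingHandlers(
    lme4::lmer(form, data = d, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE)),
    warning = function(w) invokeRestart("muffleWarning"))
  opt <- fit@optinfo
  converged <- is.null(opt$conv$lme4$messages) ||
    !length(opt$conv$lme4$messages)

  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- stats::setNames(vc$vcov, vc$grp)
  # map lme4 grouping names back to the canonical component names
  canon <- c(names(terms), "residual")
  lookup <- c(stats::setNames(names(terms), unname(terms)),
              Residual = "residual")
  names(est) <- lookup[names(est)]
  est <- est[canon]
  names(est) <- canon

  ses <- rep(NA_real_, length(est))
  names(ses) <- canon
  if (se) {
    Z <- lapply(unname(terms), function(v)
      Matrix::sparse.model.matrix(~ 0 + d[[v]]))
    ses_all <- tryCatch(vc_information_se(est, Z, nrow(d)),
                        error = function(e) ses)
    ses <- ses_all
    names(ses) <- canon
    ses[est <= 1e-8 * max(est)] <- NA_real_   # boundary estimates
  }
  structure(list(components = est, se = ses,
                 mu = unname(lme4::fixef(fit)[1]),
                 converged = converged, n = nrow(d), trait = trait,
                 multi_site = multi_site, model = fit),
            class = "variance_components")
}

# Asymptotic SEs of variance components from the REML information matrix.
# est: named variances with "residual" last; Z: list of sparse incidence
# matrices for the non-residual terms; n: observation count.
vc_information_se <- function(est, Z, n) {
  k <- length(est)                       # includes residual
  V <- Matrix::Diagonal(n) * est[["residual"]]
  for (i in seq_along(Z))
    V <- V + est[[i]] * Matrix::tcrossprod(Z[[i]])
  V <- as.matrix(V)
  Vinv <- chol2inv(chol(V))
  X <- matrix(1, n, 1)
  u <- Vinv %*% X
  P <- Vinv - u %*% solve(crossprod(X, u), t(u))
  # A_cd = Z_c' P Z_d ; tr(P G_c P G_d) = sum(A_cd^2)
  PZ <- c(lapply(Z, function(z) as.matrix(P %*% z)), list(P))
  Zs <- c(lapply(Z, as.matrix), list(diag(n)))
  info <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in a:k) {
    A <- crossprod(Zs[[a]], PZ[[b]])
    info[a, b] <- info[b, a] <- 0.5 * sum(A * A)
  }
  sqrt(diag(solve(info)))
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> trait %s, %d records%s, mu = %.3f\n",
              x$trait, x$n,
              if (x$converged) "" else " [NOT CONVERGED]", x$mu))
  tab <- data.frame(component = names(x$components),
                    estimate = round(unname(x$components), 4),
                    se = round(unname(x$se), 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Region-by-trait residual variance summary
#'
#' Runs [fit_variance_model()] separately for every region and trait
#' combination present in the table (the regional within-population
#' variance analysis) and collects the residual components with their SEs.
#' Missing combinations are reported as `NA` rows rather than dropped
#' silently.
#'
#' @param table Long phenotype table with a `region` column (see
#'   [simulate_trial()]).
#' @param traits Traits to fit (default: all present).
#' @param regions Regions to fit (default: all present).
#' @param se Compute standard errors per fit.
#' @return Data frame with one row per region x trait: `region`, `trait`,
#'   `residual`, `se`, `converged`, `n`.  Attribute `fits` holds the full
#'   `variance_components` objects.
#' @export
region_trait_table <- function(table, traits = NULL, regions = NULL,
                               se = TRUE) {
  if (is.null(traits)) traits <- unique(table$trait)
  if (is.null(regions)) regions <- unique(table$region)
  rows <- vector("list", length(regions) * length(traits))
  fits <- list()
  i <- 0
  for (rg in regions) for (tr in traits) {
    i <- i + 1
    sub <- table[table$region == rg & table$trait == tr, ]
    if (!nrow(sub)) {
      warning(sprintf("no data for region '%s', trait '%s'", rg, tr),
              call. = FALSE)
      rows[[i]] <- data.frame(region = rg, trait = tr, residual = NA_real_,
                              se = NA_real_, converged = NA, n = 0L)
      next
    }
    fit <- fit_variance_model(sub, trait = tr, se = se)
    fits[[paste(rg, tr, sep = ".")]] <- fit
    rows[[i]] <- data.frame(region = rg, trait = tr,
                            residual = unname(fit$components["residual"]),
                            se = unname(fit$se["residual"]),
                            converged = fit$converged, n = fit$n)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Provenance means across traits and sites
#'
#' Builds the provenance-by-variable matrix used for trait ordination:
#' multi-site traits contribute one variable per site (e.g. height at each
#' test site), single-site traits one variable each.  Means are arithmetic
#' provenance means, which equal least-squares means under the balanced RCB
#' design.
#'
#' @param table Long phenotype table (see [simulate_trial()]).
#' @return Numeric matrix, provenances in rows, variables in columns.
#' @export
provenance_summaries <- function(table) {
  table$site <- as.character(table$site)
  multi <- tapply(table$site, table$trait,
                  function(s) length(unique(s)) > 1)
  table$variable <- ifelse(multi[table$trait],
                           paste(table$trait, table$site, sep = ":"),
                           as.character(table$trait))
  m <- tapply(table$value, list(table$provenance, table$variable), mean)
  if (any(is.na(m)))
    stop("every provenance must be measured for every variable",
         call. = FALSE)
  m <- as.matrix(m)
  m[, order(colnames(m)), drop = FALSE]
}

#' Principal component ordination
#'
#' PCA of a provenance-by-variable matrix (or any observations-by-variables
#' matrix).  With `standardize = TRUE` (default) the analysis is of the
#' correlation matrix, so the component loadings scaled by the singular
#' values are the correlations of the components with the original
#' variables — the usual biplot vectors.  Component signs follow a
#' deterministic convention: the largest-magnitude loading of each component
#' is positive.
#'
#' @param mat Numeric matrix, >= 2 rows and >= 2 columns, no missing values.
#' @param standardize Use the correlation (`TRUE`) or covariance matrix.
#' @return An object of class `ordination`: `loadings` (orthonormal
#'   eigenvectors, variables x components), `cor_loadings` (variable-
#'   component correlations when standardised), `scores`, `eigenvalues` and
#'   `explained` (fractions of total variance).
#' @export
pca_ordination <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2)
    stop("ordination needs at least 2 rows and 2 columns", call. = FALSE)
  if (any(is.na(mat)))
    stop("ordination input must have no missing values", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (standardize && any(sds == 0))
    stop(sprintf("zero-variance column(s): %s; cannot standardize",
                 paste(colnames(mat)[sds == 0], collapse = ", ")),
         call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = standardize)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  eig <- pc$sdev^2
  cor_load <- if (standardize) sweep(load, 2, pc$sdev, `*`) else NULL
  structure(list(loadings = load, cor_loadings = cor_load, scores = scores,
                 eigenvalues = eig, explained = eig / sum(eig),
                 standardized = standardize),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("<ordination> %d variables, %d observations\n",
              nrow(x$loadings), nrow(x$scores)))
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$explained),
                    100 * x$explained), collapse = ", "), "\n")
  invisible(x)
}
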