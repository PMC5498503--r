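#' Provenance-trial design with per-region generating parameters
#'
#' Describes a randomised complete block (RCB) provenance trial: provenances
#' grouped into geographic regions, planted in fixed-size row plots within
#' blocks at a series of test sites.  Each trait carries per-region
#' generating parameters for the random-effects model used by
#' [simulate_trial()]: grand mean and the variances of the provenance (P),
#' site (S), provenance-by-site (PxS), block-within-site (B(S)),
#' provenance-by-block (PxB(S)) and residual terms.  Traits flagged
#' `single_site` are measured at one site only, where the site terms drop and
#' block-within-site becomes a simple block effect.
#'
#' @param regions Named integer vector: provenances per region.
#' @param n_sites Number of test sites.
#' @param n_blocks Blocks per site.
#' @param n_trees Trees per row plot.
#' @param traits List of trait specifications from [trait_spec()].
#' @return An object of class `trial_design`.
#' @seealso [default_aspen_design()] for the trial layout used throughout
#'   the package's examples and tests.
#' @export
trial_design <- function(regions, n_sites, n_blocks, n_trees, traits) {
  stopifnot(is.numeric(regions), !is.null(names(regions)),
            all(regions >= 1), n_sites >= 1, n_blocks >= 1, n_trees >= 1)
  traits <- lapply(traits, function(tr) {
    stopifnot(inherits(tr, "trait_spec"))
    missing_rg <- setdiff(names(regions), tr$params$region)
    if (length(missing_rg))
      stop(sprintf("trait '%s' lacks parameters for region(s): %s",
                   tr$name, paste(missing_rg, collapse = ", ")), call. = FALSE)
    tr
  })
  structure(list(regions = vapply(regions, as.integer, 1L),
                 n_sites = as.integer(n_sites),
                 n_blocks = as.integer(n_blocks),
                 n_trees = as.integer(n_trees),
                 traits = stats::setNames(traits,
                                          vapply(traits, `[[`, "", "name"))),
            class = "trial_design")
}

#' @rdname trial_design
#' @param name Trait name.
#' @param single_site Is the trait measured at a single site?
#' @param params Data frame with one row per region and columns `region`,
#'   `mu`, `s2_prov`, `s2_site`, `s2_prov_site`, `s2_block`, `s2_prov_block`,
#'   `s2_resid` (variances, all >= 0).  Site-related columns are ignored for
#'   single-site traits.
#' @export
trait_spec <- function(name, params, single_site = FALSE) {
  need <- c("region", "mu", "s2_prov", "s2_site", "s2_prov_site",
            "s2_block", "s2_prov_block", "s2_resid")
  if (!all(need %in% names(params)))
    stop(sprintf("trait params need columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  vc <- as.matrix(params[, setdiff(need, c("region", "mu"))])
  if (any(vc < 0))
    stop("variance parameters must be non-negative", call. = FALSE)
  structure(list(name = name, single_site = isTRUE(single_site),
                 params = as.data.frame(params)),
            class = "trait_spec")
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("<trial_design> %d provenances in %d regions, %d sites x %d blocks x %d-tree plots\n",
              sum(x$regions), length(x$regions), x$n_sites, x$n_blocks,
              x$n_trees))
  for (tr in x$traits)
    cat(sprintf("  trait %s%s\n", tr$name,
                if (tr$single_site) " (single site)" else ""))
  invisible(x)
}

#' Regional residual variance components used as generating defaults
#'
#' Region-by-trait residual (within-population) variance components for tree
#' height (measured at all sites), timing of bud break and timing of leaf
#' senescence (measured at the central Alberta site only), on the trait
#' measurement scale.  These magnitudes — a southeast-to-northwest decline
#' from Minnesota to northeastern British Columbia in height, with Minnesota
#' far more variable in bud break — define the study conditions that
#' [default_aspen_design()] simulates.
#'
#' @return Data frame with columns `region`, `height`, `budbreak`,
#'   `senescence`.
#' @export
aspen_residual_components <- function() {
  data.frame(
    region = c("BC Northeast", "Northern AB", "AB Foothills",
               "Central AB", "Saskatchewan", "Minnesota"),
    height = c(0.61, 0.71, 0.87, 0.81, 0.80, 0.94),
    budbreak = c(8.4, 8.9, 9.2, 8.8, 8.9, 13.1),
    senescence = c(5.2, 6.6, 10.3, 7.5, 6.2, 8.3))
}

#' Default aspen provenance-trial design
#'
#' The trial layout used throughout the package: 43 provenances from six
#' boreal regions, planted in 5-tree row plots in 6 blocks at each of 5 test
#' sites (6,450 height measurements); bud break and leaf senescence scored at
#' the central Alberta site only (1,290 trees each).  Residual variances
#' follow [aspen_residual_components()]; the remaining variance components
#' default to fixed fractions of the regional residual (provenance 0.3,
#' site 0.5, provenance-by-site 0.1, block 0.05, provenance-by-block 0.1),
#' keeping every term comfortably away from the zero boundary.
#'
#' @param height_mu,budbreak_mu,senescence_mu Grand means per trait (trait
#'   units; bud break and senescence in day-of-year).
#' @return A [trial_design()].
#' @export
default_aspen_design <- function(height_mu = 10, budbreak_mu = 140,
                                 senescence_mu = 260) {
  rc <- aspen_residual_components()
  regions <- stats::setNames(c(7L, 7L, 7L, 8L, 7L, 7L), rc$region)
  mk <- function(trait, mu, single_site) {
    s2e <- rc[[trait]]
    trait_spec(trait, data.frame(
      region = rc$region, mu = mu,
      s2_prov = 0.3 * s2e, s2_site = 0.5 * s2e, s2_prov_site = 0.1 * s2e,
      s2_block = 0.05 * s2e, s2_prov_block = 0.1 * s2e, s2_resid = s2e),
      single_site = single_site)
  }
  trial_design(regions, n_sites = 5, n_blocks = 6, n_trees = 5,
               traits = list(mk("height", height_mu, FALSE),
                             mk("budbreak", budbreak_mu, TRUE),
                             mk("senescence", senescence_mu, TRUE)))
}

#' Restrict a trial design to one region (and optionally one trait)
#'
#' Convenience for parameter-recovery studies that simulate and fit a single
#' region at a time, as the regional variance analysis does.
#'
#' @param design A [trial_design()] (default [default_aspen_design()]).
#' @param region Region name to keep.
#' @param trait Optional trait name to keep (default: all traits).
#' @return A [trial_design()] with a single region.
#' @export
region_design <- function(region, trait = NULL,
                          design = default_aspen_design()) {
  if (!region %in% names(design$regions))
    stop(sprintf("unknown region '%s'", region), call. = FALSE)
  traits <- if (is.null(trait)) design$traits else design$traits[trait]
  if (any(vapply(traits, is.null, TRUE)))
    stop(sprintf("unknown trait '%s'", trait), call. = FALSE)
  traits <- lapply(traits, function(tr) {
    tr$params <- tr$params[tr$params$region == region, ]
    tr
  })
  trial_design(design$regions[region], design$n_sites, design$n_blocks,
               design$n_trees, traits)
}

#' Expand a trial design into its record skeleton
#'
#' Full crossing of provenances, sites, blocks and trees per plot.  The
#' record count is the product of the four dimensions (e.g. 43 x 5 x 6 x 5 =
#' 6,450 for the default design; 1,290 at a single site).
#'
#' @param design A [trial_design()].
#' @param single_site If `TRUE`, expand for a one-site trait (site fixed to
#'   `"S1"`).
#' @return Data frame with columns `region`, `provenance`, `site`, `block`,
#'   `tree` (all factors except `tree`); attribute `n_records` gives the row
#'   count.
#' @export
expand_design <- function(design, single_site = FALSE) {
  stopifnot(inherits(design, "trial_design"))
  prov_region <- rep(names(design$regions), design$regions)
  nprov <- sum(design$regions)
  prov <- sprintf("P%02d", seq_len(nprov))
  nsites <- if (single_site) 1L else design$n_sites
  out <- expand.grid(
    tree = seq_len(design$n_trees),
    provenance = prov,
    block = sprintf("B%d", seq_len(design$n_blocks)),
    site = sprintf("S%d", seq_len(nsites)),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$region <- prov_region[match(out$provenance, prov)]
  out <- out[, c("region", "provenance", "site", "block", "tree")]
  attr(out, "n_records") <- nrow(out)
  out
}

#' Simulate phenotypes under the trial's random-effects model
#'
#' Generates one observation per tree and trait as
#' `Y = mu + P_i + S_j + (PxS)_ij + B(S)_jk + (PxB(S))_ijk + e_ijkl`,
#' with every effect drawn independently as mean-zero Gaussian at its
#' generating variance, separately for each region (the model is fit per
#' region downstream, so regions are independent by construction).
#' Single-site traits omit the site and provenance-by-site terms and use a
#' simple block effect.
#'
#' @param design A [trial_design()].
#' @param seed Integer seed.
#' @return Long data frame with columns `region`, `provenance`, `site`,
#'   `block`, `tree`, `trait`, `value`.
#' @export
simulate_trial <- function(design, seed) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(seed)
  out <- vector("list", length(design$traits))
  for (ti in seq_along(design$traits)) {
    tr <- design$traits[[ti]]
    skel <- expand_design(design, single_site = tr$single_site)
    vals <- numeric(nrow(skel))
    for (rg in names(design$regions)) {
      pr <- tr$params[tr$params$region == rg, ]
      idx <- which(skel$region == rg)
      sub <- skel[idx, ]
      draw <- function(f, s2) {
        lv <- unique(f)
        e <- stats::rnorm(length(lv), 0, sqrt(s2))
        e[match(f, lv)]
      }
      y <- pr$mu +
        draw(sub$provenance, pr$s2_prov) +
        draw(interaction(sub$site, sub$block, drop = TRUE), pr$s2_block) +
        draw(interaction(sub$provenance, sub$site, sub$block, drop = TRUE),
             pr$s2_prov_block) +
        stats::rnorm(length(idx), 0, sqrt(pr$s2_resid))
      if (!tr$single_site) {
        y <- y + draw(sub$site, pr$s2_site) +
          draw(interaction(sub$provenance, sub$site, drop = TRUE),
               pr$s2_prov_site)
      }
      vals[idx] <- y
    }
    out[[ti]] <- data.frame(skel[, c("region", "provenance", "site",
                                     "block", "tree")],
                            trait = tr$name, value = vals)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a long-format phenotype table from CSV
#'
#' Expects columns `region`, `provenance`, `site`, `block`, `tree`, `trait`,
#' `value` with finite trait values.
#'
#' @param path CSV path.
#' @return Data frame of phenotype records.
#' @export
read_phenotype_csv <- function(path) {
  x <- utils::read.csv(path)
  need <- c("region", "provenance", "site", "block", "tree", "trait", "value")
  if (!all(need %in% names(x)))
    stop(sprintf("phenotype CSV needs columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  if (!all(is.finite(x$value)))
    stop("phenotype values must be finite", call. = FALSE)
  x
}
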