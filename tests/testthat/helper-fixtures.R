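# Shared small fixtures, built in code at test time.

test_config <- function(seed = 42, rows = 30, cols = 30, ...) {
  synthetic_config(grid_rows = rows, grid_cols = cols, seed = seed, ...)
}

test_bioclim <- function(seed = 42, rows = 30, cols = 30, ...) {
  derive_bioclim(make_climate_grid(test_config(seed, rows, cols, ...)))
}

# A smooth niche centred in the middle of the default test grid's climate.
test_niche <- function() {
  niche_gaussian(optima = c(DD5 = 1200, MAP = 500),
                 breadths = c(DD5 = 500, MAP = 250))
}

# A tiny single-trait design for fast variance-model fits.
toy_design <- function(n_prov = 6, n_sites = 2, n_blocks = 2, n_trees = 4,
                       mu = 5, s2_prov = 1, s2_site = 0.5, s2_prov_site = 0.25,
                       s2_block = 0.25, s2_prov_block = 0.25, s2_resid = 1,
                       region = "R1", single_site = FALSE) {
  trial_design(
    stats::setNames(n_prov, region), n_sites, n_blocks, n_trees,
    traits = list(trait_spec("y", data.frame(
      region = region, mu = mu, s2_prov = s2_prov, s2_site = s2_site,
      s2_prov_site = s2_prov_site, s2_block = s2_block,
      s2_prov_block = s2_prov_block, s2_resid = s2_resid),
      single_site = single_site)))
}
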