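test_that("a constant response yields zero components and the constant mean", {
  des <- toy_design(s2_prov = 0, s2_site = 0, s2_prov_site = 0, s2_block = 0,
                    s2_prov_block = 0, s2_resid = 0, mu = 3.5)
  ph <- simulate_trial(des, seed = 1)
  f <- fit_variance_model(ph, trait = "y")
  expect_true(all(f$components == 0))
  expect_equal(f$mu, 3.5)
})

test_that("REML equals the closed-form ANOVA estimators on a balanced one-way toy", {
  # one site, one block: the model collapses to value ~ (1|provenance),
  # whose balanced REML solution is the textbook method-of-moments estimator
  des <- toy_design(n_prov = 12, n_sites = 1, n_blocks = 1, n_trees = 8,
                    s2_prov = 2, s2_block = 0, s2_prov_block = 0,
                    s2_resid = 1, single_site = TRUE)
  ph <- simulate_trial(des, seed = 42)
  f <- fit_variance_model(ph, trait = "y", se = TRUE)
  want <- oracle_oneway_components(ph$value, ph$provenance)
  expect_equal(unname(f$components["residual"]), unname(want["residual"]),
               tolerance = 1e-6)
  expect_equal(unname(f$components["provenance"]), unname(want["provenance"]),
               tolerance = 1e-6)
  expect_true(all(f$se[c("provenance", "residual")] > 0))
})

test_that("multi-site fits recover generating components without bias", {
  # 200 small single-site replicates: residual and provenance estimates
  # unbiased within 3 Monte-Carlo standard errors
  des <- toy_design(n_prov = 8, n_sites = 1, n_blocks = 4, n_trees = 4,
                    s2_prov = 1, s2_block = 0.5, s2_prov_block = 0.25,
                    s2_resid = 1, single_site = TRUE)
  ests <- t(vapply(1:200, function(i) {
    f <- fit_variance_model(simulate_trial(des, seed = 5000 + i), se = FALSE)
    f$components[c("provenance", "residual")]
  }, c(provenance = 0, residual = 0)))
  for (comp in c("provenance", "residual")) {
    gen <- c(provenance = 1, residual = 1)[comp]
    mc_se <- sd(ests[, comp]) / sqrt(nrow(ests))
    expect_lt(abs(mean(ests[, comp]) - gen), 3 * mc_se)
  }
})

test_that("confidence intervals from information-matrix SEs cover the truth", {
  des <- toy_design(n_prov = 10, n_sites = 1, n_blocks = 5, n_trees = 5,
                    s2_prov = 1, s2_block = 0.5, s2_prov_block = 0.5,
                    s2_resid = 1, single_site = TRUE)
  hits <- vapply(1:40, function(i) {
    f <- fit_variance_model(simulate_trial(des, seed = 7000 + i), se = TRUE)
    est <- f$components["residual"]; s <- f$se["residual"]
    is.finite(s) && abs(est - 1) <= 1.96 * s
  }, TRUE)
  expect_gte(mean(hits), 0.85)   # ~95% nominal, 40 draws
})

test_that("location and scale changes transform components as they must", {
  des <- toy_design(n_prov = 8, n_sites = 2, n_blocks = 3, n_trees = 4)
  ph <- simulate_trial(des, seed = 11)
  f0 <- fit_variance_model(ph, trait = "y", se = FALSE)
  shift <- ph; shift$value <- shift$value + 100
  f1 <- fit_variance_model(shift, trait = "y", se = FALSE)
  expect_equal(f1$components, f0$components, tolerance = 1e-5)
  expect_equal(f1$mu, f0$mu + 100, tolerance = 1e-6)
  scaled <- ph; scaled$value <- scaled$value * 3
  f2 <- fit_variance_model(scaled, trait = "y", se = FALSE)
  expect_equal(f2$components, 9 * f0$components, tolerance = 1e-4)
})

test_that("degenerate designs are rejected", {
  des <- toy_design(n_prov = 4, n_sites = 2, n_blocks = 2, n_trees = 1)
  ph <- simulate_trial(des, seed = 2)
  expect_error(fit_variance_model(ph, trait = "y"),
               "no replication within plots")
})

test_that("the region-by-trait table runs one fit per combination", {
  des <- default_aspen_design()
  ph <- simulate_trial(des, seed = 101)
  tab <- region_trait_table(ph, se = FALSE)
  expect_equal(nrow(tab), 18)   # 6 regions x 3 traits
  expect_equal(length(attr(tab, "fits")), 18)
  expect_true(all(tab$n[tab$trait == "height"] %in% c(1050, 1200)))
  expect_true(all(tab$n[tab$trait != "height"] %in% c(210, 240)))
  # single region x single trait matches a direct fit
  sub <- ph[ph$region == "Minnesota" & ph$trait == "height", ]
  direct <- fit_variance_model(sub, trait = "height", se = FALSE)
  one <- region_trait_table(sub, se = FALSE)
  expect_equal(one$residual, unname(direct$components["residual"]))
})

test_that("a residual-variance gradient across regions is recovered in rank", {
  rc <- aspen_residual_components()
  hits <- vapply(1:5, function(s) {
    ph <- simulate_trial(default_aspen_design(), seed = 300 + s)
    tab <- region_trait_table(ph, traits = "height", se = FALSE)
    est <- tab$residual[match(rc$region, tab$region)]
    cor(est, rc$height, method = "spearman")
  }, 1)
  expect_gte(mean(hits), 0.8)   # strong rank agreement across seeds
})

test_that("provenance summaries are balanced means with the right shape", {
  des <- default_aspen_design()
  ph <- simulate_trial(des, seed = 21)
  m <- provenance_summaries(ph)
  expect_equal(dim(m), c(43L, 7L))   # height at 5 sites + 2 phenology traits
  # balanced data: provenance mean equals the arithmetic mean of its records
  sub <- ph[ph$provenance == "P01" & ph$trait == "height" & ph$site == "S2", ]
  expect_equal(m["P01", "height:S2"], mean(sub$value))
  # known provenance effects are recovered within Monte-Carlo error
  des2 <- toy_design(n_prov = 30, n_sites = 1, n_blocks = 6, n_trees = 5,
                     s2_prov = 4, s2_block = 0, s2_prov_block = 0,
                     s2_resid = 0.01, single_site = TRUE)
  ph2 <- simulate_trial(des2, seed = 22)
  m2 <- provenance_summaries(ph2)
  expect_equal(sd(m2[, "y"]), 2, tolerance = 0.5)
})

test_that("ordination reproduces eigenstructure and its invariants", {
  # two perfectly correlated variables: PC1 explains everything
  x <- cbind(a = 1:10, b = 2 * (1:10) + 3)
  ord <- pca_ordination(x)
  expect_equal(ord$explained[1], 1)
  # orthonormal loadings
  set.seed(3)
  y <- matrix(rnorm(15 * 5), 15, 5, dimnames = list(NULL, letters[1:5]))
  ord2 <- pca_ordination(y)
  expect_equal(crossprod(ord2$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # eigenvalues equal those of the correlation matrix (independent solver)
  z <- matrix(c(1, 2, 3, 2, 1, 4, 6, 5, 2, 8, 1, 0, 2, 4, 3), 5, 3,
              dimnames = list(NULL, c("u", "v", "w")))
  ord3 <- pca_ordination(z)
  expect_equal(sort(ord3$eigenvalues, decreasing = TRUE),
               sort(eigen(cor(z))$values, decreasing = TRUE),
               tolerance = 1e-10)
  # total variance conserved: eigenvalues sum to the number of variables
  expect_equal(sum(ord2$eigenvalues), 5)
  # deterministic sign convention
  for (j in 1:5) {
    l <- ord2$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # zero-variance column names the offender
  bad <- cbind(ok = rnorm(6), flat = rep(1, 6))
  expect_error(pca_ordination(bad), "flat")
})
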