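test_that("AUC equals the Mann-Whitney pair statistic on known cases", {
  expect_equal(auc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auc(c(0.1, 0.9), c(1, 0)), 0)
  # ties counted half: brute force over the 4 presence-absence pairs
  expect_equal(auc(c(0.9, 0.8, 0.8, 0.3), c(1, 1, 0, 0)), 0.875)
  expect_error(auc(c(0.2, 0.4), c(1, 1)), "at least one")
  expect_error(auc(c(0.2, 0.4), c(1, 2)), "binary")
})

test_that("AUC matches all-pairs brute force on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(5)
  scores <- runif(200); labels <- rbinom(200, 1, 0.4)
  a <- auc(scores, labels)
  expect_equal(auc(qlogis(scores), labels), a)
  expect_equal(auc(scores^3 + 2 * scores, labels), a)
  # complement identity for tie-free scores
  expect_equal(a + auc(scores, 1 - labels), 1)
})

test_that("cross-check against an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(6)
  scores <- round(runif(300), 2); labels <- rbinom(300, 1, 0.5)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("hindcast validation pools periods and counts drops", {
  bc <- test_bioclim(seed = 41)
  occ <- sample_occurrences(bc, test_niche(), 3000, seed = 1)
  m <- fit_sdm(extract_covariates(occ, bc), n_trees = 150, seed = 2)
  surf <- predict_surface(m, bc, period = "modern")
  truth <- niche_probability(test_niche(), bc)
  fos <- make_fossil_records(truth, "modern", 800, seed = 3)
  res <- validate_hindcast(list(modern = surf), fos)
  expect_gte(res$pooled_auc, 0.9)   # noise-free fossils from a well-fit model
  expect_equal(res$n_used + res$n_dropped, 800)

  # labels independent of the surface give AUC near 0.5
  set.seed(4)
  fos_null <- fos; fos_null$label <- sample(fos$label)
  a <- validate_hindcast(list(modern = surf), fos_null)$pooled_auc
  expect_gt(a, 0.42); expect_lt(a, 0.58)

  # records on masked cells are excluded and counted
  mask <- raster_grid(matrix(0, bc$geom$nrow, bc$geom$ncol), bc$geom)
  mask$values[, 1:10] <- 1
  surf_m <- predict_surface(m, bc, period = "modern", mask = mask)
  res_m <- validate_hindcast(list(modern = surf_m), fos)
  on_ice <- sum(fos$lon < bc$geom$xmin + 10 * bc$geom$cellsize)
  expect_equal(res_m$n_dropped, on_ice)

  expect_error(validate_hindcast(list(lgm = surf), fos), "no surface")
})

test_that("pooled AUC degrades as taphonomic noise rates grow", {
  bc <- test_bioclim(seed = 42)
  occ <- sample_occurrences(bc, test_niche(), 3000, seed = 5)
  m <- fit_sdm(extract_covariates(occ, bc), n_trees = 150, seed = 6)
  surf <- predict_surface(m, bc, period = "modern")
  truth <- niche_probability(test_niche(), bc)
  mean_auc <- function(rate) {
    mean(vapply(1:5, function(s) {
      fos <- make_fossil_records(truth, "modern", 600, fp_rate = rate,
                                 fn_rate = rate, seed = 100 + s)
      validate_hindcast(list(modern = surf), fos)$pooled_auc
    }, 1))
  }
  a0 <- mean_auc(0); a2 <- mean_auc(0.2); a4 <- mean_auc(0.4)
  expect_gt(a0, a2)
  expect_gt(a2, a4)
})
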