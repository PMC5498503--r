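make_const_anomaly <- function(geom, dt = 0, pf = 1, period = "custom") {
  anomaly_grid(array(dt, c(geom$nrow, geom$ncol, 12)),
               array(pf, c(geom$nrow, geom$ncol, 12)), geom, period)
}

test_that("regridding maps constant fields to constant fields", {
  coarse <- grid_geometry(5, 5, xmin = -120, ymin = 40, cellsize = 0.8)
  fine <- grid_geometry(20, 20, xmin = -120, ymin = 40, cellsize = 0.2)
  an <- make_const_anomaly(coarse, dt = -8, pf = 0.7)
  rg <- regrid_anomaly(an, fine)
  expect_true(same_geometry(rg$geom, fine))
  expect_true(all(abs(rg$dt - (-8)) < 1e-12))
  expect_true(all(abs(rg$p_factor - 0.7) < 1e-12))
})

test_that("regridding with identical geometries is the identity", {
  cfg <- test_config(seed = 21, rows = 12, cols = 12)
  an <- make_anomaly_grid(cfg, "11k", coarsening_factor = 1)
  expect_identical(regrid_anomaly(an, an$geom), an)
})

test_that("bilinear regridding reproduces planar fields exactly", {
  coarse <- grid_geometry(6, 7, xmin = 0, ymin = 0, cellsize = 1)
  fine <- grid_geometry(18, 21, xmin = 0, ymin = 0, cellsize = 1 / 3)
  plane <- function(lon, lat) 2 + 0.7 * lon - 1.3 * lat
  ctr_c <- cell_centers(coarse, rep(1:6, 7), rep(1:7, each = 6))
  vals <- matrix(plane(ctr_c$lon, ctr_c$lat), 6, 7)
  an <- make_const_anomaly(coarse, dt = 0, pf = 1)
  for (m in 1:12) an$dt[, , m] <- vals
  rg <- regrid_anomaly(an, fine)
  ctr_f <- cell_centers(fine, rep(1:18, 21), rep(1:21, each = 18))
  want <- matrix(plane(ctr_f$lon, ctr_f$lat), 18, 21)
  expect_equal(rg$dt[, , 1], want, tolerance = 1e-12)
})

test_that("targets outside the anomaly coverage are an error", {
  coarse <- grid_geometry(5, 5, xmin = 0, ymin = 0, cellsize = 1)
  beyond <- grid_geometry(5, 5, xmin = 3, ymin = 0, cellsize = 1)
  an <- make_const_anomaly(coarse)
  expect_error(regrid_anomaly(an, beyond), "outside the anomaly coverage")
})

test_that("the delta overlay shifts temperature and scales precipitation", {
  cl <- make_climate_grid(test_config(seed = 22, rows = 10, cols = 10))
  zero <- make_const_anomaly(cl$geom)
  expect_equal(apply_delta(cl, zero)$tmin, cl$tmin)
  expect_equal(apply_delta(cl, zero)$prec, cl$prec)

  plus2 <- make_const_anomaly(cl$geom, dt = 2)
  warm <- apply_delta(cl, plus2)
  expect_equal(warm$tmin, cl$tmin + 2)
  expect_equal(warm$tmax, cl$tmax + 2)
  expect_true(all(warm$tmax >= warm$tmin))   # order preserved

  half <- make_const_anomaly(cl$geom, pf = 0.5)
  dry <- apply_delta(cl, half)
  expect_true(all(dry$prec >= 0))
  # MAP of the derived palaeo grid is exactly half the baseline MAP cellwise
  bc0 <- derive_bioclim(cl); bc1 <- derive_bioclim(dry)
  expect_equal(bc1$values[, , "MAP"], bc0$values[, , "MAP"] / 2)
  expect_equal(bc1$values[, , "MSP"], bc0$values[, , "MSP"] / 2)
})

test_that("applying an anomaly then its inverse round-trips the baseline", {
  cfg <- test_config(seed = 23, rows = 12, cols = 12)
  cl <- make_climate_grid(cfg)
  an <- regrid_anomaly(make_anomaly_grid(cfg, "21k"), cl$geom)
  back <- apply_delta(apply_delta(cl, an), inverse_anomaly(an))
  expect_equal(back$tmin, cl$tmin, tolerance = 1e-12)
  expect_equal(back$tmax, cl$tmax, tolerance = 1e-12)
  expect_equal(back$prec, cl$prec, tolerance = 1e-12)
})

test_that("geometry mismatches in the overlay are an error", {
  cl <- make_climate_grid(test_config(seed = 24, rows = 10, cols = 10))
  other <- grid_geometry(5, 5, xmin = -120, ymin = 40, cellsize = 0.2)
  expect_error(apply_delta(cl, make_const_anomaly(other)), "regrid")
})
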