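test_that("monthly-to-daily interpolation honours its basic contracts", {
  expect_equal(monthly_to_daily(rep(3.5, 12)), rep(3.5, 365))
  expect_length(monthly_to_daily(rnorm(12)), 365)
  expect_error(monthly_to_daily(1:5), "12 monthly")

  # alternating series: month-mean reconstruction error bounded by direct
  # evaluation of the interpolant (linear interpolation flattens extremes)
  v <- rep(c(10, -10), 6)
  daily <- monthly_to_daily(v)
  idx <- rep(1:12, MONTH_LENGTHS)
  recon <- tapply(daily, idx, mean)
  # the interpolant is the shared definition: month means must match the
  # independent daily oracle exactly, and the flattening error stays below
  # the series amplitude
  recon_oracle <- tapply(oracle_daily(v), idx, mean)
  expect_equal(as.numeric(recon), as.numeric(recon_oracle), tolerance = 1e-10)
  expect_lt(max(abs(recon - v)), 10)
  expect_gt(max(abs(recon - v)), 0)   # linear interpolation cannot be exact here
})

test_that("degree-days match the brute-force daily oracle", {
  expect_equal(degree_days(rep(5, 12), 5, "above"), 0)
  expect_equal(degree_days(rep(5, 12), 5, "below"), 0)
  expect_equal(degree_days(rep(6, 12), 5, "above"), 365)

  tmean <- 10 + 15 * cos(2 * pi * ((1:12) - 7) / 12)
  expect_equal(degree_days(tmean, 5, "above"), oracle_dd(tmean, 5, "above"),
               tolerance = 1e-10)
  expect_equal(degree_days(tmean, 0, "below"), oracle_dd(tmean, 0, "below"),
               tolerance = 1e-10)
})

test_that("temperature summaries read off the monthly series correctly", {
  expect_equal(temperature_summaries(rep(10, 12)),
               c(MWMT = 10, MCMT = 10, MAT = 10, TD = 0))
  tmean <- c(-5, -3, 0, 5, 10, 15, 20, 19, 14, 8, 2, -4)
  s <- temperature_summaries(tmean)
  expect_equal(unname(s["MWMT"]), 20)
  expect_equal(unname(s["MCMT"]), -5)
  expect_equal(unname(s["TD"]), 25)
  # day-length-weighted annual mean, computed directly
  expect_equal(unname(s["MAT"]),
               sum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) * tmean) / 365)
})

test_that("precipitation summaries sum the right month windows", {
  s <- precipitation_summaries(rep(50, 12))
  expect_equal(s, c(MAP = 600, MSP = 300, MWP = 200))
  july_only <- c(rep(0, 6), 120, rep(0, 5))
  s2 <- precipitation_summaries(july_only)
  expect_equal(unname(s2["MAP"]), unname(s2["MSP"]))
  expect_equal(unname(s2["MWP"]), 0)
  expect_error(precipitation_summaries(c(rep(10, 11), -1)), "non-negative")
  # disjoint month sets
  for (i in 1:10) {
    p <- runif(12, 0, 100)
    s3 <- precipitation_summaries(p)
    expect_lte(s3["MSP"] + s3["MWP"], s3["MAP"] + 1e-12)
  }
})

test_that("frost-free days and snow follow their threshold definitions", {
  expect_equal(unname(frost_and_snow(rep(5, 12), rep(9, 12), rep(10, 12))["NFFD"]),
               365)
  expect_equal(unname(frost_and_snow(rep(-2, 12), rep(2, 12), rep(10, 12))["PAS"]),
               0)
  tmin <- c(-15, -12, -6, -1, 4, 9, 12, 11, 6, 0, -7, -13)
  tmean <- tmin + 4
  fs <- frost_and_snow(tmin, tmean, rep(30, 12))
  expect_equal(unname(fs["NFFD"]), oracle_nffd(tmin))
  expect_equal(unname(fs["PAS"]), 30 * sum(tmean <= 0))
})

test_that("degree-day monotonicity and constant-temperature limits hold", {
  set.seed(7)
  for (i in 1:20) {
    tmean <- runif(12, -20, 25)
    delta <- runif(1, 0.1, 5)
    expect_gte(degree_days(tmean + delta, 5, "above"),
               degree_days(tmean, 5, "above"))
    expect_lte(degree_days(tmean + delta, 0, "below"),
               degree_days(tmean, 0, "below"))
  }
  for (T in c(-12, -3, 2, 7, 19)) {
    expect_equal(degree_days(rep(T, 12), 5, "above"), 365 * max(0, T - 5))
    expect_equal(degree_days(rep(T, 12), 0, "below"), 365 * max(0, -T))
  }
})

test_that("grid derivation equals the scalar operations cellwise", {
  bc <- test_bioclim(seed = 6, rows = 8, cols = 9)
  cl <- make_climate_grid(test_config(seed = 6, rows = 8, cols = 9))
  set.seed(2)
  for (k in 1:12) {
    r <- sample(8, 1); c <- sample(9, 1)
    pt <- bioclim_point(cl$tmin[r, c, ], cl$tmax[r, c, ], cl$prec[r, c, ])
    expect_equal(bc$values[r, c, ], pt)
  }
  # DD5 layer against the independent daily oracle on every cell (72 cells)
  tmean <- (cl$tmin + cl$tmax) / 2
  for (r in 1:8) for (c in 1:9)
    expect_equal(unname(bc$values[r, c, "DD5"]),
                 oracle_dd(tmean[r, c, ], 5, "above"), tolerance = 1e-8)
  # TD identity on every cell
  expect_equal(bc$values[, , "TD"],
               bc$values[, , "MWMT"] - bc$values[, , "MCMT"])
})

test_that("nodata in any input layer propagates to all derived layers", {
  cl <- make_climate_grid(test_config(seed = 8, rows = 5, cols = 5))
  cl$prec[2, 3, 7] <- NA    # one missing precipitation month
  cl$tmin[4, 1, 2] <- NA    # one missing temperature month
  bc <- derive_bioclim(cl)
  expect_true(all(is.na(bc$values[2, 3, ])))
  expect_true(all(is.na(bc$values[4, 1, ])))
  expect_true(all(!is.na(bc$values[1, 1, ])))
  # geometry mismatch among layers errors
  cl$tmin <- cl$tmin[1:4, , , drop = FALSE]
  expect_error(derive_bioclim(cl), "co-registered")
})
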