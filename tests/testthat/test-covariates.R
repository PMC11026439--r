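test_that("the three-row toy reproduces hand arithmetic", {
  st <- mk_series(c(10, 8, 9), years = 2000:2002,
                  f = c(0.2, 0.4, 0.3), sst = c(7, 8, 9),
                  rec = c(100, 50, 80))
  slice <- structure(list(stock_id = "toy", period = "before",
                          years = 2001:2002, data = st$data),
                     class = "period_slice")
  ds <- build_dataset(slice)
  expect_equal(ds$y, c(log(0.8), log(1.125)), tolerance = 1e-12)
  # two lagged values each: z-scores are always -1/sqrt(2), +1/sqrt(2)
  s2 <- 1 / sqrt(2)
  expect_equal(unname(ds$X[, "zF"]), c(-s2, s2), tolerance = 1e-12)
  expect_equal(unname(ds$X[, "zST"]), c(-s2, s2), tolerance = 1e-12)
  expect_equal(unname(ds$X[, "zRec"]), c(-s2, s2), tolerance = 1e-12)
  expect_equal(ds$raw_stats$mean, c(0.3, 7.5, 65), tolerance = 1e-12)
  expect_equal(ds$raw_stats$sd, c(sd(c(0.2, 0.4)), sd(c(7, 8)),
                                  sd(c(50, 80))), tolerance = 1e-12)
})

test_that("doubling biomass each year gives y = ln 2 and telescoping holds", {
  st <- mk_series(2^(0:20))
  sl <- split_periods_at(st, st$data$year[11], wmin = 5, wmax = 10)
  ds <- build_dataset(sl$before)
  expect_equal(ds$y, rep(log(2), length(ds$y)), tolerance = 1e-12)

  sim <- mk_sim_stock(seed = 19)
  slc <- split_periods_at(sim, sim$truth$collapse_year)
  for (per in c("before", "after")) {
    d <- build_dataset(slc[[per]])
    yrs <- range(slc[[per]]$data$year)
    b <- slc[[per]]$data$biomass_mt
    expect_equal(sum(d$y), log(b[length(b)]) - log(b[1]), tolerance = 1e-10)
  }
})

test_that("z columns have mean 0 and sd 1 within 1e-10", {
  sim <- mk_sim_stock(seed = 23)
  slc <- split_periods_at(sim, sim$truth$collapse_year)
  for (per in c("before", "after")) {
    X <- build_dataset(slc[[per]])$X
    expect_true(all(abs(colMeans(X)) < 1e-10))
    expect_equal(unname(apply(X, 2, sd)), rep(1, 3), tolerance = 1e-10)
  }
})

test_that("affine rescaling of raw covariates leaves X unchanged", {
  sim <- mk_sim_stock(seed = 29)
  slc <- split_periods_at(sim, sim$truth$collapse_year)
  X0 <- build_dataset(slc$before)$X
  d2 <- sim$data
  d2$f_per_yr <- 3.7 * d2$f_per_yr + 0.21
  d2$sst_c <- 1.8 * d2$sst_c - 40
  d2$recruitment_n <- 0.001 * d2$recruitment_n + 5
  sim2 <- stock_series("resc", d2)
  X1 <- build_dataset(split_periods_at(sim2, sim$truth$collapse_year)$before)$X
  expect_equal(X1, X0, tolerance = 1e-12)
})

test_that("degenerate covariates and bad slices are rejected", {
  st <- mk_series(2^(0:20), f = rep(0.3, 21))
  sl <- split_periods_at(st, st$data$year[11], wmin = 5, wmax = 10)
  expect_error(build_dataset(sl$before), "constant within the window")
})

test_that("external sst series overrides the stock column", {
  sim <- mk_sim_stock(seed = 31)
  sl <- split_periods_at(sim, sim$truth$collapse_year)
  yrs <- sl$before$data$year
  ext <- stats::setNames(sim$data$sst_c[match(yrs, sim$data$year)] + 2, yrs)
  ds0 <- build_dataset(sl$before)
  ds1 <- build_dataset(sl$before, sst_series = ext)
  # shift drops out of the z-score
  expect_equal(ds1$X[, "zST"], ds0$X[, "zST"], tolerance = 1e-12)
  expect_error(build_dataset(sl$before, sst_series = ext[1:3]),
               "does not cover")
})

test_that("regional averaging reproduces hand arithmetic on a 2x2 grid", {
  # one year, 12 months, 2x2 cells with known values
  temp <- array(NA_real_, dim = c(12, 2, 2))
  vals <- matrix(c(1, 2, 3, 4), 2, 2)
  for (m in 1:12) temp[m, , ] <- vals + m / 10
  fld <- structure(list(temp = temp, years = 2000L, months = 1:12,
                        lat = c(1, 2), lon = c(10, 11)),
                   class = "sst_field")
  bbox_all <- c(lat_min = 0, lat_max = 3, lon_min = 9, lon_max = 12)
  got <- regional_yearly_sst(fld, bbox_all, 2000)
  expect_equal(unname(got), mean(vals) + mean(1:12) / 10, tolerance = 1e-12)
  # single-cell bbox picks that cell's 12-month mean
  bbox_one <- c(lat_min = 1.5, lat_max = 2.5, lon_min = 9.5, lon_max = 10.5)
  got1 <- regional_yearly_sst(fld, bbox_one, 2000)
  expect_equal(unname(got1), vals[2, 1] + mean(1:12) / 10, tolerance = 1e-12)
  # empty bbox errors
  bbox_none <- c(lat_min = 5, lat_max = 6, lon_min = 9, lon_max = 12)
  expect_error(regional_yearly_sst(fld, bbox_none, 2000), "no grid-cell")
  expect_error(regional_yearly_sst(fld, bbox_all, 2001), "not covered")
})

test_that("vif matches closed forms on constructed designs", {
  n <- 40
  # orthonormal centered basis via QR
  set.seed(7)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4] * sqrt(n - 1)
  X_orth <- Q
  colnames(X_orth) <- c("zF", "zST", "zRec")
  v <- vif(mk_dataset(rnorm(n), X_orth))
  expect_equal(unname(v), rep(1, 3), tolerance = 1e-10)

  # two columns with exact sample correlation 0.8, third orthogonal
  Xc <- cbind(zF = Q[, 1], zST = 0.8 * Q[, 1] + 0.6 * Q[, 2], zRec = Q[, 3])
  v2 <- vif(mk_dataset(rnorm(n), Xc))
  expect_equal(unname(v2[c("zF", "zST")]), rep(1 / (1 - 0.64), 2),
               tolerance = 1e-8)
  expect_equal(unname(v2["zRec"]), 1, tolerance = 1e-8)

  # duplicate column: rank deficient
  Xd <- cbind(zF = Q[, 1], zST = Q[, 1], zRec = Q[, 2])
  expect_error(vif(mk_dataset(rnorm(n), Xd)), "rank-deficient")
})

test_that("recruitment/SST coupling inflates VIF as designed", {
  mk <- function(rho) {
    cfg <- scenario_config(stock_id = "c", seed = 101,
                           sst_ar1 = list(mean = 10, rho = 0.2, sd = 1),
                           recruitment = list(meanlog = log(1e6), sdlog = 0.5,
                                              sst_rho = rho))
    st <- simulate_stock(cfg, driver_params_set(
      driver_params(-0.1, -0.2, 0.1, 0.1, 0.1),
      driver_params(0.1, -0.1, 0.1, 0.1, 0.1)))
    ds <- build_dataset(split_periods_at(st, st$truth$collapse_year)$before)
    max(vif(ds))
  }
  expect_gt(mk(0.95), mk(0))
})
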