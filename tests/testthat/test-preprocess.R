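make_fine <- function(nlat = 20, nlon = 20, nt = 2, res = 0.25, seed = 1) {
  set.seed(seed)
  monthly_grid(array(runif(nlat * nlon * nt, 0, 5), c(nlat, nlon, nt)),
               lat = seq(res / 2, by = res, length.out = nlat),
               lon = seq(res / 2, by = res, length.out = nlon),
               units = "ha")
}

test_that("burned-area block-sum remapping conserves totals", {
  fine <- make_fine()
  fine[] <- 1
  coarse <- remap_ba_sum(fine, 10)
  expect_true(all(coarse == 100))

  fine <- make_fine(seed = 2)
  coarse <- remap_ba_sum(fine, 10)
  expect_equal(sum(coarse), sum(fine), tolerance = 1e-12)
  for (k in 1:2)
    expect_equal(coarse[, , k], oracle_blocksum(fine[, , k], 10),
                 tolerance = 1e-10)
  expect_error(remap_ba_sum(fine, 7), "multiples")
})

test_that("missing fine burned-area cells count as zero, with a diagnostic", {
  fine <- make_fine(10, 10, 1)
  fine[1, 1, 1] <- NA
  coarse <- remap_ba_sum(fine, 10)
  expect_equal(coarse[1, 1, 1], sum(fine[, , 1], na.rm = TRUE))
  expect_equal(attr(coarse, "missing_fraction")[1, 1, 1], 0.01)
})

test_that("bilinear remapping reproduces constants and linear fields", {
  g <- monthly_grid(array(3.5, c(5, 6, 1)), lat = 0:4 * 2, lon = 0:5 * 2)
  out <- remap_bilinear(g, lat_out = c(1, 3), lon_out = c(2, 7))
  expect_true(all(out == 3.5))

  lat <- 0:9; lon <- 0:9
  fld <- outer(lat, lon, function(a, b) 2 * a - 0.5 * b + 1)
  g <- monthly_grid(array(fld, c(10, 10, 1)), lat, lon)
  lat_t <- c(0.3, 4.7, 8.1); lon_t <- c(1.25, 6.5)
  out <- remap_bilinear(g, lat_t, lon_t)
  expect_equal(out[, , 1],
               outer(lat_t, lon_t, function(a, b) 2 * a - 0.5 * b + 1),
               tolerance = 1e-12)
})

test_that("conservative remapping preserves the area-weighted mean", {
  g <- monthly_grid(array(2.2, c(8, 8, 1)), lat = (0:7) + 0.5,
                    lon = (0:7) + 0.5)
  out <- remap_conservative(g, lat_out = c(2, 6), lon_out = c(2, 6))
  expect_equal(as.vector(out[, , 1]), rep(2.2, 4), tolerance = 1e-12)

  set.seed(3)
  lat_f <- seq(0.5, 19.5, by = 1); lon_f <- seq(0.5, 19.5, by = 1)
  g <- monthly_grid(array(rnorm(400, 10, 3), c(20, 20, 1)), lat_f, lon_f)
  lat_c <- c(2.5, 7.5, 12.5, 17.5); lon_c <- lat_c
  out <- remap_conservative(g, lat_c, lon_c)
  # oracle: explicit spherical cell areas on the nesting 5x5 blocks
  band <- function(lo, hi) sin(hi * pi / 180) - sin(lo * pi / 180)
  area_f <- outer(band(lat_f - 0.5, lat_f + 0.5), rep(1, 20))
  area_c <- outer(band(lat_c - 2.5, lat_c + 2.5), rep(5, 4))
  expect_equal(sum(out[, , 1] * area_c), sum(g[, , 1] * area_f),
               tolerance = 1e-10)
  # block oracle for one coarse cell
  w <- area_f[6:10, 6:10]
  expect_equal(out[2, 2, 1], sum(g[6:10, 6:10, 1] * w) / sum(w),
               tolerance = 1e-10)
})

test_that("seasonal totals follow the season calendar, DJF included", {
  x <- rep(0, 36); x[18] <- 2; x[19] <- 3; x[20] <- 5   # Jun-Aug of year 2
  g <- grid1(x, units = "ha")
  tot <- seasonal_total(g, season_spec("JJA"))
  yrs <- attr(tot, "years")
  expect_equal(tot[1, 1, yrs == 2], 10)
  expect_equal(tot[1, 1, yrs == 3], 0)

  # DJF of year 2 = Dec year 1 + Jan/Feb year 2
  x <- rep(0, 36); x[12] <- 7; x[13] <- 1; x[14] <- 2
  tot <- seasonal_total(grid1(x, units = "ha"), season_spec("DJF"))
  yrs <- attr(tot, "years")
  expect_equal(tot[1, 1, yrs == 2], 10)
  # year 1 has no prior December: DJF season-year 1 must not be labelled
  expect_false(1 %in% yrs)

  x[13] <- NA
  tot <- seasonal_total(grid1(x, units = "ha"), season_spec("DJF"))
  expect_true(is.na(tot[1, 1, attr(tot, "years") == 2]))

  set.seed(4)
  x <- rgamma(60, 1, scale = 10)
  tot <- seasonal_total(grid1(x, units = "ha"), season_spec("SON"))
  yrs <- attr(tot, "years")
  for (k in seq_along(yrs))
    expect_equal(tot[1, 1, k], sum(x[(yrs[k] - 1) * 12 + 9:11]),
                 tolerance = 1e-12)
})

test_that("burnable mask requires nonzero seasons in more than half the years", {
  mk <- function(nonzero, n = 21) {
    v <- c(rep(1, nonzero), rep(0, n - nonzero))
    seasonal_series(array(v, c(1, 1, n)), 0, 0, season_spec("JJA"), 1:n)
  }
  expect_true(burnable_mask(mk(11))[1, 1])
  expect_false(burnable_mask(mk(10))[1, 1])
  expect_false(burnable_mask(mk(0))[1, 1])
  # invariant to positive rescaling
  v <- mk(13); v[] <- v[] * 1e6
  expect_true(burnable_mask(v)[1, 1])
  # general n: 5 of 8 eligible, 4 of 8 not
  expect_true(burnable_mask(mk(5, 8))[1, 1])
  expect_false(burnable_mask(mk(4, 8))[1, 1])
})

test_that("robust detrending resists outliers and matches its oracle", {
  yr <- 1:21
  lin <- 3 + 0.5 * yr
  fit <- robust_detrend(lin)
  expect_equal(fit$residuals, rep(0, 21), tolerance = 1e-10)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)

  set.seed(5)
  y <- 3 + 0.5 * yr + rnorm(21, sd = 0.2)
  y[8] <- y[8] + 30                      # one gross outlier
  rob <- robust_detrend(y)$slope
  ols <- coef(lm(y ~ yr))[[2]]
  expect_lt(abs(rob - 0.5), abs(ols - 0.5))

  # matches the plain-R IRLS oracle
  or <- oracle_irls(cbind(1, yr), y)
  expect_equal(robust_detrend(y)$slope, or[2], tolerance = 1e-6)

  # cross-check against MASS::rlm with the same psi (looser: different
  # scale-update details)
  skip_if_not_installed("MASS")
  m <- MASS::rlm(y ~ yr, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(robust_detrend(y)$slope, coef(m)[[2]], tolerance = 0.02)

  # zero-slope noise: slope near 0 over replicates (the occasional
  # non-convergent IRLS falls back to OLS with a warning, by design)
  set.seed(6)
  sl <- suppressWarnings(replicate(200, robust_detrend(rnorm(21))$slope))
  expect_lt(abs(mean(sl)), 0.02)
})

test_that("moment standardization is exact and flags degenerate series", {
  set.seed(7)
  x <- rnorm(21, 5, 2)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(z, (x - mean(x)) / sd(x), tolerance = 1e-12)
  expect_warning(out <- standardize(rep(4, 10)), "zero-variance")
  expect_true(all(is.na(out)))
})
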