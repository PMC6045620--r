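test_that("accumulate matches hand sums and the brute-force oracle", {
  expect_equal(accumulate(c(1, 1, 1, 1), 3), c(NA, NA, 3, 3))
  expect_equal(accumulate(c(0, 10, 0, 5), 3), c(NA, NA, 10, 15))
  set.seed(1)
  x <- rgamma(120, 2, scale = 40)
  for (t in c(3, 6, 12))
    expect_equal(accumulate(x, t), oracle_rollsum(x, t), tolerance = 1e-10)
  expect_warning(out <- accumulate(1:3, 5), "longer than the series")
  expect_length(out, 0)
})

test_that("empirical standardization has the documented rank properties", {
  expect_warning(z <- empirical_standardize(rep(2, 10)), "tied")
  expect_equal(z, rep(0, 10))

  set.seed(2)
  v <- rnorm(21)
  z <- empirical_standardize(v)
  # odd n, distinct values: plotting positions are symmetric around 1/2
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), sd(qnorm(((1:21) - 0.44) / 21.12)), tolerance = 1e-12)
  expect_equal(z, oracle_gringorten(v), tolerance = 1e-10)
  # monotone: larger value never maps to a smaller index
  expect_true(all(diff(z[order(v)]) >= 0))

  zw <- empirical_standardize(v, pp = "weibull")
  expect_equal(zw, qnorm(rank(v) / 22), tolerance = 1e-12)

  expect_warning(small <- empirical_standardize(rnorm(5)), "returning missing")
  expect_true(all(is.na(small)))
})

test_that("SPI is rank-invariant, local, and calibrated on long series", {
  set.seed(3)
  pr <- grid1(rgamma(600, 2, scale = 50))
  spi <- compute_spi(pr, 3)
  # uniform rescaling leaves ranks, hence the index, unchanged
  pr2 <- grid1(2 * as.vector(pr))
  expect_equal(as.vector(compute_spi(pr2, 3)), as.vector(spi))
  # t = 3: perturbing month 100 can only move windows ending in 100..102,
  # i.e. only the three affected calendar-month samples can re-rank
  pr3 <- as.vector(pr); pr3[100] <- pr3[100] + 500
  spi3 <- compute_spi(grid1(pr3), 3)
  a <- as.vector(spi); b <- as.vector(spi3)
  changed <- which(a != b)
  affected_cal <- (((100:102) - 1) %% 12) + 1
  expect_true(length(changed) > 0)
  expect_true(all((((changed - 1) %% 12) + 1) %in% affected_cal))

  # long-series calibration: per-calendar-month mean ~ 0, sd ~ 1
  set.seed(4)
  long <- grid1(rgamma(600, 2, scale = 50))
  z <- as.vector(compute_spi(long, 6))
  cal <- rep(1:12, 50)
  for (cm in c(1, 7)) {
    g <- z[cal == cm & !is.na(z)]
    expect_lt(abs(mean(g)), 0.05)
    expect_lt(abs(sd(g) - 1), 0.06)
  }
})

test_that("SPI equals a naive double-loop oracle on a small grid", {
  set.seed(5)
  d <- c(2, 2, 120)
  pr <- monthly_grid(array(rgamma(prod(d), 2, scale = 50), d),
                     lat = c(0, 2.5), lon = c(0, 2.5), units = "mm/month")
  spi <- compute_spi(pr, 6)
  for (i in 1:2) for (j in 1:2) {
    acc <- oracle_rollsum(pr[i, j, ], 6)
    want <- rep(NA_real_, 120)
    for (cm in 1:12) {
      idx <- which(rep(1:12, 10) == cm & !is.na(acc))
      want[idx] <- oracle_gringorten(acc[idx])
    }
    expect_equal(spi[i, j, ], want, tolerance = 1e-10)
  }
})

test_that("Thornthwaite PET has the cold limit, oracle value and monotonicity", {
  cold <- grid1(rep(-5, 24), units = "degC")
  expect_true(all(compute_pet_thornthwaite(cold) == 0))

  warm <- grid1(rep(20, 24), units = "degC")   # constant 20 degC at equator
  pet <- compute_pet_thornthwaite(warm)
  for (m in 1:12)
    expect_equal(pet[1, 1, m],
                 oracle_thornthwaite_month(20, rep(20, 12), 0, m),
                 tolerance = 1e-10)
  # all 30-day months get identical PET at the equator (12 h day length)
  d30 <- c(4, 6, 9, 11)
  expect_equal(diff(pet[1, 1, d30]), rep(0, 3), tolerance = 1e-9)

  # PET strictly increasing in the month's own temperature above 0
  warm2 <- as.vector(warm); warm2[7] <- 25
  pet2 <- compute_pet_thornthwaite(grid1(warm2, units = "degC"))
  expect_gt(pet2[1, 1, 7], pet[1, 1, 7])

  expect_error(compute_pet_thornthwaite(warm, latitudes = 95), "90")
})

test_that("SPEI reduces to SPI in the cold limit and is shift-invariant", {
  set.seed(6)
  n <- 240
  pr <- grid1(rgamma(n, 2, scale = 50))
  cold <- grid1(rep(-2, n), units = "degC")
  expect_equal(as.vector(compute_spei(pr, cold, 6)),
               as.vector(compute_spi(pr, 6)))
  # adding a constant to every month's water balance preserves ranks
  pr2 <- grid1(as.vector(pr) + 30)
  expect_equal(as.vector(compute_spei(pr2, cold, 6)),
               as.vector(compute_spi(pr, 6)))
  # oracle composition on a warm cell
  tmp <- grid1(rep(c(5, 10, 18, 24, 25, 20, 15, 8, 4, 2, 1, 3), n / 12),
               units = "degC")
  spei <- compute_spei(pr, tmp, 3)
  wb <- as.vector(pr) - as.vector(compute_pet_thornthwaite(tmp))
  acc <- oracle_rollsum(wb, 3)
  cal <- rep(1:12, n / 12)
  for (cm in c(2, 8)) {
    idx <- which(cal == cm & !is.na(acc))
    expect_equal(spei[1, 1, idx], oracle_gringorten(acc[idx]),
                 tolerance = 1e-10)
  }
})

test_that("temperature indicator is an exact per-month z-score", {
  set.seed(7)
  tm <- grid1(rnorm(240, 15, 3), units = "degC")
  ti <- compute_t_index(tm, 3)
  cal <- rep(1:12, 20)
  acc <- oracle_rollsum(as.vector(tm), 3) / 3
  for (cm in c(1, 6, 12)) {
    idx <- which(cal == cm & !is.na(acc))
    g <- ti[1, 1, idx]
    expect_equal(mean(g), 0, tolerance = 1e-12)
    expect_equal(sd(g), 1, tolerance = 1e-12)
    expect_equal(g, (acc[idx] - mean(acc[idx])) / sd(acc[idx]),
                 tolerance = 1e-12)
  }
  const <- grid1(rep(10, 240), units = "degC")
  expect_true(all(is.na(as.vector(compute_t_index(const, 3)))))
})

test_that("indicator specs validate their domain", {
  expect_error(indicator_spec("SPI", t = 4, lag = 0), "3, 6, 12")
  expect_error(indicator_spec("SPI", t = 3, lag = 6), "0..5")
  sp <- indicator_spec("SPEI", 12, 5)
  expect_equal(sp$t, 12L)
})
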