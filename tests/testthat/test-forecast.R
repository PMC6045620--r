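# shared small world for the forecast tests
fc_world <- local({
  sc <- synthetic_scenario(2, 2, seed = 40)
  cl <- generate_climate(sc)
  ba <- generate_ba(sc, cl$precip)
  list(sc = sc, cl = cl, ba = ba)
})

test_that("bias correction leaves an unbiased archive unchanged to machine precision", {
  w <- fc_world
  sp <- pseudo_forecast_spec("perfect", alpha = 1, seed = 1)
  arc <- generate_forecast_system(sp, w$cl$precip, w$cl$temp, w$sc$ba_years)
  cor <- bias_correct(arc, w$cl$precip, w$cl$temp)
  expect_identical(cor$precip, arc$precip)
  expect_identical(cor$temp, arc$temp)
  expect_true(cor$bias_corrected)
})

test_that("bias correction closes a multiplicative precipitation bias", {
  w <- fc_world
  sp <- pseudo_forecast_spec("wet", alpha = 0.7, precip_bias = 1.3,
                             temp_bias = 2, seed = 2)
  arc <- generate_forecast_system(sp, w$cl$precip, w$cl$temp, w$sc$ba_years)
  cor <- bias_correct(arc, w$cl$precip, w$cl$temp)
  for (l in c(0L, 3L)) {
    tgt <- firecast:::normalize_ym(w$sc$ba_years + arc$issue_year_offset,
                                   arc$issue_month + l)
    ti <- firecast:::month_index(w$cl$precip, tgt$year, tgt$month)
    ratio <- mean(cor$precip[1, 1, l + 1, ]) / mean(w$cl$precip[1, 1, ti])
    expect_equal(ratio, 1, tolerance = 0.05)
    offset <- mean(cor$temp[2, 2, l + 1, ]) - mean(w$cl$temp[2, 2, ti])
    expect_lt(abs(offset), 0.6)
  }
})

test_that("the forecast year's own value never informs its scaling factor", {
  w <- fc_world
  sp <- pseudo_forecast_spec("wet", alpha = 0.7, precip_bias = 1.3, seed = 3)
  arc <- generate_forecast_system(sp, w$cl$precip, w$cl$temp, w$sc$ba_years)
  cor1 <- bias_correct(arc, w$cl$precip, w$cl$temp)
  # doubling year 5's raw forecast doubles its corrected value exactly:
  # the factor applied to year 5 is computed from the other years only
  arc2 <- arc
  arc2$precip[, , 2, 5] <- 2 * arc$precip[, , 2, 5]
  cor2 <- bias_correct(arc2, w$cl$precip, w$cl$temp)
  expect_equal(cor2$precip[, , 2, 5], 2 * cor1$precip[, , 2, 5],
               tolerance = 1e-12)
})

test_that("merging respects the issue date and the archive's lead range", {
  obs <- 1:60
  fc <- c(100, 200, 300, 400, 500)     # leads 0..4
  # issue at index 41: window ending at 38 (t=3) is purely observational
  expect_equal(merge_window_sum(obs, fc, 41L, 38L, 3L), 36 + 37 + 38)
  # window ending at 43 with t=3 is purely forecast (leads 0..2)
  expect_equal(merge_window_sum(obs, fc, 41L, 43L, 3L), 100 + 200 + 300)
  # window straddling the issue date mixes both sources
  expect_equal(merge_window_sum(obs, fc, 41L, 42L, 6L),
               37 + 38 + 39 + 40 + 100 + 200)
  expect_error(merge_window_sum(obs, fc, 41L, 46L, 3L), "beyond")
  expect_error(merge_window_sum(obs, fc, 41L, 2L, 6L), "before the observed")
})

test_that("perfect forecasts reproduce the observed indicator exactly", {
  w <- fc_world
  sp <- pseudo_forecast_spec("perfect", alpha = 1, seed = 4)
  arc <- bias_correct(
    generate_forecast_system(sp, w$cl$precip, w$cl$temp, w$sc$ba_years),
    w$cl$precip, w$cl$temp)
  season <- season_spec("JJA")
  for (t in c(3L, 12L)) for (lag in c(0L, 4L)) {
    fi <- forecast_indicator(w$cl$precip, arc, t, lag, season)
    cube <- compute_spi(w$cl$precip, t)
    oi <- indicator_series(cube, season, lag, w$sc$ba_years)
    expect_identical(unclass(fi)[, , ], unclass(oi)[, , ])
  }
})

test_that("skill-free forecasts degrade the merged indicator", {
  w <- fc_world
  sp <- pseudo_forecast_spec("none", alpha = 0, seed = 5)
  arc <- bias_correct(
    generate_forecast_system(sp, w$cl$precip, w$cl$temp, w$sc$ba_years),
    w$cl$precip, w$cl$temp)
  season <- season_spec("JJA")
  # lag 0, t = 3: the window is entirely forecast, so correlation with the
  # observed index should be weak across the 21 issue years x 4 cells
  fi <- forecast_indicator(w$cl$precip, arc, 3L, 0L, season)
  oi <- indicator_series(compute_spi(w$cl$precip, 3L), season, 0L,
                         w$sc$ba_years)
  r <- cor(as.vector(unclass(fi)), as.vector(unclass(oi)))
  expect_lt(abs(r), 0.35)
  # monotone: a wetter merged accumulation never lowers the index
  expect_true(all(is.finite(as.vector(unclass(fi)))))
})

test_that("ensembles average archives and best-k selection is deterministic", {
  w <- fc_world
  sp <- pseudo_forecast_spec("a", alpha = 0.8, seed = 6)
  arc <- generate_forecast_system(sp, w$cl$precip, w$cl$temp, w$sc$ba_years)
  ens <- ensemble_mean(list(arc, arc, arc))
  expect_equal(ens$precip, arc$precip, tolerance = 1e-14)

  skill <- c(s1 = 10, s2 = 40, s3 = 25, s4 = 40, s5 = 5)
  expect_equal(select_best_systems(skill, 3), c("s2", "s4", "s3"))
  expect_equal(sort(select_best_systems(skill, 5)), sort(names(skill)))

  # two systems with independent noise beat one: ensemble anomaly keeps
  # the common signal and halves the noise variance
  sc <- synthetic_scenario(1, 1, n_years = 150, spinup_years = 0, seed = 41)
  cl <- generate_climate(sc)
  s1 <- generate_forecast_system(pseudo_forecast_spec("x", 0.7, seed = 7),
                                 cl$precip, cl$temp, sc$ba_years)
  s2 <- generate_forecast_system(pseudo_forecast_spec("y", 0.7, seed = 8),
                                 cl$precip, cl$temp, sc$ba_years)
  e <- ensemble_mean(list(s1, s2))
  tgt <- firecast:::normalize_ym(sc$ba_years + s1$issue_year_offset,
                                 s1$issue_month + 2)
  ti <- firecast:::month_index(cl$temp, tgt$year, tgt$month)
  r1 <- cor(s1$temp[1, 1, 3, ], cl$temp[1, 1, ti])
  re <- cor(e$temp[1, 1, 3, ], cl$temp[1, 1, ti])
  expect_gt(re, r1)
})
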