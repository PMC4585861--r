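p <- oil_palm_params()

test_that("temperature and moisture trapezoids hit their landmark values", {
  expect_equal(temperature_index(26, p), 1)    # optimal plateau 24-28
  expect_equal(temperature_index(19, p), 0)    # at DV0
  expect_equal(temperature_index(32, p), 0.5)  # midpoint of 28 -> 36 ramp
  expect_equal(temperature_index(c(-40, 21.5, 36, 50), p),
               c(0, 0.5, 0, 0))

  expect_equal(moisture_index(1.0, p), 1)      # plateau 0.6-1.6
  expect_equal(moisture_index(0.4, p), 0)      # at SM0
  expect_equal(moisture_index(1.8, p), 0.5)    # midpoint of 1.6 -> 2 ramp
  expect_equal(moisture_index(c(0, 0.5, 2, 2.5), p), c(0, 0.5, 0, 0))
})

test_that("annual growth index averages weekly growth onto 0-100", {
  expect_equal(annual_growth_index(rep(1, 52)), 100)
  expect_equal(annual_growth_index(rep(0, 52)), 0)
  expect_equal(annual_growth_index(c(rep(1, 26), rep(0, 26))), 50)
})

test_that("stress accumulators reproduce the hand computations exactly", {
  # 4 weeks at t_min = 10 (5 degC below TTCS), ample degree-days
  wk <- constant_weekly()
  t_min <- rep(22, 52); t_min[1:4] <- 10
  wk_cold <- weekly_climate(t_min, rep(30, 52), rep(50, 52), rep(80, 52),
                            t_avg = rep(26, 52))
  dd_ample <- matrix(50, 1, 52)
  expect_equal(cold_stress(wk_cold, dd_ample, p), 100 * 0.005 * 5 * 4)

  # t_avg at DV0 all year: dd = 0, degree-day mechanism gives 52
  wk_dd <- weekly_climate(rep(19, 52), rep(19, 52), rep(50, 52), rep(80, 52))
  dd0 <- degree_days(wk_dd$t_avg, p)
  expect_equal(as.vector(dd0), rep(0, 52))
  expect_equal(cold_stress(wk_dd, dd0, p), 100 * 0.0005 * 20 * 52)

  # heat: at the threshold no stress; one week 2 degC over; all-year 10 over
  expect_equal(heat_stress(constant_weekly(t_max = 36), p), 0)
  t_max <- rep(30, 52); t_max[10] <- 38
  expect_equal(heat_stress(weekly_climate(rep(20, 52), t_max, rep(50, 52),
                                          rep(80, 52)), p),
               100 * 0.001 * 2)
  expect_equal(heat_stress(constant_weekly(t_max = 46), p),
               100 * 0.001 * 10 * 52)

  # dry: at threshold zero; 0.2 and 0.0 all year
  expect_equal(dry_stress(rep(0.4, 52), p), 0)
  expect_equal(dry_stress(rep(0.2, 52), p), 100 * 0.007 * 0.2 * 52)
  expect_equal(dry_stress(rep(0, 52), p), 100 * 0.007 * 0.4 * 52)

  # wet: at threshold zero; at the 2.5 cap all year; below threshold zero
  expect_equal(wet_stress(rep(2, 52), p), 0)
  expect_equal(wet_stress(rep(2.5, 52), p), 100 * 0.0023 * 0.5 * 52)
  expect_equal(wet_stress(rep(0.8, 52), p), 0)
})

test_that("EI composes growth and stresses multiplicatively with a hard degree-day gate", {
  expect_equal(ecoclimatic_index(80, 0, 0, 0, 0, 2000, p), 80)
  expect_equal(ecoclimatic_index(80, 100, 0, 0, 0, 2000, p), 0)
  expect_equal(ecoclimatic_index(80, 0, 0, 100, 0, 2000, p), 0)
  expect_equal(ecoclimatic_index(50, 20, 10, 0, 0, 2000, p), 50 * 0.8 * 0.9)
  # below the degree-day threshold the index is annihilated
  expect_equal(ecoclimatic_index(80, 0, 0, 0, 0, 1499.9, p), 0)
  expect_equal(ecoclimatic_index(80, 0, 0, 0, 0, 1500, p), 80)
})

test_that("vectorized accumulators equal a literal-loop oracle on random weekly series", {
  wk <- random_weekly_climate(1000, seed = 101)
  sms <- soil_moisture_balance(wk, p)
  dd <- degree_days(wk$t_avg, p)
  cs <- cold_stress(wk, dd, p)
  hs <- heat_stress(wk, p)
  ds <- dry_stress(sms, p)
  ws <- wet_stress(sms, p)
  ti <- temperature_index(wk$t_avg, p)
  mi <- moisture_index(sms$sm, p)
  gia <- annual_growth_index(ti * mi)
  for (i in seq_len(nrow(wk$t_min))) {
    ref <- oracle_stresses(wk$t_min[i, ], wk$t_max[i, ], wk$t_avg[i, ],
                           sms$sm[i, ], dd[i, ], p)
    expect_equal(cs[i], ref$CS, tolerance = 1e-12)
    expect_equal(hs[i], ref$HS, tolerance = 1e-12)
    expect_equal(ds[i], ref$DS, tolerance = 1e-12)
    expect_equal(ws[i], ref$WS, tolerance = 1e-12)
    expect_equal(gia[i], oracle_growth(wk$t_avg[i, ], sms$sm[i, ], p),
                 tolerance = 1e-12)
  }
})

test_that("with all stress rates zero and no degree-day gate, EI equals GIA", {
  relaxed <- unclass(p)
  relaxed$THCS <- 0; relaxed$DHCS <- 0; relaxed$THHS <- 0
  relaxed$HDS <- 0; relaxed$HWS <- 0; relaxed$PDD <- 0
  p0 <- do.call(climex_params, relaxed)
  wk <- random_weekly_climate(50, seed = 5)
  res <- run_weekly(wk, p0)
  expect_identical(res$EI, res$GIA)
})

test_that("EI stays within [0, 100] and responds monotonically to stress rates", {
  wk <- random_weekly_climate(300, seed = 17)
  res <- run_weekly(wk, p)
  expect_true(all(res$EI >= 0 & res$EI <= 100))
  expect_true(all(res$GIA >= 0 & res$GIA <= 100))
  expect_true(all(res$EI <= res$GIA + 1e-12))

  harsher <- unclass(p)
  harsher$THCS <- -0.01; harsher$HDS <- -0.014; harsher$THHS <- 0.002
  harsher$HWS <- 0.0046
  p2 <- do.call(climex_params, harsher)
  res2 <- run_weekly(wk, p2)
  expect_true(all(res2$EI <= res$EI + 1e-12))
})

test_that("warming a series already past the heat threshold never lowers heat stress", {
  wk <- random_weekly_climate(100, seed = 23)
  hot <- weekly_climate(wk$t_min + 3, wk$t_max + 3, wk$precip, wk$rh_mean)
  expect_true(all(heat_stress(hot, p) >= heat_stress(wk, p)))
})

test_that("grid runs equal cell-by-cell runs and propagate the mask", {
  clim <- toy_climatology(mask_out = cbind(1, 2))
  res_grid <- run_grid(clim, p)
  wk <- to_weekly(clim)
  res_cells <- run_weekly(wk, p)
  expect_equal(res_grid$EI[clim$mask], res_cells$EI)
  expect_equal(res_grid$CS[clim$mask], res_cells$CS)
  expect_true(all(is.na(res_grid$EI[!clim$mask])))
  expect_true(all(is.na(res_grid$class_code[!clim$mask])))

  # single-cell path gives the same numbers as the grid row
  one <- toy_climatology(n_lat = 1L, n_lon = 1L)
  expect_equal(run_cell(one, p)$EI, run_grid(one, p)$EI[1, 1])
})

test_that("a cell below the development threshold year-round scores zero", {
  grid <- grid_definition(100, 2, 1, 1, 1)
  arr <- function(v) array(v, c(1, 1, 12))
  cold <- monthly_climatology(grid, arr(10), arr(20), arr(150),
                              arr(85), arr(65))
  res <- run_cell(cold, p)  # t_avg = 15 in every week
  expect_equal(res$annual_dd, 0)
  expect_equal(res$EI, 0)
  expect_equal(as.character(res$class), "unsuitable")
})
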