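test_that("generator is fully reproducible from config and seed", {
  cfg <- scenario_config(c(2001, 2003), seed = 31)
  a <- generate_daily_weather(cfg)
  b <- generate_daily_weather(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # a different seed changes the realisation
  c_ <- generate_daily_weather(scenario_config(c(2001, 2003), seed = 32))
  expect_false(identical(a$precip_mm, c_$precip_mm))
})

test_that("zero-noise deterministic config repeats the seasonal climatology", {
  cfg <- scenario_config(c(2001, 2002), seed = 1,
                         temp_noise_sd = 0, et0_noise_sd = 0,
                         temp_trend = 0, et_trend = 0,
                         et0_mode = "direct", precip_mode = "climatology")
  wx <- generate_daily_weather(cfg)
  y1 <- wx[wx$year == 2001, ]
  y2 <- wx[wx$year == 2002, ]
  common <- intersect(y1$doy, y2$doy)
  for (col in c("tmean_c", "precip_mm", "et0_mm")) {
    expect_equal(y1[[col]][match(common, y1$doy)],
                 y2[[col]][match(common, y2$doy)])
  }
})

test_that("configured warming trend is recovered from annual means", {
  slopes <- vapply(1:20, function(seed) {
    wx <- generate_daily_weather(scenario_config(
      c(2011, 2070), seed = seed, temp_trend = 1.7, et0_mode = "direct"
    ))
    ann <- dplyr::summarise(dplyr::group_by(wx, year),
                            t = mean(tmean_c), .groups = "drop")
    unname(coef(lm(t ~ year, data = ann))[2])
  }, numeric(1))
  recovered <- mean(slopes) * 60
  expect_lt(abs(recovered - 1.7), 0.3)
})

test_that("annual precipitation matches the configured mean across seeds", {
  totals <- vapply(1:20, function(seed) {
    wx <- generate_daily_weather(scenario_config(
      c(2001, 2010), seed = seed, et0_mode = "direct"
    ))
    mean(annual_precip(wx)$precip_mm)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 654.4) / 654.4, 0.05)
})

test_that("generated ET0 is non-negative with a summer-peaking seasonal cycle", {
  wx <- generate_daily_weather(scenario_config(c(2001, 2004), seed = 8))
  expect_true(all(wx$et0_mm >= 0))
  mo <- as.integer(strftime(wx$date, "%m"))
  expect_gt(mean(wx$et0_mm[mo %in% 6:8]), mean(wx$et0_mm[mo %in% c(12, 1, 2)]))
  # penman mode keeps its drivers and they satisfy ea <= es
  expect_true(all(c("rn_mj", "u2_ms", "es_kpa", "ea_kpa") %in% names(wx)))
  expect_true(all(wx$ea_kpa <= wx$es_kpa + 1e-9))
})

test_that("scenario presets carry the configured contrasts", {
  tmax <- scenario_preset("Tmax", seed = 1)
  expect_equal(tmax$temp_trend, 1.7)
  expect_equal(tmax$et_trend, 28.4)
  expect_equal(tmax$annual_precip_mean, 654.4 + 14.1)
  obs <- scenario_preset("observation", seed = 1)
  expect_equal(obs$year_range, c(1951L, 2010L))
  expect_equal(obs$temp_trend, 0)
  expect_error(scenario_config(c(2001, 2000), seed = 1), "last >= first")
  expect_error(scenario_config(c(2001, 2002), seed = 1,
                               annual_precip_mean = -5), "positive")
  expect_error(scenario_config(c(2001, 2002)), "seed")
})

test_that("reference ET0 reproduces the FAO-56 worked example and its limits", {
  # Uccle, 6 July: Tmean 16.9 C, Rn 13.28 MJ/m2/d, G 0, u2 2.078 m/s,
  # es 1.997 kPa, ea 1.409 kPa, P 100.1 kPa -> guideline prints 3.9 mm/day
  et0 <- et0_penman_monteith(16.9, 13.28, 0, 2.078, 1.997, 1.409, 100.1)
  expect_lt(abs(et0 - 3.9), 0.05)

  # both numerator terms vanish
  expect_equal(et0_penman_monteith(20, 5, 5, 2, 2.0, 2.0), 0)

  # radiation-only limit at zero wind and saturated air
  tm <- 18
  delta <- 4098 * sat_vapour_pressure(tm) / (tm + 237.3)^2
  gamma <- 0.665e-3 * 101.3
  expect_equal(et0_penman_monteith(tm, 12, 0, 0, 1.5, 1.5),
               0.408 * delta * 12 / (delta + gamma))

  # monotone in vapour pressure deficit
  lo <- et0_penman_monteith(16.9, 13.28, 0, 2.078, 1.997, 1.6)
  hi <- et0_penman_monteith(16.9, 13.28, 0, 2.078, 1.997, 1.2)
  expect_gt(hi, lo)

  # negative net radiation floors at zero, never a water gain
  expect_equal(et0_penman_monteith(5, -8, 0, 0, 0.9, 0.9), 0)

  expect_error(et0_penman_monteith(16.9, NA, 0, 2, 1.9, 1.4), "Missing")
  expect_error(et0_penman_monteith(16.9, 13.28, 0, 2, 1.4, 1.9), "exceeds")
})

test_that("climate CSV round-trips exactly and rejects malformed files", {
  wx <- generate_daily_weather(scenario_config(c(2001, 2002), seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_climate_csv(wx, path)
  back <- read_climate_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(wx))

  # gap: drop a mid-year day
  gap <- wx[wx$date != as.Date("2001-06-10"), ]
  p2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(as.data.frame(gap), -year, -doy), p2)
  expect_error(read_climate_csv(p2), "2001-06-10")

  # negative precipitation names the row
  bad <- wx
  bad$precip_mm[100] <- -1.0
  p3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(as.data.frame(bad), -year, -doy), p3)
  expect_error(read_climate_csv(p3), "row 100")

  # duplicated date
  dup <- rbind(as.data.frame(wx[1:50, ]), as.data.frame(wx[50, ]))
  dup <- dup[order(dup$date), ]
  p4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dplyr::select(dup, -year, -doy), p4)
  expect_error(read_climate_csv(p4), "Duplicated")
})

test_that("quantile-year selection matches a sort-and-interpolate oracle", {
  years <- 2001:2010
  totals <- seq(100, 1000, by = 100)
  wx <- flat_climate(years, et0 = 1)
  days_per_year <- table(wx$year)
  wx$precip_mm <- rep(totals / as.integer(days_per_year),
                      as.integer(days_per_year))
  got <- select_quantile_years(wx, c(0.1, 0.5, 0.9))
  expect_equal(nrow(got), 3)
  for (i in seq_len(3)) {
    q <- oracle_quantile(totals, got$prob[i])
    expect_equal(got$year[i], years[which.min(abs(totals - q))])
  }

  # identical totals: earliest year wins every probability
  wx2 <- flat_climate(2001:2003, precip = 2, et0 = 1)
  got2 <- select_quantile_years(wx2, c(0.1, 0.5, 0.9))
  expect_equal(got2$year, rep(2001L, 3))

  expect_error(select_quantile_years(wx, c(0.5, 1.2)), "0, 1")
})
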