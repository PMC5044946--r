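test_that("storage derivation converts soil 31 percentages to the l/m3 scale", {
  st <- derive_storages(soil_profile(), irrigation_policy())
  expect_equal(st$fc_l_per_m3, 240)
  expect_equal(st$wp_l_per_m3, 70)
  expect_equal(st$awc_l_per_m3, 170)
  expect_equal(st$trigger_l_per_m3, 104) # 70 + 0.20 * 170

  st2 <- derive_storages(soil_profile(30, 20, 10),
                         irrigation_policy(trigger_fraction = 0.25))
  expect_equal(st2$trigger_l_per_m3, 100 + 0.25 * 200)

  # degenerate zero-AWC profile: trigger collapses onto the wilting point
  st3 <- derive_storages(soil_profile(24, 0, 24), irrigation_policy())
  expect_equal(st3$trigger_l_per_m3, st3$wp_l_per_m3)
})

test_that("inconsistent soil profiles are rejected", {
  expect_error(soil_profile(24, 16, 7), "Inconsistent")
  expect_error(soil_profile(24, 17, 7, depth_cm = 0), "positive")
  expect_error(irrigation_policy(trigger_fraction = 1), "between 0 and 1")
  expect_error(irrigation_policy(cap_window_years = 0), ">= 1")
})

test_that("daily update follows balance, clamps, and threshold trigger", {
  st <- derive_storages()
  pol <- irrigation_policy()

  # additive balance above threshold: no event
  r <- daily_update(224.9, 0, 3.0, st, pol)
  expect_equal(r$swc_l_per_m3, 221.9)
  expect_false(r$event)

  # balance crosses below 104: one 20 mm event fires the same day
  r <- daily_update(105.0, 0, 2.0, st, pol)
  expect_true(r$event)
  expect_equal(r$swc_l_per_m3, 123.0)
  expect_equal(r$irrigation_mm, 20)

  # upper clamp at field capacity
  r <- daily_update(239.0, 5, 0, st, pol)
  expect_equal(r$swc_l_per_m3, 240)
  expect_false(r$event)

  # lower clamp at wilting point, then event from the floored value
  r <- daily_update(71.0, 0, 5.0, st, pol)
  expect_true(r$event)
  expect_equal(r$swc_l_per_m3, 90.0)

  # no event when irrigation is not allowed
  r <- daily_update(105.0, 0, 2.0, st, pol, irrigation_allowed = FALSE)
  expect_false(r$event)
  expect_equal(r$swc_l_per_m3, 103.0)

  # entry state outside the physical bounds is an error
  expect_error(daily_update(60, 0, 0, st, pol), "outside")
  expect_error(daily_update(150, NA, 0, st, pol), "must be present")
})

test_that("depth-scaled unit mode converts depths over the rooting zone", {
  st <- derive_storages(soil_profile(), irrigation_policy(unit_convention = "depth_scaled"))
  pol <- irrigation_policy(unit_convention = "depth_scaled")
  # 1 mm over 60 cm rooting depth = 1000/600 l/m3
  r <- daily_update(200, 1, 0, st, pol, irrigation_allowed = FALSE)
  expect_equal(r$swc_l_per_m3, 200 + 1000 / 600)
})

test_that("bucket obeys bounds always and conserves water between clamps/events", {
  st <- derive_storages()
  pol <- irrigation_policy()
  set.seed(402)
  n <- 20000
  precip <- ifelse(runif(n) < 0.35, rgamma(n, 0.8, scale = 5), 0)
  et0 <- pmax(rnorm(n, 2.5, 1.5), 0)
  res <- run_bucket_trace(105, precip, et0, st, pol)
  swc <- res$swc
  expect_true(all(swc >= st$wp_l_per_m3 - 1e-9))
  expect_true(all(swc <= st$fc_l_per_m3 + 1e-9))
  prev <- c(105, swc[-n])
  predicted <- prev + precip - et0
  free <- !res$event &
    predicted > st$wp_l_per_m3 & predicted < st$fc_l_per_m3
  expect_gt(sum(free), 1000)
  expect_equal(swc[free], predicted[free])
  # every event adds exactly the event amount on top of the balance step
  ev <- res$event & predicted > st$wp_l_per_m3 &
    predicted + pol$event_amount_mm < st$fc_l_per_m3
  expect_equal(swc[ev], predicted[ev] + pol$event_amount_mm)
})

test_that("no irrigation fires when precipitation covers evapotranspiration", {
  wx <- flat_climate(2001, precip = 3, et0 = 2)
  s <- simulate_season(wx, 2001, "Sugar beet")
  expect_equal(s$n_events, 0)
  expect_equal(s$total_mm, 0)
})

test_that("wetter climates never need materially more irrigation", {
  st <- derive_storages()
  pol <- irrigation_policy()
  set.seed(77)
  for (i in 1:15) {
    n <- 162
    base <- ifelse(runif(n) < 0.3, rgamma(n, 0.8, scale = 5), 0)
    extra <- ifelse(runif(n) < 0.3, rgamma(n, 0.8, scale = 3), 0)
    et0 <- pmax(rnorm(n, 3, 1), 0)
    dry <- run_bucket_trace(224.9, base, et0, st, pol)
    wet <- run_bucket_trace(224.9, base + extra, et0, st, pol)
    # event granularity (20 mm) permits at most one extra event
    expect_lte(sum(wet$event) * pol$event_amount_mm,
               sum(dry$event) * pol$event_amount_mm + pol$event_amount_mm)
  }
})
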