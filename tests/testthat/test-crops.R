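test_that("every default crop matures exactly three weeks before harvest", {
  tbl <- default_crop_table()
  expect_equal(nrow(tbl), 10)
  expect_true(all(tbl$harvest_doy - tbl$maturity_start_doy == 21))
  # and every crop has a usable irrigation window
  for (crop in tbl$name) {
    w <- irrigation_window(crop, tbl)
    expect_gt(w$n_days, 0)
  }
})

test_that("maturity lookups reproduce the printed calendar days", {
  expect_equal(maturity_start("Sugar beet"), 269)
  expect_equal(maturity_start("Winter barley"), 177)
  expect_equal(maturity_start("Potato"), 244)
  expect_error(maturity_start("Maize"), "Unknown crop")
})

test_that("crop table validation enforces the three-week rule", {
  bad <- default_crop_table()
  bad$maturity_start_doy[1] <- bad$maturity_start_doy[1] - 1
  expect_error(validate_crop_table(bad), "21 days")
  # a crop harvested on day 22 matures on day 1: no window before day 107
  tiny <- tibble::tibble(name = "Synthetic cress", share_pct = 1,
                         harvest_doy = 22L, maturity_start_doy = 1L)
  expect_error(irrigation_window("Synthetic cress", validate_crop_table(tiny)),
               "zero-length")
})

test_that("irrigation windows are half-open from day 107 to maturation", {
  w <- irrigation_window("Sugar beet")
  expect_equal(w$start_doy, 107)
  expect_equal(w$end_doy, 269)
  expect_equal(w$start_swc_l_per_m3, 224.9)

  wb <- irrigation_window("Winter barley")
  expect_equal(wb$n_days, 70) # [107, 177)

  # boundary: crop maturing the day after the start has a one-day window
  t1 <- tibble::tibble(name = "Boundary crop", share_pct = 1,
                       harvest_doy = 129L, maturity_start_doy = 108L)
  w1 <- irrigation_window("Boundary crop", t1)
  expect_equal(w1$n_days, 1)

  # maturing on/before day 107 cannot be irrigated at all
  t0 <- tibble::tibble(name = "Early crop", share_pct = 1,
                       harvest_doy = 128L, maturity_start_doy = 107L)
  expect_error(irrigation_window("Early crop", t0), "zero-length")
})

test_that("rotation cycles deterministically from its anchor year", {
  plan <- rotation_plan()
  expect_equal(rotation_crop_for_year(plan, 1991), "Sugar beet")
  expect_equal(rotation_crop_for_year(plan, 1992), "Potato")
  expect_equal(rotation_crop_for_year(plan, 1993), "Winter rye")
  expect_equal(rotation_crop_for_year(plan, 1994), "Winter barley")
  expect_equal(rotation_crop_for_year(plan, 1995), "Sugar beet")
  # periodic with the plan length, also backwards in time
  yrs <- 1951:2070
  expect_equal(rotation_crop_for_year(plan, yrs),
               rotation_crop_for_year(plan, yrs + 4))
  expect_equal(rotation_crop_for_year(plan, 1987), "Sugar beet")
  expect_error(rotation_plan(crops = character(0)), "at least one")
  expect_error(rotation_plan(crops = c("Sugar beet", "Quinoa")), "Unknown")
})

test_that("crop tables read from CSV derive maturity when absent", {
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(name = c("A crop", "B crop"),
                                  share_pct = c(50, 50),
                                  harvest_doy = c(219, 290)), path)
  tbl <- read_crop_table(path)
  expect_equal(tbl$maturity_start_doy, c(198L, 269L))
  # the shipped fixture equals the built-in table
  shipped <- read_crop_table(system.file("extdata", "crops_uelzen.csv",
                                         package = "irribucket"))
  expect_equal(as.data.frame(shipped), as.data.frame(default_crop_table()))
})
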