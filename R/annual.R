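#' Annual irrigation totals for a crop rotation
#'
#' Simulates one season per calendar year covered by the climate series,
#' with the crop of each year taken from the rotation plan, and collects
#' the annual irrigation totals. Every season restarts at the standard
#' window start day and content.
#'
#' @param climate A `climate_series` tibble.
#' @param plan A [rotation_plan()].
#' @param table Crop table.
#' @param storages [derive_storages()] result.
#' @param policy [irrigation_policy()].
#' @param years Years to simulate (default: all complete years of the
#'   series).
#' @param start_doy,start_swc_l_per_m3 Window start day and content
#'   applied to every crop and year.
#' @return A tibble of class `irrig_annual` with columns `year`, `crop`,
#'   `n_events`, `total_mm`.
#' @examples
#' wx <- generate_daily_weather(scenario_config(c(1991, 1998), seed = 3))
#' annual_irrigation_series(wx, rotation_plan())
#' @export
annual_irrigation_series <- function(climate, plan = rotation_plan(),
                                     table = default_crop_table(),
                                     storages = derive_storages(),
                                     policy = irrigation_policy(),
                                     years = NULL,
                                     start_doy = 107,
                                     start_swc_l_per_m3 = 224.9) {
  years <- years %||% sort(unique(climate$year))
  out <- purrr::map_dfr(years, function(y) {
    crop <- rotation_crop_for_year(plan, y)
    w <- irrigation_window(crop, table, start_doy, start_swc_l_per_m3)
    s <- simulate_season(climate, y, crop, storages, policy, window = w)
    tibble::tibble(year = s$year, crop = s$crop,
                   n_events = s$n_events, total_mm = s$total_mm)
  })
  class(out) <- unique(c("irrig_annual", class(out)))
  out
}

#' Trailing moving average of annual irrigation totals
#'
#' Adds the trailing `window_years`-year mean of `total_mm` (the current
#' year and the `window_years - 1` preceding years). Years without a full
#' history get `NA` — warm-up years are never zero-filled; supply
#' earlier totals (e.g. simulated reference-period years) if the first
#' years of interest need a moving average.
#'
#' @param annual An `irrig_annual` tibble (or any tibble with `year` and
#'   `total_mm`), one row per consecutive year.
#' @param window_years Window length in years (default 7).
#' @return The input with an added `ma_mm` column.
#' @examples
#' tbl <- tibble::tibble(year = 1985:1998, total_mm = 1:14)
#' moving_average(tbl)
#' @export
moving_average <- function(annual, window_years = 7) {
  if (window_years < 1) abort("`window_years` must be >= 1.")
  annual <- dplyr::arrange(annual, .data$year)
  if (nrow(annual) > 1 && any(diff(annual$year) != 1)) {
    abort("Annual series must cover consecutive years with no gaps.")
  }
  ma <- if (nrow(annual) < window_years) {
    rep(NA_real_, nrow(annual)) # all warm-up
  } else {
    as.numeric(stats::filter(annual$total_mm,
                             rep(1 / window_years, window_years),
                             sides = 1))
  }
  dplyr::mutate(annual, ma_mm = ma)
}

#' Flag years exceeding the abstraction cap
#'
#' Flags every year whose trailing moving average strictly exceeds the
#' permitted cap; a moving average exactly at the cap is allowed. Years
#' without a defined moving average (warm-up) get `NA`.
#'
#' @param annual Output of [moving_average()] (must contain `ma_mm`).
#' @param cap_mm Permitted amount, mm per m2 and year (default 79).
#' @return The input with an added logical `cap_exceeded` column.
#' @export
cap_exceedance <- function(annual, cap_mm = 79) {
  if (!"ma_mm" %in% names(annual)) {
    abort("Run moving_average() first: `ma_mm` column is required.")
  }
  dplyr::mutate(annual, cap_exceeded = .data$ma_mm > cap_mm)
}

#' Plot annual irrigation totals against the cap
#'
#' Bars for annual totals, a line for the trailing moving average where
#' defined, and the cap as a horizontal reference; flagged years are
#' highlighted.
#'
#' @param object An `irrig_annual` tibble, ideally after
#'   [moving_average()] and [cap_exceedance()].
#' @param cap_mm Cap to draw (default 79).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot irrig_annual
#' @export
autoplot.irrig_annual <- function(object, cap_mm = 79, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$year)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$total_mm), fill = "grey70") +
    ggplot2::geom_hline(yintercept = cap_mm, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Year", y = "Irrigation (mm)",
                  title = "Annual irrigation requirement") +
    ggplot2::theme_minimal()
  if ("ma_mm" %in% names(object)) {
    p <- p + ggplot2::geom_line(
      data = object[!is.na(object$ma_mm), , drop = FALSE],
      ggplot2::aes(y = .data$ma_mm), colour = "steelblue", linewidth = 0.9
    )
  }
  if ("cap_exceeded" %in% names(object)) {
    flagged <- object[!is.na(object$cap_exceeded) & object$cap_exceeded, , drop = FALSE]
    if (nrow(flagged) > 0) {
      p <- p + ggplot2::geom_point(data = flagged,
                                   ggplot2::aes(y = .data$ma_mm),
                                   colour = "firebrick", size = 2)
    }
  }
  p
}
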