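#' Simulate one irrigation season
#'
#' Runs the daily soil-water bucket for one crop and year. The state is
#' initialised to the window's start content on the start day; the daily
#' update is applied for every day of the half-open window
#' `[start_doy, end_doy)` with irrigation allowed, recording the soil
#' water trace and every irrigation event. Soil water does not carry over
#' between years: each season starts fresh at the configured start value.
#'
#' @param climate A `climate_series` tibble covering `year`.
#' @param year Calendar year to simulate.
#' @param crop Crop name (used to derive the window when `window` is not
#'   given).
#' @param storages [derive_storages()] result.
#' @param policy [irrigation_policy()].
#' @param window [irrigation_window()]; defaults to the crop's window
#'   with the standard start day and content.
#' @param table Crop table used when deriving the window.
#' @return An object of class `season_result`: list with `year`, `crop`,
#'   `trace` (tibble `doy`, `swc_l_per_m3`, `event` — content after each
#'   day's update), `event_doys`, `n_events`, `total_mm` and the window.
#' @examples
#' wx <- generate_daily_weather(scenario_config(c(2003, 2003), seed = 5))
#' simulate_season(wx, 2003, "Sugar beet", derive_storages(), irrigation_policy())
#' @export
simulate_season <- function(climate, year, crop,
                            storages = derive_storages(),
                            policy = irrigation_policy(),
                            window = NULL,
                            table = default_crop_table()) {
  window <- window %||% irrigation_window(crop, table)
  days <- window$start_doy:(window$end_doy - 1L)
  sel <- climate[climate$year == year & climate$doy %in% days, , drop = FALSE]
  if (nrow(sel) != length(days)) {
    abort(sprintf(
      "Climate series covers %d of the %d window days of year %d.",
      nrow(sel), length(days), year
    ))
  }
  sel <- sel[order(sel$doy), , drop = FALSE]
  res <- run_bucket(window$start_swc_l_per_m3,
                    sel$precip_mm, sel$et0_mm,
                    rep(TRUE, length(days)), storages, policy)
  event_doys <- days[res$event]
  structure(
    list(
      year = as.integer(year), crop = crop,
      trace = tibble::tibble(doy = days, swc_l_per_m3 = res$swc,
                             event = res$event),
      event_doys = event_doys,
      n_events = length(event_doys),
      total_mm = length(event_doys) * policy$event_amount_mm,
      window = window
    ),
    class = "season_result"
  )
}

#' @export
print.season_result <- function(x, ...) {
  cat(sprintf("<season_result> %d %s: %d events, %g mm over window [%d, %d)\n",
              x$year, x$crop, x$n_events, x$total_mm,
              x$window$start_doy, x$window$end_doy))
  invisible(x)
}

#' @method tidy season_result
#' @export
tidy.season_result <- function(x, ...) {
  dplyr::mutate(x$trace, year = x$year, crop = x$crop, .before = 1)
}

#' @method glance season_result
#' @export
glance.season_result <- function(x, ...) {
  tibble::tibble(year = x$year, crop = x$crop, n_events = x$n_events,
                 total_mm = x$total_mm,
                 first_event_doy = if (x$n_events > 0) x$event_doys[1] else NA_integer_,
                 last_event_doy = if (x$n_events > 0) x$event_doys[x$n_events] else NA_integer_)
}

#' Plot a season's soil-water trace
#'
#' Soil water content over the irrigation window with event days marked
#' and the trigger/field-capacity/wilting-point levels drawn as
#' reference lines.
#'
#' @param object A `season_result`.
#' @param storages The `storage_params` used in the simulation (for the
#'   reference lines); optional.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot season_result
#' @export
autoplot.season_result <- function(object, storages = NULL, ...) {
  tr <- object$trace
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$doy, y = .data$swc_l_per_m3)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = tr[tr$event, , drop = FALSE],
                        colour = "firebrick", size = 1.6) +
    ggplot2::labs(
      title = sprintf("%s, %d: %d irrigation events (%g mm)",
                      object$crop, object$year, object$n_events, object$total_mm),
      x = "Day of year", y = "Soil water content (l/m³)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(storages)) {
    p <- p + ggplot2::geom_hline(
      yintercept = c(storages$fc_l_per_m3, storages$trigger_l_per_m3,
                     storages$wp_l_per_m3),
      linetype = "dashed", colour = "grey50"
    )
  }
  p
}
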