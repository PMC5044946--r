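#' Annual precipitation totals of a climate series
#'
#' @param series A `climate_series` tibble.
#' @return A tibble with columns `year` and `precip_mm`.
#' @export
annual_precip <- function(series) {
  validate_climate(series)
  dplyr::summarise(
    dplyr::group_by(as_tibble_plain(series), .data$year),
    precip_mm = sum(.data$precip_mm),
    .groups = "drop"
  )
}

#' Pick representative years by annual-rainfall quantile
#'
#' For each requested probability, returns the calendar year whose annual
#' precipitation total lies closest to that empirical quantile of the
#' annual-rainfall distribution — e.g. the 10%, 50% and 90% quantile years
#' characterise a dry, a median and a wet year of the period. Ties are
#' broken towards the earliest year.
#'
#' @param series A `climate_series` tibble covering at least two complete
#'   years.
#' @param probs Probabilities in `[0, 1]` (default `c(0.1, 0.5, 0.9)`).
#' @return A tibble with one row per probability: `prob`, `year`,
#'   `precip_mm` (that year's total) and `quantile_mm` (the empirical
#'   quantile aimed at).
#' @examples
#' wx <- generate_daily_weather(scenario_config(c(1991, 2010), seed = 7))
#' select_quantile_years(wx)
#' @export
select_quantile_years <- function(series, probs = c(0.1, 0.5, 0.9)) {
  if (any(probs < 0 | probs > 1)) abort("Probabilities must lie in [0, 1].")
  totals <- annual_precip(series)
  if (nrow(totals) < 2) abort("Need at least 2 complete years.")
  qs <- quantile(totals$precip_mm, probs = probs, names = FALSE)
  purrr::map2_dfr(probs, qs, function(p, q) {
    dist <- abs(totals$precip_mm - q)
    i <- which(dist == min(dist))
    i <- i[which.min(totals$year[i])] # earliest year on ties
    tibble::tibble(prob = p, year = totals$year[i],
                   precip_mm = totals$precip_mm[i], quantile_mm = q)
  })
}
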