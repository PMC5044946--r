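#' Configure the synthetic daily climate generator
#'
#' Describes a multi-decade daily weather scenario for a single site:
#' a seasonal temperature climatology with an optional linear warming
#' trend, stochastic precipitation from a two-state first-order Markov
#' occurrence chain with gamma-distributed wet-day amounts, and reference
#' evapotranspiration either derived from generated Penman-Monteith
#' drivers (`et0_mode = "penman"`, the default) or drawn directly from a
#' seasonal cycle plus trend and noise (`et0_mode = "direct"`, faster).
#'
#' Trends are expressed as the total change over the full period: a
#' `temp_trend` of 1.7 means daily temperatures ramp linearly by +1.7 degC
#' between the first and last day; an `et_trend` of 28.4 ramps the annual
#' ET0 total by about +28.4 mm/yr over the period.
#'
#' The wet-day gamma scale is calibrated so that the expected annual
#' precipitation equals `annual_precip_mean`. With
#' `precip_mode = "climatology"` precipitation is instead spread
#' deterministically and uniformly over the year (useful with zero noise
#' to obtain a fully deterministic series).
#'
#' @param year_range Integer vector `c(first, last)` of calendar years.
#' @param seed Integer RNG seed; mandatory, makes the series fully
#'   reproducible.
#' @param annual_precip_mean Expected annual precipitation, mm/yr
#'   (default 654.4, the regional reference-period mean).
#' @param temp_baseline Annual mean temperature at the period start, degC.
#' @param temp_seasonal_amp Amplitude of the seasonal temperature cycle,
#'   degC (peak mid-July).
#' @param temp_trend Total temperature change over the period, degC.
#' @param temp_noise_sd Daily temperature noise s.d., degC.
#' @param et_trend Total change of the annual ET0 sum over the period,
#'   mm/yr.
#' @param et0_mode `"penman"` or `"direct"` (see Description).
#' @param et0_base,et0_seasonal_amp Mean and seasonal amplitude of daily
#'   ET0 in `"direct"` mode, mm/day.
#' @param et0_noise_sd Daily ET0 noise s.d. in `"direct"` mode, mm/day.
#' @param wet_prob_dry Probability a day is wet given the previous day was
#'   dry.
#' @param wet_prob_wet Probability a day is wet given the previous day was
#'   wet.
#' @param gamma_shape Shape of the wet-day amount gamma distribution.
#' @param precip_mode `"markov"` (stochastic) or `"climatology"`
#'   (deterministic uniform).
#' @param rn_noise_sd,u2_noise_sd,rh_noise_sd Daily noise s.d. of the
#'   generated Penman-Monteith drivers (net radiation MJ m-2 d-1, wind
#'   m s-1, relative humidity fraction).
#' @param scenario_label Label attached to the series; one of
#'   `"observation"`, `"Tmin"`, `"Tmed"`, `"Tmax"`, `"custom"`.
#' @return An object of class `scenario_config`.
#' @seealso [scenario_preset()] for the named scenario presets,
#'   [generate_daily_weather()] to realise the series.
#' @export
scenario_config <- function(year_range = c(2011, 2070),
                            seed,
                            annual_precip_mean = 654.4,
                            temp_baseline = 8.7,
                            temp_seasonal_amp = 8,
                            temp_trend = 0,
                            temp_noise_sd = 2.5,
                            et_trend = 0,
                            et0_mode = c("penman", "direct"),
                            et0_base = 1.6,
                            et0_seasonal_amp = 1.45,
                            et0_noise_sd = 0.3,
                            wet_prob_dry = 0.3,
                            wet_prob_wet = 0.6,
                            gamma_shape = 0.8,
                            precip_mode = c("markov", "climatology"),
                            rn_noise_sd = 1.5,
                            u2_noise_sd = 0.4,
                            rh_noise_sd = 0.05,
                            scenario_label = "custom") {
  et0_mode <- match.arg(et0_mode)
  precip_mode <- match.arg(precip_mode)
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    abort("`seed` is mandatory for a reproducible scenario.")
  }
  year_range <- as.integer(year_range)
  if (length(year_range) != 2 || year_range[2] < year_range[1]) {
    abort("`year_range` must be c(first, last) with last >= first.")
  }
  if (annual_precip_mean <= 0) abort("`annual_precip_mean` must be positive.")
  probs <- c(wet_prob_dry, wet_prob_wet)
  if (any(probs < 0 | probs > 1)) abort("Wet-day probabilities must lie in [0, 1].")
  if (gamma_shape <= 0) abort("`gamma_shape` must be positive.")
  if (!scenario_label %in% c("observation", "Tmin", "Tmed", "Tmax", "custom")) {
    abort("Unknown `scenario_label`.")
  }
  structure(
    list(
      year_range = year_range, seed = as.integer(seed),
      annual_precip_mean = annual_precip_mean,
      temp_baseline = temp_baseline, temp_seasonal_amp = temp_seasonal_amp,
      temp_trend = temp_trend, temp_noise_sd = temp_noise_sd,
      et_trend = et_trend, et0_mode = et0_mode,
      et0_base = et0_base, et0_seasonal_amp = et0_seasonal_amp,
      et0_noise_sd = et0_noise_sd,
      wet_prob_dry = wet_prob_dry, wet_prob_wet = wet_prob_wet,
      gamma_shape = gamma_shape, precip_mode = precip_mode,
      rn_noise_sd = rn_noise_sd, u2_noise_sd = u2_noise_sd,
      rh_noise_sd = rh_noise_sd,
      scenario_label = scenario_label
    ),
    class = "scenario_config"
  )
}

#' Named climate scenario presets
#'
#' Ready-made configurations for a 1951--2010 observation-like series and
#' the three warming runs of a high-emission scenario, distinguished by
#' their temperature increase over 2011--2070 and the accompanying shifts
#' of annual evapotranspiration and precipitation relative to the
#' reference period:
#'
#' * `Tmin`: +0.9 degC, ET0 -8.7 mm/yr, precipitation +44.7 mm/yr
#' * `Tmed`: +1.3 degC, ET0 +5.6 mm/yr, precipitation +45.0 mm/yr
#' * `Tmax`: +1.7 degC, ET0 +28.4 mm/yr, precipitation +14.1 mm/yr
#'
#' @param scenario One of `"observation"`, `"Tmin"`, `"Tmed"`, `"Tmax"`.
#' @param seed Integer RNG seed.
#' @param year_range Years covered; defaults to 1951--2010 for
#'   `"observation"` and 2011--2070 for the scenario runs.
#' @param ... Further arguments passed to [scenario_config()] to override
#'   preset values.
#' @return A `scenario_config`.
#' @examples
#' cfg <- scenario_preset("Tmax", seed = 1)
#' @export
scenario_preset <- function(scenario = c("observation", "Tmin", "Tmed", "Tmax"),
                            seed, year_range = NULL, ...) {
  scenario <- match.arg(scenario)
  ref_precip <- 654.4
  p <- switch(scenario,
    observation = list(years = c(1951, 2010), dt = 0, det = 0, dp = 0),
    Tmin = list(years = c(2011, 2070), dt = 0.9, det = -8.7, dp = 44.7),
    Tmed = list(years = c(2011, 2070), dt = 1.3, det = 5.6, dp = 45.0),
    Tmax = list(years = c(2011, 2070), dt = 1.7, det = 28.4, dp = 14.1)
  )
  scenario_config(
    year_range = year_range %||% p$years,
    seed = seed,
    annual_precip_mean = ref_precip + p$dp,
    temp_trend = p$dt,
    et_trend = p$det,
    scenario_label = scenario,
    ...
  )
}

#' Generate a synthetic daily climate series
#'
#' Realises a [scenario_config()] as a complete daily series over whole
#' calendar years (real calendars, so leap years have 366 days). The same
#' configuration and seed always yield an identical series.
#'
#' In `"penman"` mode the generator first draws physically plausible
#' drivers (net radiation, wind at 2 m, vapour pressures from temperature
#' and a stochastic relative humidity) and computes ET0 with
#' [et0_penman_monteith()]; the driver columns are kept in the output. In
#' `"direct"` mode ET0 is a seasonal sine plus trend and noise. In both
#' modes the configured ET trend is imposed as a linear ramp of the annual
#' ET0 sum and ET0 is floored at 0.
#'
#' @param config A [scenario_config()] or [scenario_preset()].
#' @return A tibble of class `climate_series` with columns `date`, `year`,
#'   `doy`, `tmean_c`, `precip_mm`, `et0_mm` (plus driver columns `rn_mj`,
#'   `g_mj`, `u2_ms`, `es_kpa`, `ea_kpa` in `"penman"` mode) and a
#'   `scenario` attribute.
#' @examples
#' wx <- generate_daily_weather(scenario_config(c(2001, 2002), seed = 42))
#' dplyr::summarise(dplyr::group_by(wx, year), precip = sum(precip_mm))
#' @export
generate_daily_weather <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  y0 <- config$year_range[1]
  y1 <- config$year_range[2]
  dates <- seq(as.Date(sprintf("%d-01-01", y0)),
               as.Date(sprintf("%d-12-31", y1)), by = "day")
  n <- length(dates)
  doy <- as.integer(strftime(dates, "%j"))
  year <- as.integer(strftime(dates, "%Y"))
  frac <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0

  with_seed(config$seed, {
    tmean <- config$temp_baseline +
      config$temp_seasonal_amp * cos(2 * pi * (doy - 197) / 365.25) +
      config$temp_trend * frac +
      rnorm(n, sd = config$temp_noise_sd)

    precip <- generate_precip(config, n, doy)

    if (config$et0_mode == "direct") {
      et0 <- config$et0_base +
        config$et0_seasonal_amp * cos(2 * pi * (doy - 197) / 365.25) +
        rnorm(n, sd = config$et0_noise_sd)
      drivers <- NULL
    } else {
      rn <- 7.5 + 6.8 * cos(2 * pi * (doy - 172) / 365.25) +
        rnorm(n, sd = config$rn_noise_sd)
      u2 <- pmax(2 + rnorm(n, sd = config$u2_noise_sd), 0.2)
      rh <- pmin(pmax(0.78 + rnorm(n, sd = config$rh_noise_sd), 0.3), 1)
      es <- sat_vapour_pressure(tmean)
      ea <- rh * es
      et0 <- et0_penman_monteith(tmean, rn, 0, u2, es, ea)
      drivers <- tibble::tibble(rn_mj = rn, g_mj = 0, u2_ms = u2,
                                es_kpa = es, ea_kpa = ea)
    }
    et0 <- pmax(et0 + config$et_trend * frac / 365.25, 0)
  })

  out <- tibble::tibble(
    date = dates, year = year, doy = doy,
    tmean_c = tmean, precip_mm = precip, et0_mm = et0
  )
  if (!is.null(drivers)) out <- dplyr::bind_cols(out, drivers)
  as_climate_series(out, scenario = config$scenario_label)
}

# precipitation: 2-state Markov occurrence + gamma amounts, or a
# deterministic uniform climatology
generate_precip <- function(config, n, doy) {
  if (config$precip_mode == "climatology") {
    return(config$annual_precip_mean / 365.25 + numeric(n))
  }
  p01 <- config$wet_prob_dry
  p11 <- config$wet_prob_wet
  # stationary wet fraction of the occurrence chain
  pi_wet <- if (1 + p01 - p11 > 0) p01 / (1 + p01 - p11) else 1
  mean_amount <- config$annual_precip_mean / (365.25 * pi_wet)
  scale <- mean_amount / config$gamma_shape
  u <- runif(n)
  wet <- logical(n)
  wet[1] <- u[1] < pi_wet
  for (i in 2:n) {
    wet[i] <- u[i] < (if (wet[i - 1]) p11 else p01)
  }
  amounts <- rgamma(n, shape = config$gamma_shape, scale = scale)
  ifelse(wet, amounts, 0)
}

# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(code))
}

as_climate_series <- function(tbl, scenario = "custom") {
  attr(tbl, "scenario") <- scenario
  class(tbl) <- unique(c("climate_series", class(tbl)))
  tbl
}
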