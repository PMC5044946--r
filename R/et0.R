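#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Daily reference (grass) evapotranspiration from its standard drivers:
#'
#' \deqn{ET_0 = \frac{0.408\,\Delta\,(R_n - G) +
#'   \gamma\,\frac{900}{T+273}\,u_2\,(e_s - e_a)}
#'   {\Delta + \gamma\,(1 + 0.34\,u_2)}}
#'
#' with the slope of the saturation vapour pressure curve
#' \eqn{\Delta = 4098\,[0.6108\,e^{17.27 T/(T+237.3)}]/(T+237.3)^2}
#' (kPa/degC) and the psychrometric constant
#' \eqn{\gamma = 0.665 \times 10^{-3} P} (kPa/degC) at atmospheric
#' pressure `pressure_kpa`.
#'
#' Negative results (possible under negative net radiation with a moist
#' atmosphere) are floored at 0 mm/day: in the bucket model ET only ever
#' removes water.
#'
#' @param tmean_c Daily mean air temperature, degC.
#' @param rn_mj Net radiation at the surface, MJ m-2 day-1.
#' @param g_mj Soil heat flux, MJ m-2 day-1 (~0 at daily resolution).
#' @param u2_ms Wind speed at 2 m, m s-1.
#' @param es_kpa,ea_kpa Saturation and actual vapour pressure, kPa;
#'   `ea_kpa <= es_kpa` is required.
#' @param pressure_kpa Atmospheric pressure, kPa (default sea level 101.3).
#' @return Reference evapotranspiration in mm/day (vectorised, >= 0).
#' @examples
#' # FAO-56 worked example (Uccle, 6 July): approx. 3.9 mm/day
#' et0_penman_monteith(16.9, rn_mj = 13.28, g_mj = 0, u2_ms = 2.078,
#'                     es_kpa = 1.997, ea_kpa = 1.409, pressure_kpa = 100.1)
#' @export
et0_penman_monteith <- function(tmean_c, rn_mj, g_mj, u2_ms,
                                es_kpa, ea_kpa, pressure_kpa = 101.3) {
  args <- list(tmean_c = tmean_c, rn_mj = rn_mj, g_mj = g_mj,
               u2_ms = u2_ms, es_kpa = es_kpa, ea_kpa = ea_kpa)
  missing_drv <- names(args)[vapply(args, function(a) is.null(a) || anyNA(a), logical(1))]
  if (length(missing_drv) > 0) {
    abort(paste0("Missing ET0 driver(s): ", paste(missing_drv, collapse = ", "), "."))
  }
  if (any(tmean_c <= -273)) abort("Temperature at or below absolute zero.")
  if (any(ea_kpa > es_kpa + 1e-9)) {
    abort("Actual vapour pressure exceeds saturation vapour pressure.")
  }
  delta <- 4098 * sat_vapour_pressure(tmean_c) / (tmean_c + 237.3)^2
  gamma <- 0.665e-3 * pressure_kpa
  num <- 0.408 * delta * (rn_mj - g_mj) +
    gamma * (900 / (tmean_c + 273)) * u2_ms * (es_kpa - ea_kpa)
  den <- delta + gamma * (1 + 0.34 * u2_ms)
  pmax(num / den, 0)
}

#' Saturation vapour pressure after FAO-56
#'
#' \eqn{e^0(T) = 0.6108\,\exp[17.27\,T/(T+237.3)]} in kPa.
#'
#' @param tmean_c Air temperature, degC.
#' @return Saturation vapour pressure, kPa.
#' @export
sat_vapour_pressure <- function(tmean_c) {
  0.6108 * exp(17.27 * tmean_c / (tmean_c + 237.3))
}
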