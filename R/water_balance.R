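#' One daily step of the soil-water bucket with threshold irrigation
#'
#' Advances the soil water content by one day:
#' 1. additive balance `swc + k * (precip - et0)` where `k` is the unit
#'    conversion factor (1 in `"paper"` mode);
#' 2. clamp to the physical bounds `[wp, fc]`;
#' 3. if irrigation is allowed and the clamped content lies strictly below
#'    the trigger threshold, apply one event of `event_amount_mm`
#'    (at most one per day) and re-clamp to `fc`.
#'
#' Outside the clamps and events the balance is exactly conservative:
#' `swc_new - swc_old = k * (precip - et0)`.
#'
#' @param swc_l_per_m3 Soil water content entering the day, l/m3; must lie
#'   within `[wp, fc]`.
#' @param precip_mm,et0_mm Daily precipitation and reference
#'   evapotranspiration depths, mm.
#' @param storages A [derive_storages()] result.
#' @param policy An [irrigation_policy()].
#' @param irrigation_allowed Is the day inside the crop's irrigation
#'   window?
#' @return A list with `swc_l_per_m3` (content after the day), `event`
#'   (logical, did an irrigation event fire) and `irrigation_mm` (0 or the
#'   event amount).
#' @examples
#' st <- derive_storages()
#' daily_update(224.9, precip_mm = 0, et0_mm = 3, st, irrigation_policy())
#' @export
daily_update <- function(swc_l_per_m3, precip_mm, et0_mm,
                         storages, policy = irrigation_policy(),
                         irrigation_allowed = TRUE) {
  stopifnot(inherits(storages, "storage_params"),
            inherits(policy, "irrigation_policy"))
  if (is.na(swc_l_per_m3) || swc_l_per_m3 < storages$wp_l_per_m3 - 1e-9 ||
      swc_l_per_m3 > storages$fc_l_per_m3 + 1e-9) {
    abort(sprintf(
      "Soil water content %g l/m3 outside [%g, %g] on entry.",
      swc_l_per_m3, storages$wp_l_per_m3, storages$fc_l_per_m3
    ))
  }
  if (is.na(precip_mm) || is.na(et0_mm)) {
    abort("Daily precipitation and et0 must be present (not NA).")
  }
  k <- unit_factor(policy, storages)
  swc <- swc_l_per_m3 + k * (precip_mm - et0_mm)
  swc <- min(max(swc, storages$wp_l_per_m3), storages$fc_l_per_m3)
  event <- FALSE
  if (irrigation_allowed && swc < storages$trigger_l_per_m3) {
    swc <- min(swc + k * policy$event_amount_mm, storages$fc_l_per_m3)
    event <- TRUE
  }
  list(
    swc_l_per_m3 = swc,
    event = event,
    irrigation_mm = if (event) policy$event_amount_mm else 0
  )
}

# Fast internal vector loop used by simulate_season() and
# determine_window_start(): same semantics as daily_update(), without
# per-day list allocation. Returns post-update swc and event flags.
run_bucket <- function(swc0, precip, et0, allowed, storages, policy) {
  n <- length(precip)
  stopifnot(length(et0) == n, length(allowed) == n)
  k <- unit_factor(policy, storages)
  wp <- storages$wp_l_per_m3
  fc <- storages$fc_l_per_m3
  trig <- storages$trigger_l_per_m3
  amt <- k * policy$event_amount_mm
  swc <- numeric(n)
  event <- logical(n)
  s <- swc0
  for (i in seq_len(n)) {
    s <- s + k * (precip[i] - et0[i])
    if (s < wp) s <- wp else if (s > fc) s <- fc
    if (allowed[i] && s < trig) {
      s <- s + amt
      if (s > fc) s <- fc
      event[i] <- TRUE
    }
    swc[i] <- s
  }
  list(swc = swc, event = event)
}
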