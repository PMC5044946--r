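#' Define a soil profile by its hydraulic percentages
#'
#' A single-layer ("bucket") soil description on the volumetric percent
#' scale used by soil survey maps: field capacity, available water
#' capacity (AWC) and wilting point, over a fixed rooting depth. The
#' three percentages must be consistent: wilting + AWC = field capacity.
#'
#' The default is the brown podzolic sand ("soil type 31") that dominates
#' arable land in the study region: field capacity 24%, AWC 17%,
#' wilting point 7%, rooting zone 0--60 cm.
#'
#' @param field_capacity_pct Volumetric water content at field capacity, in %.
#' @param awc_pct Available water capacity (field capacity minus wilting
#'   point), in %.
#' @param wilting_pct Volumetric water content at the wilting point, in %.
#' @param depth_cm Rooting depth in cm (informational in `"paper"` unit
#'   mode; used by the `"depth_scaled"` mode, see [irrigation_policy()]).
#' @param soil_type_id Label for the soil map unit.
#' @return An object of class `soil_profile` (a named list).
#' @examples
#' soil_profile() # soil type 31
#' @export
soil_profile <- function(field_capacity_pct = 24,
                         awc_pct = 17,
                         wilting_pct = 7,
                         depth_cm = 60,
                         soil_type_id = "31") {
  stopifnot(is.numeric(field_capacity_pct), is.numeric(awc_pct),
            is.numeric(wilting_pct), is.numeric(depth_cm))
  if (depth_cm <= 0) abort("`depth_cm` must be positive.")
  pcts <- c(field_capacity_pct, wilting_pct)
  if (any(pcts <= 0) || any(pcts >= 100)) {
    abort("Field capacity and wilting point must lie in (0, 100).")
  }
  if (awc_pct < 0 || awc_pct >= 100) {
    abort("`awc_pct` must lie in [0, 100); 0 is the degenerate no-reservoir case.")
  }
  if (abs(wilting_pct + awc_pct - field_capacity_pct) > 1e-9) {
    abort(sprintf(
      "Inconsistent soil profile: wilting (%g%%) + AWC (%g%%) != field capacity (%g%%).",
      wilting_pct, awc_pct, field_capacity_pct
    ))
  }
  structure(
    list(
      soil_type_id = as.character(soil_type_id),
      field_capacity_pct = field_capacity_pct,
      awc_pct = awc_pct,
      wilting_pct = wilting_pct,
      depth_cm = depth_cm
    ),
    class = "soil_profile"
  )
}

#' @export
print.soil_profile <- function(x, ...) {
  cat(sprintf(
    "<soil_profile> type %s: FC %g%%, AWC %g%%, WP %g%%, depth %g cm\n",
    x$soil_type_id, x$field_capacity_pct, x$awc_pct, x$wilting_pct, x$depth_cm
  ))
  invisible(x)
}

#' Define the irrigation scheduling policy
#'
#' Bundles the trigger rule, per-event application, the regulatory cap and
#' the unit convention of the water balance.
#'
#' Irrigation is triggered when soil water drops below the wilting-point
#' storage plus `trigger_fraction` of the AWC storage. Each event applies a
#' fixed `event_amount_mm`. Annual totals are judged against `annual_cap_mm`
#' as a trailing moving average over `cap_window_years` years.
#'
#' @section Unit conventions:
#' `"paper"` (default) bookkeeps soil water in l/m3 on a 1000-l/m3 percent
#' scale (1 volumetric % = 10 l/m3) and adds precipitation, ET and
#' irrigation depths in mm at face value (1 mm = 1 l/m3), so a 20 mm event
#' raises the content by 2 percentage points regardless of rooting depth.
#' `"depth_scaled"` converts depths physically over the rooting zone:
#' 1 mm over depth d cm changes the volumetric store by 1000/(10 d) l/m3.
#'
#' @param trigger_fraction Fraction of AWC below which irrigation fires
#'   (default 0.20).
#' @param event_amount_mm Water applied per irrigation event, mm (= l/m2).
#' @param annual_cap_mm Permitted annual abstraction, mm per m2 and year,
#'   evaluated on the moving average (default 79).
#' @param cap_window_years Length of the trailing moving-average window in
#'   years (default 7).
#' @param unit_convention `"paper"` or `"depth_scaled"` (see Details).
#' @return An object of class `irrigation_policy`.
#' @examples
#' irrigation_policy()
#' @export
irrigation_policy <- function(trigger_fraction = 0.20,
                              event_amount_mm = 20,
                              annual_cap_mm = 79,
                              cap_window_years = 7,
                              unit_convention = c("paper", "depth_scaled")) {
  unit_convention <- match.arg(unit_convention)
  if (!(trigger_fraction > 0 && trigger_fraction < 1)) {
    abort("`trigger_fraction` must lie strictly between 0 and 1.")
  }
  if (event_amount_mm <= 0) abort("`event_amount_mm` must be positive.")
  if (cap_window_years < 1) abort("`cap_window_years` must be >= 1.")
  structure(
    list(
      trigger_fraction = trigger_fraction,
      event_amount_mm = event_amount_mm,
      annual_cap_mm = annual_cap_mm,
      cap_window_years = as.integer(cap_window_years),
      unit_convention = unit_convention
    ),
    class = "irrigation_policy"
  )
}

#' @export
print.irrigation_policy <- function(x, ...) {
  cat(sprintf(
    "<irrigation_policy> trigger %g x AWC, %g mm/event, cap %g mm over %d-yr MA, units '%s'\n",
    x$trigger_fraction, x$event_amount_mm, x$annual_cap_mm,
    x$cap_window_years, x$unit_convention
  ))
  invisible(x)
}

#' Convert a soil profile to volumetric storages and the trigger threshold
#'
#' Converts the percent-scale soil description to the l/m3 bookkeeping
#' scale of the bucket model (1 volumetric % = 10 l/m3, i.e. a 1000-l/m3
#' percent scale) and derives the irrigation trigger threshold as
#' wilting-point storage + `trigger_fraction` x AWC storage.
#'
#' For soil type 31 with the default 20% trigger fraction this yields
#' field capacity 240 l/m3, stagnant (wilting-point) water 70 l/m3,
#' AWC 170 l/m3 and a trigger of 70 + 34 = 104 l/m3 (10.4%).
#'
#' @param profile A [soil_profile()].
#' @param policy An [irrigation_policy()]; only `trigger_fraction` is used.
#' @return An object of class `storage_params`: a named list with
#'   `fc_l_per_m3`, `wp_l_per_m3`, `awc_l_per_m3`, `trigger_l_per_m3` and
#'   the depth carried over from the profile.
#' @examples
#' derive_storages(soil_profile(), irrigation_policy())
#' @export
derive_storages <- function(profile = soil_profile(),
                            policy = irrigation_policy()) {
  stopifnot(inherits(profile, "soil_profile"),
            inherits(policy, "irrigation_policy"))
  fc <- 10 * profile$field_capacity_pct
  wp <- 10 * profile$wilting_pct
  awc <- 10 * profile$awc_pct
  trigger <- wp + policy$trigger_fraction * awc
  # zero AWC collapses the trigger onto the wilting point (never fires)
  if (!(wp <= trigger && trigger <= fc)) {
    abort("Degenerate storages: require wp <= trigger <= fc.")
  }
  structure(
    list(
      fc_l_per_m3 = fc,
      wp_l_per_m3 = wp,
      awc_l_per_m3 = awc,
      trigger_l_per_m3 = trigger,
      depth_cm = profile$depth_cm
    ),
    class = "storage_params"
  )
}

#' @export
print.storage_params <- function(x, ...) {
  cat(sprintf(
    "<storage_params> fc %g, wp %g, awc %g, trigger %g l/m3 (depth %g cm)\n",
    x$fc_l_per_m3, x$wp_l_per_m3, x$awc_l_per_m3, x$trigger_l_per_m3,
    x$depth_cm
  ))
  invisible(x)
}

# depth conversion factor: l/m3 change per mm of water depth
unit_factor <- function(policy, storages) {
  switch(policy$unit_convention,
    paper = 1,
    depth_scaled = 1000 / (10 * storages$depth_cm)
  )
}
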