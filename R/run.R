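#' Assemble a run configuration
#'
#' Bundles everything a scenario run needs: the climate source (a named
#' scenario preset, a custom generator configuration, or an existing
#' climate CSV), the soil profile, irrigation policy, crop table,
#' rotation, window defaults, output directory and seed. Accepts a YAML
#' file path or an equivalent named list.
#'
#' @param config Path to a YAML file, or a named list with (a subset of)
#'   the fields `scenario`, `seed`, `years`, `soil`, `policy`,
#'   `rotation`, `crop_table`, `window`, `climate_csv`, `out_dir`,
#'   `custom_scenario`.
#' @return An object of class `run_config` with resolved component
#'   objects.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  scenario <- config$scenario %||% "Tmed"
  seed <- config$seed
  if (is.null(seed) && is.null(config$climate_csv)) {
    abort("`seed` is mandatory for synthetic runs.")
  }
  years <- as.integer(config$years %||% c(1985, 2070))
  soil <- do.call(soil_profile, config$soil %||% list())
  policy <- do.call(irrigation_policy, config$policy %||% list())
  table <- if (!is.null(config$crop_table)) read_crop_table(config$crop_table) else default_crop_table()
  rot_args <- config$rotation %||% list()
  if (!is.null(rot_args$crops)) rot_args$crops <- unlist(rot_args$crops)
  plan <- do.call(rotation_plan, c(rot_args, list(table = table)))
  window <- config$window %||% list()
  structure(
    list(
      scenario = scenario, seed = seed, years = years,
      soil = soil, policy = policy, crop_table = table, plan = plan,
      start_doy = window$start_doy %||% 107,
      start_swc = window$start_swc_l_per_m3 %||% 224.9,
      climate_csv = config$climate_csv,
      out_dir = config$out_dir %||% ".",
      custom_scenario = config$custom_scenario %||% list(),
      raw = config
    ),
    class = "run_config"
  )
}

run_scenario_config <- function(rc) {
  if (identical(rc$scenario, "custom")) {
    do.call(scenario_config, c(
      list(year_range = rc$years, seed = rc$seed), rc$custom_scenario
    ))
  } else {
    scenario_preset(rc$scenario, seed = rc$seed, year_range = rc$years)
  }
}

run_metadata <- function(rc, step, files) {
  list(
    step = step,
    config_hash = rlang::hash(rc$raw),
    seed = rc$seed,
    scenario = rc$scenario,
    years = rc$years,
    package_version = as.character(utils::packageVersion("irribucket")),
    files = files
  )
}

write_metadata <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run-level commands: generate, simulate, trends, report
#'
#' The four stages of a scenario run, each writing plain-text artifacts
#' plus a metadata JSON (config hash, seed, package version) so every
#' output is regenerable from its metadata alone. Outputs are
#' deterministic given configuration and seed.
#'
#' * `run_generate()` realises the climate series and writes
#'   `climate.csv`.
#' * `run_simulate()` reads (or generates) the climate, simulates the
#'   rotation, and writes `seasons.csv` (year, crop, doy, soil water,
#'   event flag) and `annual.csv` (year, crop, n_events, total_mm, ma_mm,
#'   cap_exceeded).
#' * `run_trends()` computes Mann-Kendall and OLS trends for the rotation
#'   as a whole and per crop, writing `trends.csv`.
#' * `run_report()` summarises a run directory: totals, moving average
#'   vs cap, flagged years.
#'
#' @param rc A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Each command returns its main result invisibly
#'   (`run_generate`: the climate series; `run_simulate`: the annual
#'   tibble; `run_trends`: the trend tibble; `run_report`: a summary
#'   list).
#' @name run_commands
NULL

#' @rdname run_commands
#' @export
run_generate <- function(rc, quiet = FALSE) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  wx <- generate_daily_weather(run_scenario_config(rc))
  path <- file.path(rc$out_dir, "climate.csv")
  write_climate_csv(wx, path)
  write_metadata(run_metadata(rc, "generate", basename(path)),
                 file.path(rc$out_dir, "generate_meta.json"))
  if (!quiet) message(sprintf("Wrote %s (%d days, scenario %s)",
                              path, nrow(wx), rc$scenario))
  invisible(wx)
}

#' @rdname run_commands
#' @param climate Optional in-memory `climate_series`; otherwise read
#'   from `climate_csv`/`out_dir` or generated on the fly.
#' @export
run_simulate <- function(rc, climate = NULL, quiet = FALSE) {
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(climate)) {
    src <- rc$climate_csv %||% file.path(rc$out_dir, "climate.csv")
    climate <- if (file.exists(src)) read_climate_csv(src, scenario = rc$scenario)
               else run_generate(rc, quiet = quiet)
  }
  storages <- derive_storages(rc$soil, rc$policy)
  years <- sort(unique(climate$year))
  seasons <- purrr::map(years, function(y) {
    crop <- rotation_crop_for_year(rc$plan, y)
    w <- irrigation_window(crop, rc$crop_table, rc$start_doy, rc$start_swc)
    simulate_season(climate, y, crop, storages, rc$policy, window = w)
  })
  traces <- purrr::map_dfr(seasons, tidy)
  readr::write_csv(traces, file.path(rc$out_dir, "seasons.csv"), progress = FALSE)
  annual <- annual_from_seasons(seasons)
  annual <- cap_exceedance(moving_average(annual, rc$policy$cap_window_years),
                           rc$policy$annual_cap_mm)
  readr::write_csv(annual, file.path(rc$out_dir, "annual.csv"), progress = FALSE)
  write_metadata(run_metadata(rc, "simulate", c("seasons.csv", "annual.csv")),
                 file.path(rc$out_dir, "simulate_meta.json"))
  if (!quiet) message(sprintf("Simulated %d seasons (%d-%d)",
                              length(seasons), min(years), max(years)))
  invisible(annual)
}

annual_from_seasons <- function(seasons) {
  out <- purrr::map_dfr(seasons, function(s) {
    tibble::tibble(year = s$year, crop = s$crop,
                   n_events = s$n_events, total_mm = s$total_mm)
  })
  class(out) <- unique(c("irrig_annual", class(out)))
  out
}

#' @rdname run_commands
#' @param annual An annual tibble or the path to an `annual.csv`.
#' @param out_path Where to write the trend report CSV (`NULL` to skip).
#' @export
run_trends <- function(annual, out_path = NULL, rc = NULL) {
  if (is.character(annual)) {
    annual <- readr::read_csv(annual, col_types = readr::cols(
      year = readr::col_integer(), crop = readr::col_character(),
      cap_exceeded = readr::col_logical(),
      .default = readr::col_double()
    ), progress = FALSE)
  }
  scen <- if (!is.null(rc)) rc$scenario else "unknown"
  rows <- list(rotation_row(annual, scen, "rotation (all crops)"))
  for (cr in unique(annual$crop)) {
    sub <- annual[annual$crop == cr, , drop = FALSE]
    if (nrow(sub) >= 3) rows <- c(rows, list(rotation_row(sub, scen, cr)))
  }
  report <- dplyr::bind_rows(rows)
  if (!is.null(out_path)) readr::write_csv(report, out_path, progress = FALSE)
  report
}

rotation_row <- function(tbl, scenario, label) {
  tr <- irrigation_trend(tbl)
  tibble::tibble(
    scenario = scenario, series = label,
    tau_b = tr$mk$tau_b, p_value = tr$mk$p_value,
    slope = tr$ols$slope, r_squared = tr$ols$r_squared, n = tr$mk$n
  )
}

#' @rdname run_commands
#' @param run_dir Directory containing `annual.csv` from `run_simulate()`.
#' @export
run_report <- function(run_dir, quiet = FALSE) {
  path <- file.path(run_dir, "annual.csv")
  if (!file.exists(path)) {
    abort(sprintf("No annual.csv in '%s'. Run run_simulate() first.", run_dir))
  }
  annual <- readr::read_csv(path, col_types = readr::cols(
    year = readr::col_integer(), crop = readr::col_character(),
    cap_exceeded = readr::col_logical(),
    .default = readr::col_double()
  ), progress = FALSE)
  flagged <- annual$year[!is.na(annual$cap_exceeded) & annual$cap_exceeded]
  smry <- list(
    years = range(annual$year),
    total_events = sum(annual$n_events),
    total_mm = sum(annual$total_mm),
    mean_annual_mm = mean(annual$total_mm),
    max_ma_mm = if (all(is.na(annual$ma_mm))) NA_real_ else max(annual$ma_mm, na.rm = TRUE),
    flagged_years = flagged
  )
  if (!quiet) {
    message(sprintf(
      "Years %d-%d: %g mm total (%.1f mm/yr mean); max 7-yr MA %.1f mm; %d year(s) over cap%s",
      smry$years[1], smry$years[2], smry$total_mm, smry$mean_annual_mm,
      smry$max_ma_mm %||% NA,
      length(flagged),
      if (length(flagged) > 0) paste0(": ", paste(flagged, collapse = ", ")) else ""
    ))
  }
  invisible(smry)
}
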