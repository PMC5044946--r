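#' Default crop table for the Uelzen study region
#'
#' The ten dominant field crops of the region with their share of the
#' agricultural area, harvest day-of-year and maturation start
#' day-of-year. Maturation is assumed to begin 3 weeks (21 days) before
#' harvest for every crop, and irrigation stops at maturation start.
#'
#' @return A tibble with columns `name`, `share_pct`, `harvest_doy`,
#'   `maturity_start_doy`, validated by [validate_crop_table()].
#' @examples
#' default_crop_table()
#' @export
default_crop_table <- function() {
  tbl <- tibble::tribble(
    ~name,                                        ~share_pct, ~harvest_doy, ~maturity_start_doy,
    "Spring barley",                              9,          219L,         198L,
    "Triticale",                                  4,          219L,         198L,
    "Winter barley",                              12,         198L,         177L,
    "Winter rye",                                 5,          219L,         198L,
    "Winter wheat",                               14,         219L,         198L,
    "Winter rapeseed",                            4,          183L,         162L,
    "Winter rapeseed with organic fertilisation", 2,          208L,         187L,
    "Silage maize",                               5,          261L,         240L,
    "Potato",                                     22,         265L,         244L,
    "Sugar beet",                                 15,         290L,         269L
  )
  validate_crop_table(tbl)
}

#' Read and validate a crop table
#'
#' Reads a crop table from CSV (columns `name`, `share_pct`,
#' `harvest_doy` and optionally `maturity_start_doy` — derived as
#' harvest minus 21 days when absent).
#'
#' @param path CSV file path.
#' @return A validated crop-table tibble.
#' @export
read_crop_table <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    name = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  need <- c("name", "share_pct", "harvest_doy")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("Crop table lacks column(s): ", paste(miss, collapse = ", "), "."))
  }
  if (!"maturity_start_doy" %in% names(tbl)) {
    tbl$maturity_start_doy <- tbl$harvest_doy - 21
  }
  tbl$harvest_doy <- as.integer(tbl$harvest_doy)
  tbl$maturity_start_doy <- as.integer(tbl$maturity_start_doy)
  validate_crop_table(tbl)
}

#' @rdname read_crop_table
#' @param table A crop-table tibble to validate in place.
#' @export
validate_crop_table <- function(table) {
  if (anyDuplicated(table$name)) abort("Duplicated crop names in table.")
  bad <- which(table$harvest_doy - table$maturity_start_doy != 21L)
  if (length(bad) > 0) {
    abort(sprintf(
      "Crop '%s': maturation must start 21 days before harvest (harvest %d, maturity %d).",
      table$name[bad[1]], table$harvest_doy[bad[1]], table$maturity_start_doy[bad[1]]
    ))
  }
  bad <- which(table$maturity_start_doy < 1 | table$harvest_doy > 366)
  if (length(bad) > 0) {
    abort(sprintf("Crop '%s': days-of-year outside 1..366.", table$name[bad[1]]))
  }
  table
}

#' Maturation start day for a crop
#'
#' Looks a crop up in the table and returns its maturation start
#' day-of-year (harvest day minus 21). Irrigation is considered
#' unnecessary from this day onwards.
#'
#' @param crop Crop name.
#' @param table Crop table (default [default_crop_table()]).
#' @return Integer day-of-year.
#' @examples
#' maturity_start("Sugar beet") # 269
#' @export
maturity_start <- function(crop, table = default_crop_table()) {
  i <- match(crop, table$name)
  if (is.na(i)) {
    abort(sprintf("Unknown crop '%s'. Known: %s.", crop,
                  paste(table$name, collapse = ", ")))
  }
  table$maturity_start_doy[i]
}

#' Irrigation window for a crop
#'
#' The soil-water simulation runs from a fixed start day (default 107,
#' when the climatic water balance of an average year turns negative)
#' with a fixed start content (default 224.9 l/m3), up to but excluding
#' the crop's maturation start day: the window is half-open,
#' `[start_doy, maturity_start)`. No irrigation on or after the
#' maturation start day.
#'
#' @param crop Crop name.
#' @param table Crop table.
#' @param start_doy First day of the irrigation season (day-of-year).
#' @param start_swc_l_per_m3 Soil water content on `start_doy`, l/m3.
#' @return An object of class `irrigation_window`: list with `start_doy`,
#'   `end_doy` (exclusive), `start_swc_l_per_m3`, `n_days` and `crop`.
#' @examples
#' irrigation_window("Sugar beet")  # [107, 269)
#' irrigation_window("Winter barley") # [107, 177): 70 allowed days
#' @export
irrigation_window <- function(crop, table = default_crop_table(),
                              start_doy = 107, start_swc_l_per_m3 = 224.9) {
  end_doy <- maturity_start(crop, table)
  if (end_doy <= start_doy) {
    abort(sprintf(
      "Crop '%s' matures on day %d, on or before the season start day %d: zero-length irrigation window.",
      crop, end_doy, start_doy
    ))
  }
  structure(
    list(
      crop = crop, start_doy = as.integer(start_doy),
      end_doy = as.integer(end_doy),
      start_swc_l_per_m3 = start_swc_l_per_m3,
      n_days = as.integer(end_doy - start_doy)
    ),
    class = "irrigation_window"
  )
}

#' @export
print.irrigation_window <- function(x, ...) {
  cat(sprintf("<irrigation_window> %s: [%d, %d), %d days, start %g l/m3\n",
              x$crop, x$start_doy, x$end_doy, x$n_days, x$start_swc_l_per_m3))
  invisible(x)
}

#' Define a crop rotation plan
#'
#' An ordered crop cycle anchored to a calendar year. The default is the
#' region's most common rotation, sugar beet - potato - winter rye -
#' winter barley, anchored so that sugar beet is grown in 1991.
#'
#' @param crops Character vector of crop names, in rotation order.
#' @param anchor_year Year in which `crops[1]` is grown.
#' @param table Crop table the names must resolve in.
#' @return An object of class `rotation_plan`.
#' @export
rotation_plan <- function(crops = c("Sugar beet", "Potato", "Winter rye", "Winter barley"),
                          anchor_year = 1991,
                          table = default_crop_table()) {
  if (length(crops) == 0) abort("Rotation must contain at least one crop.")
  unknown <- setdiff(crops, table$name)
  if (length(unknown) > 0) {
    abort(paste0("Unknown crop(s) in rotation: ", paste(unknown, collapse = ", "), "."))
  }
  structure(
    list(crops = crops, anchor_year = as.integer(anchor_year)),
    class = "rotation_plan"
  )
}

#' @export
print.rotation_plan <- function(x, ...) {
  cat(sprintf("<rotation_plan> %s (anchored %d)\n",
              paste(x$crops, collapse = " - "), x$anchor_year))
  invisible(x)
}

#' Crop grown in a given year under a rotation plan
#'
#' Cycles deterministically through the plan: the crop of year `y` is
#' `crops[(y - anchor_year) mod length + 1]`. Years before the anchor are
#' handled by the same modular rule.
#'
#' @param plan A [rotation_plan()].
#' @param year Calendar year (vectorised).
#' @return Character vector of crop names.
#' @examples
#' rotation_crop_for_year(rotation_plan(), 1991:1995)
#' @export
rotation_crop_for_year <- function(plan, year) {
  stopifnot(inherits(plan, "rotation_plan"))
  idx <- (as.integer(year) - plan$anchor_year) %% length(plan$crops)
  plan$crops[idx + 1L]
}
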