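#' Read and write the daily-climate CSV format
#'
#' The on-disk format has a header row and columns `date` (ISO-8601),
#' `tmean_c`, `precip_mm`, `et0_mm`, optionally followed by the
#' Penman-Monteith driver columns `rn_mj`, `g_mj`, `u2_ms`, `es_kpa`,
#' `ea_kpa`. Decimal points, UTF-8. `read_climate_csv()` validates the
#' series on the way in ([validate_climate()]); `write_climate_csv()`
#' drops the derived `year`/`doy` columns, which are reconstructed from
#' `date` on reading, so write-then-read is an identity.
#'
#' @param path File path.
#' @param scenario Scenario label to attach to the series read.
#' @return `read_climate_csv()` returns a `climate_series` tibble;
#'   `write_climate_csv()` returns `path` invisibly.
#' @export
read_climate_csv <- function(path, scenario = "custom") {
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      date = readr::col_date(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  need <- c("date", "tmean_c", "precip_mm", "et0_mm")
  miss <- setdiff(need, names(tbl))
  if (length(miss) > 0) {
    abort(paste0("Climate CSV lacks column(s): ", paste(miss, collapse = ", "), "."))
  }
  tbl <- dplyr::mutate(
    tbl,
    year = as.integer(strftime(.data$date, "%Y")),
    doy = as.integer(strftime(.data$date, "%j")),
    .after = "date"
  )
  out <- as_climate_series(tbl, scenario = scenario)
  validate_climate(out)
  out
}

#' @rdname read_climate_csv
#' @param series A `climate_series` tibble (see [generate_daily_weather()]).
#' @export
write_climate_csv <- function(series, path) {
  validate_climate(series)
  out <- dplyr::select(as_tibble_plain(series), -dplyr::any_of(c("year", "doy")))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# strip the climate_series class for plain tibble operations
as_tibble_plain <- function(x) {
  class(x) <- setdiff(class(x), "climate_series")
  attr(x, "scenario") <- NULL
  x
}

#' Validate a daily climate series
#'
#' Checks the structural contract of a daily series: strictly increasing
#' gap-free dates, no duplicates, complete calendar years (365/366 days),
#' non-negative precipitation and ET0, and `ea <= es` where both driver
#' columns are present. Violations raise an error naming the offending
#' row or date.
#'
#' @param series A climate tibble with at least `date`, `tmean_c`,
#'   `precip_mm`, `et0_mm`.
#' @return The series, invisibly, if valid.
#' @export
validate_climate <- function(series) {
  need <- c("date", "tmean_c", "precip_mm", "et0_mm")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    abort(paste0("Climate series lacks column(s): ", paste(miss, collapse = ", "), "."))
  }
  d <- series$date
  if (anyNA(d)) abort(sprintf("Unparseable date at row %d.", which(is.na(d))[1]))
  dd <- diff(as.integer(d))
  if (any(dd == 0)) {
    abort(sprintf("Duplicated date %s (row %d).",
                  d[which(dd == 0)[1] + 1], which(dd == 0)[1] + 1))
  }
  if (any(dd < 0)) {
    abort(sprintf("Dates not increasing at row %d.", which(dd < 0)[1] + 1))
  }
  if (any(dd > 1)) {
    i <- which(dd > 1)[1]
    abort(sprintf("Gap in dates: %s is missing (after row %d).",
                  d[i] + 1, i))
  }
  bad_p <- which(is.na(series$precip_mm) | series$precip_mm < 0)
  if (length(bad_p) > 0) {
    abort(sprintf("Negative or missing precipitation at row %d (%s).",
                  bad_p[1], d[bad_p[1]]))
  }
  bad_e <- which(is.na(series$et0_mm) | series$et0_mm < 0)
  if (length(bad_e) > 0) {
    abort(sprintf("Negative or missing et0 at row %d (%s).",
                  bad_e[1], d[bad_e[1]]))
  }
  if (all(c("es_kpa", "ea_kpa") %in% names(series))) {
    bad_v <- which(series$ea_kpa > series$es_kpa + 1e-9)
    if (length(bad_v) > 0) {
      abort(sprintf("ea > es at row %d (%s).", bad_v[1], d[bad_v[1]]))
    }
  }
  yr <- as.integer(strftime(d, "%Y"))
  counts <- table(yr)
  expect <- ifelse(is_leap(as.integer(names(counts))), 366L, 365L)
  short <- which(as.integer(counts) != expect)
  if (length(short) > 0) {
    abort(sprintf("Year %s is incomplete (%d of %d days).",
                  names(counts)[short[1]], as.integer(counts)[short[1]],
                  expect[short[1]]))
  }
  invisible(series)
}

is_leap <- function(year) {
  (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
}
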