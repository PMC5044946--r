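#' Kendall's tau-b and the Mann-Kendall trend test
#'
#' Rank correlation between year and value with tie correction:
#' `tau_b = S / sqrt((n0 - n1)(n0 - n2))` where `S` is the number of
#' concordant minus discordant pairs, `n0 = n(n-1)/2` and `n1`, `n2` the
#' tie corrections for values and years. The two-sided p-value of the
#' Mann-Kendall test is exact (full null distribution of S by an
#' inversion-counting recursion) for tie-free series with `n <= 10`, and
#' otherwise uses the normal approximation with tie-adjusted variance and
#' continuity correction.
#'
#' If all values are identical, tau is undefined and returned as `NA`
#' (not 0), with p-value `NA`.
#'
#' @param years Numeric vector of years (must be distinct), or a data
#'   frame with columns `year` and `total_mm` (or the column named by
#'   `value_col`).
#' @param values Numeric vector of annual values; ignored when `years` is
#'   a data frame.
#' @param value_col Value column name used when a data frame is given.
#' @return A list with `tau_b`, `s_statistic`, `p_value`, `n` and
#'   `method` (`"exact"` or `"normal approximation"`).
#' @examples
#' kendall_tau_b(2001:2010, c(3, 5, 4, 6, 8, 7, 9, 12, 11, 13))
#' @export
kendall_tau_b <- function(years, values = NULL, value_col = "total_mm") {
  xy <- as_year_value(years, values, value_col)
  x <- xy$year
  y <- xy$value
  n <- length(x)
  if (n < 3) abort("Need at least 3 years for a trend test.")
  if (anyDuplicated(x)) abort("Years must be distinct.")
  if (length(unique(y)) == 1) {
    return(list(tau_b = NA_real_, s_statistic = 0, p_value = NA_real_,
                n = n, method = "undefined (constant series)"))
  }
  sgn <- sign(outer(y, y, "-") * outer(x, x, "-"))
  s <- sum(sgn[upper.tri(sgn)])
  n0 <- n * (n - 1) / 2
  tie_y <- table(y)
  tie_y <- tie_y[tie_y > 1]
  n1 <- sum(tie_y * (tie_y - 1) / 2)
  tau <- s / sqrt((n0 - n1) * n0) # years untied: n2 = 0
  has_ties <- length(tie_y) > 0
  if (n <= 10 && !has_ties) {
    p <- mk_exact_p(s, n)
    method <- "exact"
  } else {
    v <- (n * (n - 1) * (2 * n + 5) -
            sum(tie_y * (tie_y - 1) * (2 * tie_y + 5))) / 18
    z <- if (s > 0) (s - 1) / sqrt(v) else if (s < 0) (s + 1) / sqrt(v) else 0
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(tau_b = tau, s_statistic = s, p_value = min(p, 1), n = n,
       method = method)
}

# Exact two-sided p-value of the Mann-Kendall S statistic for tie-free
# series: counts permutations by number of discordant pairs (inversions)
# with the standard convolution recursion.
mk_exact_p <- function(s, n) {
  counts <- 1 # n = 1: one permutation, 0 inversions
  if (n > 1) {
    for (k in 2:n) {
      new <- numeric(length(counts) + k - 1)
      # inserting the k-th element adds 0..k-1 inversions
      for (j in 0:(k - 1)) {
        idx <- seq_along(counts) + j
        new[idx] <- new[idx] + counts
      }
      counts <- new
    }
  }
  n0 <- n * (n - 1) / 2
  s_vals <- n0 - 2 * (seq_along(counts) - 1) # S for 0,1,... inversions
  p_one <- sum(counts[s_vals >= abs(s)]) / sum(counts)
  min(2 * p_one, 1)
}

#' Ordinary least-squares trend of an annual series
#'
#' Fits `value ~ year` by least squares (via [stats::lm()]) and reports
#' the slope (mm/yr per year), intercept and coefficient of
#' determination. A constant series is reported with slope 0 and
#' R-squared 0 (no explained variance) rather than `NaN`.
#'
#' @inheritParams kendall_tau_b
#' @return A list with `slope`, `intercept`, `r_squared` and `n`.
#' @examples
#' ols_trend(2001:2010, 3 * (2001:2010) + 7)
#' @export
ols_trend <- function(years, values = NULL, value_col = "total_mm") {
  xy <- as_year_value(years, values, value_col)
  if (length(xy$year) < 3) abort("Need at least 3 years for a trend fit.")
  if (length(unique(xy$year)) == 1) abort("Zero variance in years.")
  if (length(unique(xy$value)) == 1) {
    # constant response: no trend, no explained variance
    return(list(slope = 0, intercept = xy$value[1], r_squared = 0,
                n = length(xy$year)))
  }
  fit <- lm(value ~ year, data = xy)
  # summary.lm warns on exact fits; the R^2 of 1 is still what we report
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2)) r2 <- 0
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, n = length(xy$year))
}

#' Trend summary of an annual irrigation series
#'
#' Combines the Mann-Kendall test ([kendall_tau_b()]) and the
#' least-squares trend ([ols_trend()]) for one annual series into a
#' single fitted object with [tidy()]/[glance()] methods.
#'
#' @inheritParams kendall_tau_b
#' @return An object of class `irrig_trend`.
#' @examples
#' wx <- generate_daily_weather(scenario_preset("Tmax", seed = 2,
#'                                              year_range = c(2011, 2040)))
#' ann <- annual_irrigation_series(wx)
#' glance(irrigation_trend(ann))
#' @export
irrigation_trend <- function(years, values = NULL, value_col = "total_mm") {
  xy <- as_year_value(years, values, value_col)
  mk <- kendall_tau_b(xy$year, xy$value)
  ols <- ols_trend(xy$year, xy$value)
  structure(
    list(mk = mk, ols = ols, data = tibble::as_tibble(xy)),
    class = "irrig_trend"
  )
}

as_year_value <- function(years, values, value_col) {
  if (is.data.frame(years)) {
    if (!all(c("year", value_col) %in% names(years))) {
      abort(sprintf("Data frame must have columns 'year' and '%s'.", value_col))
    }
    list(year = as.numeric(years$year), value = as.numeric(years[[value_col]]))
  } else {
    if (is.null(values) || length(values) != length(years)) {
      abort("`years` and `values` must be numeric vectors of equal length.")
    }
    list(year = as.numeric(years), value = as.numeric(values))
  }
}

#' @export
print.irrig_trend <- function(x, ...) {
  cat(sprintf(
    "<irrig_trend> n = %d: tau_b = %s, p = %s (%s); OLS slope = %.3f mm/yr^2, R^2 = %.3f\n",
    x$mk$n, fmt_or_na(x$mk$tau_b), fmt_or_na(x$mk$p_value), x$mk$method,
    x$ols$slope, x$ols$r_squared
  ))
  invisible(x)
}

fmt_or_na <- function(v) if (is.na(v)) "NA" else sprintf("%.3f", v)

#' @method tidy irrig_trend
#' @export
tidy.irrig_trend <- function(x, ...) {
  tibble::tibble(
    term = c("kendall_tau_b", "ols_slope"),
    estimate = c(x$mk$tau_b, x$ols$slope),
    p.value = c(x$mk$p_value, NA_real_)
  )
}

#' @method glance irrig_trend
#' @export
glance.irrig_trend <- function(x, ...) {
  tibble::tibble(
    tau_b = x$mk$tau_b, p_value = x$mk$p_value, method = x$mk$method,
    slope = x$ols$slope, r_squared = x$ols$r_squared, n_years = x$mk$n
  )
}

#' @method autoplot irrig_trend
#' @export
autoplot.irrig_trend <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$ols$intercept,
                         slope = object$ols$slope, colour = "steelblue") +
    ggplot2::labs(
      x = "Year", y = "Annual irrigation (mm)",
      title = sprintf("tau_b = %s (p = %s), slope = %.2f mm/yr², R² = %.2f",
                      fmt_or_na(object$mk$tau_b), fmt_or_na(object$mk$p_value),
                      object$ols$slope, object$ols$r_squared)
    ) +
    ggplot2::theme_minimal()
}
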