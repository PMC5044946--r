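# Shared fixtures and independent oracles, built in code.

# Deterministic daily series over whole calendar years. `precip` / `et0`
# are either scalars or functions of doy.
flat_climate <- function(years, precip = 0, et0 = 2, tmean = 10) {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])),
               by = "day")
  doy <- as.integer(strftime(dates, "%j"))
  p <- if (is.function(precip)) precip(doy) else rep(precip, length(doy))
  e <- if (is.function(et0)) et0(doy) else rep(et0, length(doy))
  structure(
    tibble::tibble(
      date = dates,
      year = as.integer(strftime(dates, "%Y")),
      doy = doy, tmean_c = tmean, precip_mm = p, et0_mm = e
    ),
    class = c("climate_series", class(tibble::tibble())),
    scenario = "custom"
  )
}

# Independent brute-force day loop: balance, clamp, threshold, event,
# re-clamp. Returns event indices (1-based within the day vectors).
oracle_bucket <- function(swc0, precip, et0, fc, wp, trigger, amount) {
  swc <- swc0
  events <- integer(0)
  trace <- numeric(length(precip))
  for (i in seq_along(precip)) {
    swc <- swc + precip[i] - et0[i]
    if (swc > fc) swc <- fc
    if (swc < wp) swc <- wp
    if (swc < trigger) {
      swc <- swc + amount
      if (swc > fc) swc <- fc
      events <- c(events, i)
    }
    trace[i] <- swc
  }
  list(events = events, n = length(events), trace = trace)
}

# Exhaustive concordant/discordant pair counting with tie correction.
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]
      dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx * dy > 0) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# Sort-and-interpolate empirical quantile (linear, type-7 convention),
# written out longhand.
oracle_quantile <- function(v, p) {
  s <- sort(v)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# run the package's daily loop with irrigation allowed on every day
run_bucket_trace <- function(swc0, precip, et0, storages, policy) {
  irribucket:::run_bucket(swc0, precip, et0, rep(TRUE, length(precip)),
                          storages, policy)
}
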