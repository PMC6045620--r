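#' Rolling accumulation of a monthly series
#'
#' The value at month `m` is the sum over the window `m - t + 1 .. m`; the
#' first `t - 1` entries are missing because their window is incomplete.
#' Windows containing missing values propagate `NA`.
#'
#' @param series numeric monthly series.
#' @param t accumulation window in months.
#' @return numeric vector of the same length.
#' @export
accumulate <- function(series, t) {
  n <- length(series)
  t <- as.integer(t)
  if (t < 1L) stop("`t` must be a positive number of months")
  if (t > n) {
    warning("accumulation window longer than the series; nothing to return")
    return(numeric(0))
  }
  out <- rep(NA_real_, n)
  for (m in t:n) out[m] <- sum(series[(m - t + 1L):m])
  out
}

#' Empirical (rank-based) standardization of a climatological sample
#'
#' Maps a sample to standard-normal scores through its empirical
#' distribution: average ranks, a plotting position, then the inverse normal
#' CDF. The default Gringorten position `(i - 0.44)/(n + 0.12)` is bounded
#' away from 0 and 1; Weibull `i/(n + 1)` is also available. Ties (including
#' runs of zero precipitation) receive average ranks, so an all-tied sample
#' maps to all zeros. Missing values are passed through.
#'
#' @param x numeric sample (one calendar-month group).
#' @param min_n minimum non-missing sample size; smaller groups return all
#'   missing with a warning.
#' @param pp plotting position, `"gringorten"` (default) or `"weibull"`.
#' @return standardized values, dimensionless.
#' @export
empirical_standardize <- function(x, min_n = 8L,
                                  pp = c("gringorten", "weibull")) {
  pp <- match.arg(pp)
  ok <- !is.na(x)
  n <- sum(ok)
  out <- rep(NA_real_, length(x))
  if (n < min_n) {
    warning(sprintf("sample of %d < %d values; returning missing", n, min_n))
    return(out)
  }
  v <- x[ok]
  if (max(v) == min(v)) {
    warning("all values tied; standardized index is 0 throughout")
    out[ok] <- 0
    return(out)
  }
  r <- rank(v, ties.method = "average")
  p <- if (pp == "gringorten") (r - 0.44) / (n + 0.12) else r / (n + 1)
  out[ok] <- stats::qnorm(p)
  out
}

# apply empirical standardization per calendar month to a (cells x time)
# matrix given the calendar-month label of each column
standardize_by_calendar_month <- function(mat, cal, min_n = 8L,
                                          pp = "gringorten") {
  out <- mat
  for (cm in unique(cal)) {
    idx <- which(cal == cm)
    sub <- mat[, idx, drop = FALSE]
    out[, idx] <- t(apply(sub, 1L, function(v)
      suppressWarnings(empirical_standardize(v, min_n = min_n, pp = pp))))
  }
  out
}

grid_to_cells <- function(g) {
  d <- dim(g)
  matrix(g, nrow = d[1L] * d[2L], ncol = d[3L])
}

cells_to_grid <- function(mat, template, units = NULL) {
  d <- dim(template)
  monthly_grid(array(mat, dim = d),
               lat = attr(template, "lat"), lon = attr(template, "lon"),
               start = attr(template, "start"),
               units = if (is.null(units)) attr(template, "units") else units)
}

#' Standardized precipitation index (SPI)
#'
#' Accumulates precipitation over `t` months and maps each calendar month's
#' sample of accumulated values to standard-normal scores by the empirical
#' (rank-based) transform, so each calendar month's index has mean near 0
#' and standard deviation near 1 by construction. Negative values are dry
#' relative to that cell's climatology, positive values wet.
#'
#' @param precip `monthly_grid` of precipitation (mm/month).
#' @param t accumulation window in months (3, 6 or 12 in the standard setup).
#' @param pp plotting position passed to [empirical_standardize()].
#' @return `monthly_grid` of the dimensionless index, with attributes
#'   `variable = "SPI"` and `scale = t`. Months whose accumulation window is
#'   not fully covered are missing.
#' @export
compute_spi <- function(precip, t, pp = "gringorten") {
  acc <- t(apply(grid_to_cells(precip), 1L, accumulate, t = t))
  if (n_months(precip) == 1L) acc <- t(acc)
  idx <- standardize_by_calendar_month(acc, calendar_months(precip), pp = pp)
  out <- cells_to_grid(idx, precip, units = "")
  attr(out, "variable") <- "SPI"
  attr(out, "scale") <- as.integer(t)
  out
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical temperature-based monthly PET: heat index
#' `I = sum((T_clim/5)^1.514)` over the 12 monthly climatological means
#' (months above 0 degC only), exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`, and
#' `PET = 16 (10 T / I)^a (L/12)(N/30)` mm/month, where `L` is mean day
#' length (hours) for the cell latitude and month and `N` the number of days
#' in the month. PET is 0 for months with `T <= 0` degC.
#'
#' @param temp `monthly_grid` of 2 m temperature (degC).
#' @param latitudes optional latitude per grid row; defaults to the grid's
#'   `lat` attribute.
#' @return `monthly_grid` of PET in mm/month.
#' @export
compute_pet_thornthwaite <- function(temp, latitudes = NULL) {
  lat <- if (is.null(latitudes)) attr(temp, "lat") else latitudes
  if (any(abs(lat) > 90)) stop("latitudes must lie in [-90, 90]")
  d <- dim(temp)
  cal <- calendar_months(temp)
  daylen <- vapply(1:12, function(m) day_length_hours(lat, m),
                   numeric(length(lat)))          # n_lat x 12
  if (length(lat) == 1L) daylen <- matrix(daylen, nrow = 1L)
  ndays <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  out <- array(0, dim = d)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    ts <- temp[i, j, ]
    clim <- vapply(1:12, function(m) mean(ts[cal == m]), numeric(1))
    pos <- pmax(clim, 0)
    I <- sum((pos[pos > 0] / 5)^1.514)
    if (I <= 0) next
    a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
    pet <- ifelse(ts > 0, 16 * (10 * ts / I)^a, 0)
    corr <- (daylen[i, cal] / 12) * (ndays[cal] / 30)
    out[i, j, ] <- pet * corr
  }
  g <- cells_to_grid(matrix(out, nrow = d[1L] * d[2L]), temp,
                     units = "mm/month")
  g
}

# mean day length (hours) for a latitude (deg) and calendar month, computed
# at the mid-month day of a 365-day year from the solar declination
day_length_hours <- function(lat_deg, month) {
  mid <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
  J <- mid[month]
  delta <- 0.409 * sin(2 * pi * J / 365 - 1.39)
  phi <- lat_deg * pi / 180
  x <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  ws <- acos(x)
  24 / pi * ws
}

#' Standardized precipitation-evapotranspiration index (SPEI)
#'
#' Like [compute_spi()] but applied to the monthly climatic water balance
#' `P - PET`, with PET from [compute_pet_thornthwaite()]. When PET is zero
#' everywhere (all months at or below 0 degC) SPEI reduces exactly to SPI.
#'
#' @inheritParams compute_spi
#' @param temp `monthly_grid` of temperature (degC), same grid and calendar
#'   as `precip`.
#' @param latitudes optional latitude per grid row.
#' @return `monthly_grid` of the dimensionless index.
#' @export
compute_spei <- function(precip, temp, t, latitudes = NULL,
                         pp = "gringorten") {
  if (!all(dim(precip) == dim(temp)))
    stop("`precip` and `temp` must share one grid and calendar")
  pet <- compute_pet_thornthwaite(temp, latitudes)
  wb <- unclass(precip) - unclass(pet)
  wbg <- cells_to_grid(matrix(wb, nrow = dim(wb)[1L] * dim(wb)[2L]),
                       precip, units = "mm/month")
  out <- compute_spi(wbg, t, pp = pp)
  attr(out, "variable") <- "SPEI"
  out
}

#' Standardized multi-month temperature indicator
#'
#' The `t`-month mean of monthly temperature, standardized per calendar
#' month by the moment-based z-score (subtract the long-term mean, divide by
#' the long-term standard deviation) - a parametric standardization, unlike
#' the rank-based SPI/SPEI transform.
#'
#' @param temp `monthly_grid` of temperature (degC).
#' @param t averaging window in months.
#' @return `monthly_grid` of the dimensionless indicator; calendar months
#'   with zero variance are missing.
#' @export
compute_t_index <- function(temp, t) {
  mat <- t(apply(grid_to_cells(temp), 1L, accumulate, t = t)) / t
  if (n_months(temp) == 1L) mat <- t(mat)
  cal <- calendar_months(temp)
  out <- mat
  for (cm in unique(cal)) {
    idx <- which(cal == cm)
    sub <- mat[, idx, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    sdv <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    sdv[sdv < 1e-12] <- NA_real_
    out[, idx] <- (sub - mu) / sdv
  }
  g <- cells_to_grid(out, temp, units = "")
  attr(g, "variable") <- "T"
  attr(g, "scale") <- as.integer(t)
  g
}

#' Candidate predictor specification
#'
#' A predictor is identified by the index variable, the accumulation window
#' `t` and the lag `m` of its target month back from the season's last month
#' `M` (lag 0 targets `M` itself, lag 5 the month five months earlier).
#'
#' @param variable `"SPI"`, `"SPEI"` or `"T"`.
#' @param t accumulation window, one of 3, 6, 12.
#' @param lag months back from the season's last month, 0..5.
#' @return list of class `indicator_spec`.
#' @export
indicator_spec <- function(variable = c("SPI", "SPEI", "T"), t, lag) {
  variable <- match.arg(variable)
  if (!t %in% c(3L, 6L, 12L)) stop("`t` must be one of 3, 6, 12")
  if (!lag %in% 0:5) stop("`lag` must be in 0..5")
  structure(list(variable = variable, t = as.integer(t),
                 lag = as.integer(lag)),
            class = "indicator_spec")
}

#' Extract a seasonal predictor series from an indicator cube
#'
#' For each season-year, picks the indicator value at the target month
#' `M - lag` (which may fall in the preceding calendar year).
#'
#' @param cube `monthly_grid` of a standardized index.
#' @param season a [season_spec()].
#' @param lag months back from the season's last month `M`.
#' @param years season-year labels to extract.
#' @return `seasonal_series` of indicator values.
#' @export
indicator_series <- function(cube, season, lag, years) {
  tg <- lag_target(season, lag)
  idx <- month_index(cube, years + tg$year_offset, tg$month)
  d <- dim(cube)
  out <- array(NA_real_, dim = c(d[1L], d[2L], length(years)))
  for (k in seq_along(years))
    if (!is.na(idx[k])) out[, , k] <- cube[, , idx[k]]
  seasonal_series(out, attr(cube, "lat"), attr(cube, "lon"),
                  season, years, units = "")
}
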