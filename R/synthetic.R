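#' Synthetic study scenario with known ground truth
#'
#' Defines a gridded synthetic world in which monthly precipitation is
#' gamma-distributed with a seasonal cycle, temperature follows a seasonal
#' cycle plus an AR(1) anomaly, and seasonal burned area responds linearly
#' to a standardized precipitation index with known per-cell sensitivity:
#' standardized BA anomaly `= beta_true * SPI_{t_true}(lag_true) + noise`.
#' Raw burned area is an affine map of the standardized anomaly (baseline
#' plus optional linear trend), floored at zero, with optional zero
#' inflation so the burnable-cell filter can be exercised.
#'
#' Per-cell fields (`beta_true`, `t_true`, `lag_true`, `noise_sd`,
#' `trend_slope`, `ba_baseline`, `ba_sd`, `zero_inflation_prob`) accept a
#' scalar (recycled) or an `(n_lat, n_lon)` matrix. `precip_shape`,
#' `precip_scale` and `temp_mean` accept a scalar or a length-12 seasonal
#' cycle. The default 21-year record with two extra lead-in years mirrors a
#' typical satellite burned-area archive length; defaults for the fire
#' response (`beta_true = -0.8`, 6-month accumulation, 1-month lag, noise sd
#' 0.3) describe a moderately strong drought-driven fire regime.
#'
#' @param n_lat,n_lon grid extents.
#' @param n_years number of season-years with burned area (>= 8; leave-one-out
#'   validation needs a meaningful training set).
#' @param spinup_years extra initial years of climate only, so that even the
#'   longest accumulation window (12 months) at the largest lag (5 months)
#'   is covered for the first burned-area year.
#' @param seed integer RNG seed; all generators derive their streams from it.
#' @param precip_shape,precip_scale gamma shape/scale of monthly
#'   precipitation (mm/month), scalar or per-calendar-month.
#' @param temp_mean seasonal cycle of monthly temperature (degC).
#' @param temp_ar1 AR(1) coefficient of the temperature anomaly.
#' @param temp_innov_sd innovation standard deviation (degC).
#' @param beta_true sensitivity of standardized BA to the true SPI predictor.
#' @param t_true true accumulation window (3, 6 or 12 months).
#' @param lag_true true lag (0..5 months) back from the season's last month.
#' @param noise_sd standard deviation of the stochastic BA noise
#'   (standardized units).
#' @param trend_slope linear trend of raw BA (area units per year).
#' @param ba_baseline,ba_sd affine map from standardized anomaly to raw BA
#'   (area units): `raw = baseline + trend + ba_sd * anomaly`, floored at 0.
#' @param zero_inflation_prob probability a season-year's BA is set to 0.
#' @return list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_lat, n_lon, n_years = 21L,
                               spinup_years = 2L, seed = 1L,
                               precip_shape = 2,
                               precip_scale = 50 * (1 + 0.4 * cos(2 * pi * (1:12 - 1) / 12)),
                               temp_mean = 15 + 10 * cos(2 * pi * (1:12 - 7) / 12),
                               temp_ar1 = 0.5, temp_innov_sd = 1,
                               beta_true = -0.8, t_true = 6L, lag_true = 1L,
                               noise_sd = 0.3, trend_slope = 0,
                               ba_baseline = 1000, ba_sd = 250,
                               zero_inflation_prob = 0) {
  if (n_years < 8L) stop("`n_years` must be at least 8")
  if (any(precip_shape <= 0) || any(precip_scale <= 0))
    stop("gamma shape and scale must be positive")
  if (any(zero_inflation_prob >= 1) || any(zero_inflation_prob < 0))
    stop("`zero_inflation_prob` must lie in [0, 1)")
  if (!all(unique(as.vector(t_true)) %in% c(3L, 6L, 12L)))
    stop("`t_true` must be one of 3, 6, 12")
  if (!all(unique(as.vector(lag_true)) %in% 0:5))
    stop("`lag_true` must lie in 0..5")
  cell_mat <- function(x) {
    if (length(x) == 1L) matrix(x, n_lat, n_lon)
    else matrix(x, n_lat, n_lon)
  }
  cyc12 <- function(x) if (length(x) == 1L) rep(x, 12L) else rep_len(x, 12L)
  structure(list(
    n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
    n_years = as.integer(n_years), spinup_years = as.integer(spinup_years),
    seed = as.integer(seed),
    precip_shape = cyc12(precip_shape), precip_scale = cyc12(precip_scale),
    temp_mean = cyc12(temp_mean), temp_ar1 = temp_ar1,
    temp_innov_sd = temp_innov_sd,
    beta_true = cell_mat(beta_true),
    t_true = cell_mat(as.integer(t_true)),
    lag_true = cell_mat(as.integer(lag_true)),
    noise_sd = cell_mat(noise_sd), trend_slope = cell_mat(trend_slope),
    ba_baseline = cell_mat(ba_baseline), ba_sd = cell_mat(ba_sd),
    zero_inflation_prob = cell_mat(zero_inflation_prob),
    ba_years = as.integer(spinup_years + seq_len(n_years))),
    class = "synthetic_scenario")
}

#' Generate synthetic monthly climate fields
#'
#' Draws per-cell monthly precipitation from the scenario's gamma
#' distributions and temperature from the seasonal cycle plus a stationary
#' AR(1) anomaly. The calendar starts in January of year 1 and spans
#' `spinup_years + n_years` years. Deterministic for a fixed scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `monthly_grid`s `precip` (mm/month) and `temp` (degC).
#' @export
generate_climate <- function(scenario) {
  s <- scenario
  ntime <- (s$n_years + s$spinup_years) * 12L
  cal <- ((seq_len(ntime) - 1L) %% 12L) + 1L
  ncell <- s$n_lat * s$n_lon
  with_seed(s$seed, {
    shape <- rep(s$precip_shape[cal], each = ncell)
    scale <- rep(s$precip_scale[cal], each = ncell)
    pr <- array(stats::rgamma(ncell * ntime, shape = shape, scale = scale),
                dim = c(s$n_lat, s$n_lon, ntime))
    innov <- array(stats::rnorm(ncell * ntime, sd = s$temp_innov_sd),
                   dim = c(s$n_lat, s$n_lon, ntime))
    anom <- innov
    anom[, , 1L] <- innov[, , 1L] / sqrt(1 - s$temp_ar1^2)
    for (k in 2L:ntime)
      anom[, , k] <- s$temp_ar1 * anom[, , k - 1L] + innov[, , k]
    tm <- sweep(anom, 3L, s$temp_mean[cal], "+")
    lat <- seq(0, by = 2.5, length.out = s$n_lat)
    lon <- seq(0, by = 2.5, length.out = s$n_lon)
    list(precip = monthly_grid(pr, lat, lon, units = "mm/month"),
         temp = monthly_grid(tm, lat, lon, units = "degC"))
  })
}

#' Generate synthetic seasonal burned area from the true SPI response
#'
#' Computes the true SPI predictor for each cell (its `t_true` accumulation
#' at lag `lag_true` from the season's last month), forms the standardized
#' anomaly `beta_true * SPI + noise`, and maps it to raw burned area
#' `baseline + trend_slope * (year - 1) + ba_sd * anomaly`, floored at 0,
#' with optional zero inflation. Deterministic for a fixed scenario seed
#' (a stream separate from the climate generator's).
#'
#' @param scenario a [synthetic_scenario()].
#' @param precip the precipitation `monthly_grid` from [generate_climate()].
#' @param season a [season_spec()]; default JJA.
#' @return `seasonal_series` of raw burned area with attributes `truth`
#'   (the scenario's per-cell parameters) and `anomaly` (the noiseless-scale
#'   standardized anomaly array actually used).
#' @export
generate_ba <- function(scenario, precip, season = season_spec("JJA")) {
  s <- scenario
  yrs <- s$ba_years
  tvals <- sort(unique(as.vector(s$t_true)))
  cubes <- lapply(tvals, function(t) compute_spi(precip, t))
  names(cubes) <- as.character(tvals)
  d <- c(s$n_lat, s$n_lon, length(yrs))
  spi_true <- array(NA_real_, dim = d)
  for (i in seq_len(s$n_lat)) for (j in seq_len(s$n_lon)) {
    cube <- cubes[[as.character(s$t_true[i, j])]]
    ser <- indicator_series(cube, season, s$lag_true[i, j], yrs)
    spi_true[i, j, ] <- ser[i, j, ]
  }
  if (anyNA(spi_true))
    stop("requested season/lag months are not covered by the record")
  with_seed(s$seed + 1000L, {
    noise <- array(stats::rnorm(prod(d)), dim = d) *
      array(rep(s$noise_sd, length(yrs)), dim = d)
    anom <- array(rep(s$beta_true, length(yrs)), dim = d) * spi_true + noise
    trend <- array(rep(s$trend_slope, length(yrs)), dim = d) *
      rep(seq_along(yrs) - 1L, each = s$n_lat * s$n_lon)
    raw <- array(rep(s$ba_baseline, length(yrs)), dim = d) + trend +
      array(rep(s$ba_sd, length(yrs)), dim = d) * anom
    raw <- pmax(raw, 0)
    zi <- array(stats::runif(prod(d)), dim = d) <
      array(rep(s$zero_inflation_prob, length(yrs)), dim = d)
    raw[zi] <- 0
    out <- seasonal_series(raw, attr(precip, "lat"), attr(precip, "lon"),
                           season, yrs, units = "ha")
    attr(out, "truth") <- s[c("beta_true", "t_true", "lag_true", "noise_sd",
                              "trend_slope", "ba_baseline", "ba_sd",
                              "zero_inflation_prob")]
    attr(out, "anomaly") <- anom
    out
  })
}

#' Pseudo-forecast system specification
#'
#' Describes a synthetic seasonal forecast system by its correlation skill
#' `alpha` per lead (fraction of the observed standardized anomaly retained;
#' the rest is independent noise), a multiplicative precipitation bias and
#' an additive temperature bias per calendar month. By convention `alpha`
#' should be non-increasing with lead, as real systems lose skill at longer
#' leads.
#'
#' @param name system name.
#' @param alpha numeric vector of length `max_lead + 1` (leads 0..L) or a
#'   scalar, each in `[0, 1]`.
#' @param precip_bias multiplicative precipitation bias, scalar or
#'   per-calendar-month (length 12).
#' @param temp_bias additive temperature bias (degC), scalar or length 12.
#' @param max_lead maximum lead L in months (>= 4 so a season issued one
#'   month before its start is fully covered).
#' @param seed RNG seed for the system's noise stream.
#' @return list of class `pseudo_forecast_spec`.
#' @export
pseudo_forecast_spec <- function(name, alpha = 0.7, precip_bias = 1,
                                 temp_bias = 0, max_lead = 4L, seed = 1L) {
  max_lead <- as.integer(max_lead)
  if (max_lead < 4L) stop("`max_lead` must be at least 4")
  alpha <- if (length(alpha) == 1L) rep(alpha, max_lead + 1L)
           else rep_len(alpha, max_lead + 1L)
  if (any(alpha < 0 | alpha > 1)) stop("`alpha` must lie in [0, 1]")
  structure(list(name = name, alpha = alpha,
                 precip_bias = rep_len(precip_bias, 12L),
                 temp_bias = rep_len(temp_bias, 12L),
                 max_lead = max_lead, seed = as.integer(seed)),
            class = "pseudo_forecast_spec")
}

#' Generate a pseudo-forecast archive from observations
#'
#' For each issue year and lead, the forecast is built around the observed
#' per-calendar-month climatology: with `z` the observed standardized
#' anomaly of the target month, the forecast anomaly is
#' `alpha(lead) * z + sqrt(1 - alpha(lead)^2) * eps` with independent
#' standard-normal `eps`, mapped back to physical units and then biased
#' (multiplicatively for precipitation, which is floored at 0; additively
#' for temperature). With `alpha = 1` and unit/zero biases the forecast
#' reproduces the observation bit for bit.
#'
#' @param spec a [pseudo_forecast_spec()].
#' @param precip,temp observed `monthly_grid`s.
#' @param years issue years (season-year labels), e.g. the scenario's
#'   `ba_years`.
#' @param season a [season_spec()]; the issue date is one month before the
#'   season's first month.
#' @return list of class `forecast_archive` with per-year, per-lead monthly
#'   precipitation and temperature fields.
#' @export
generate_forecast_system <- function(spec, precip, temp, years,
                                     season = season_spec("JJA")) {
  iss <- issue_date(season)
  nlat <- dim(precip)[1L]; nlon <- dim(precip)[2L]
  L <- spec$max_lead
  nyr <- length(years)
  cal <- calendar_months(precip)
  clim <- obs_climatology(precip)
  climt <- obs_climatology(temp)
  fp <- array(NA_real_, dim = c(nlat, nlon, L + 1L, nyr))
  ft <- array(NA_real_, dim = c(nlat, nlon, L + 1L, nyr))
  with_seed(spec$seed, {
    for (k in seq_len(nyr)) for (l in 0:L) {
      tgt <- normalize_ym(years[k] + iss$year_offset, iss$month + l)
      ti <- month_index(precip, tgt$year, tgt$month)
      if (is.na(ti)) stop("forecast lead falls outside the observed record")
      cm <- tgt$month
      a <- spec$alpha[l + 1L]
      eps <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
      op <- precip[, , ti]
      fpk <- op + (a - 1) * (op - clim$mean[, , cm]) +
        sqrt(1 - a^2) * clim$sd[, , cm] * eps
      fp[, , l + 1L, k] <- pmax(fpk * spec$precip_bias[cm], 0)
      eps2 <- matrix(stats::rnorm(nlat * nlon), nlat, nlon)
      ot <- temp[, , ti]
      ftk <- ot + (a - 1) * (ot - climt$mean[, , cm]) +
        sqrt(1 - a^2) * climt$sd[, , cm] * eps2
      ft[, , l + 1L, k] <- ftk + spec$temp_bias[cm]
    }
  })
  structure(list(name = spec$name, lat = attr(precip, "lat"),
                 lon = attr(precip, "lon"),
                 issue_month = iss$month, issue_year_offset = iss$year_offset,
                 years = as.integer(years), max_lead = L,
                 precip = fp, temp = ft,
                 alpha = spec$alpha, bias_corrected = FALSE),
            class = "forecast_archive")
}

#' @export
print.forecast_archive <- function(x, ...) {
  cat(sprintf(
    "<forecast_archive> %s: %d issue years (month %d), leads 0..%d%s\n",
    x$name, length(x$years), x$issue_month, x$max_lead,
    if (x$bias_corrected) ", bias-corrected" else ""))
  invisible(x)
}

# issue date: one month before the season's first month
issue_date <- function(season) {
  first <- season$months[1L]
  off <- season_month_year_offset(season)[1L]
  m <- first - 1L
  if (m < 1L) { m <- 12L; off <- off - 1L }
  list(month = m, year_offset = off)
}

normalize_ym <- function(year, month) {
  yoff <- (month - 1L) %/% 12L
  list(year = as.integer(year + yoff), month = as.integer(((month - 1L) %% 12L) + 1L))
}

# per-cell, per-calendar-month climatological mean and sd of a monthly grid
obs_climatology <- function(g) {
  cal <- calendar_months(g)
  d <- dim(g)
  mn <- array(NA_real_, dim = c(d[1L], d[2L], 12L))
  sdv <- array(NA_real_, dim = c(d[1L], d[2L], 12L))
  for (cm in 1:12) {
    idx <- which(cal == cm)
    if (!length(idx)) next
    sub <- g[, , idx, drop = FALSE]
    mn[, , cm] <- apply(sub, c(1L, 2L), mean)
    sdv[, , cm] <- apply(sub, c(1L, 2L), stats::sd)
  }
  list(mean = mn, sd = sdv)
}
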