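#' Leave-one-out linear-scaling bias correction of a forecast archive
#'
#' Corrects the (ensemble-mean) forecast fields against observations by
#' simple linear scaling, separately for every lead (and hence every
#' forecasted calendar month, since the archive has one issue date per
#' year): precipitation is multiplied by the ratio of observed to forecast
#' long-term means, temperature is shifted by the difference of long-term
#' means. With `loo = TRUE` (default) the scaling parameters for each year
#' exclude that year - the forecasted year never informs its own
#' correction, as an operational hindcast evaluation requires.
#'
#' Near-zero forecast precipitation climatologies make the ratio unstable;
#' the factor is capped to `cap` and capped cells are counted in the
#' returned archive's `n_capped`.
#'
#' @param archive a `forecast_archive`.
#' @param obs_precip,obs_temp observed `monthly_grid`s on the same grid and
#'   calendar the archive was built against.
#' @param loo leave-one-out correction (default) or full-period scaling.
#' @param cap numeric length-2, allowed range of the precipitation ratio.
#' @return the archive with corrected `precip`/`temp`,
#'   `bias_corrected = TRUE` and a correction log.
#' @export
bias_correct <- function(archive, obs_precip, obs_temp, loo = TRUE,
                         cap = c(0.2, 5)) {
  a <- archive
  nyr <- length(a$years)
  if (nyr < 8L) stop("need at least 8 training years per (month, lead)")
  n_capped <- 0L
  for (l in 0:a$max_lead) {
    tgt <- normalize_ym(a$years + a$issue_year_offset, a$issue_month + l)
    ti <- month_index(obs_precip, tgt$year, tgt$month)
    if (anyNA(ti)) stop("archive leads fall outside the observed record")
    op <- obs_precip[, , ti, drop = FALSE]   # nlat x nlon x nyr
    ot <- obs_temp[, , ti, drop = FALSE]
    fp <- a$precip[, , l + 1L, , drop = FALSE]
    ft <- a$temp[, , l + 1L, , drop = FALSE]
    dim(fp) <- dim(ft) <- dim(op) <- dim(ot) <- c(dim(a$precip)[1:2], nyr)
    for (k in seq_len(nyr)) {
      tr <- if (loo) setdiff(seq_len(nyr), k) else seq_len(nyr)
      mo <- apply(op[, , tr, drop = FALSE], c(1L, 2L), mean)
      mf <- apply(fp[, , tr, drop = FALSE], c(1L, 2L), mean)
      ratio <- mo / mf
      bad <- !is.finite(ratio) | ratio < cap[1L] | ratio > cap[2L]
      n_capped <- n_capped + sum(bad)
      ratio[!is.finite(ratio)] <- 1
      ratio <- pmin(pmax(ratio, cap[1L]), cap[2L])
      a$precip[, , l + 1L, k] <- fp[, , k] * ratio
      moT <- apply(ot[, , tr, drop = FALSE], c(1L, 2L), mean)
      mfT <- apply(ft[, , tr, drop = FALSE], c(1L, 2L), mean)
      a$temp[, , l + 1L, k] <- ft[, , k] + (moT - mfT)
    }
  }
  if (n_capped > 0L)
    warning(sprintf("precipitation scaling ratio capped in %d cell-years",
                    n_capped))
  a$bias_corrected <- TRUE
  a$n_capped <- n_capped
  a
}

#' Merge observations and forecasts into one accumulation-window sum
#'
#' Builds the `t`-month accumulation ending at the target month from the
#' two data sources available at forecast time: months strictly before the
#' issue month come from observations, the issue month onward from the
#' (bias-corrected) forecast leads. Windows that close before the issue
#' month are purely observational - for those predictors no dynamical
#' forecast is needed at all.
#'
#' @param obs_series numeric monthly observation series for the cell.
#' @param fc_by_lead numeric forecast values at leads `0..L` for the cell
#'   and issue date.
#' @param issue_index time index (into `obs_series`) of the issue month.
#' @param target_index time index of the window's last month.
#' @param t accumulation window (months).
#' @return scalar window sum.
#' @export
merge_window_sum <- function(obs_series, fc_by_lead, issue_index,
                             target_index, t) {
  w <- (target_index - t + 1L):target_index
  if (w[1L] < 1L) stop("window starts before the observed record")
  maxlead <- max(w) - issue_index
  if (maxlead >= length(fc_by_lead))
    stop("window requires a forecast lead beyond the archive's maximum")
  vals <- numeric(length(w))
  for (q in seq_along(w)) {
    m <- w[q]
    vals[q] <- if (m < issue_index) obs_series[m]
               else fc_by_lead[m - issue_index + 1L]
  }
  sum(vals)
}

#' Forecast-driven standardized indicator series
#'
#' For each issue year, merges observations (before the issue month) with
#' bias-corrected forecasts (from it onward) into the candidate's
#' accumulation window, then standardizes the merged value by ranking it
#' within the observed climatological sample of that calendar window - the
#' target year's own observed accumulation is replaced by the merged value,
#' so the predicted year's observation is never used. With perfect
#' forecasts the result equals the purely observational index exactly.
#'
#' @param obs `monthly_grid` of the observed variable (precipitation for
#'   SPI).
#' @param archive a (typically bias-corrected) `forecast_archive`.
#' @param t accumulation window (months).
#' @param lag months back from the season's last month.
#' @param season a [season_spec()].
#' @param pp plotting position for the rank transform.
#' @return `seasonal_series` of the standardized merged indicator for the
#'   archive's issue years.
#' @export
forecast_indicator <- function(obs, archive, t, lag,
                               season = season_spec("JJA"),
                               pp = "gringorten") {
  yrs <- archive$years
  tg <- lag_target(season, lag)
  d <- dim(obs)
  cal <- calendar_months(obs)
  cyr <- calendar_years(obs)
  # all record years whose window for this calendar target is complete
  tgt_all <- which(cal == tg$month)
  tgt_all <- tgt_all[tgt_all - t + 1L >= 1L]
  acc_obs <- matrix(NA_real_, d[1L] * d[2L], length(tgt_all))
  obs_cells <- grid_to_cells(obs)
  for (q in seq_along(tgt_all)) {
    w <- (tgt_all[q] - t + 1L):tgt_all[q]
    acc_obs[, q] <- apply(obs_cells[, w, drop = FALSE], 1L, sum)
  }
  iss_idx <- month_index(obs, yrs + archive$issue_year_offset,
                         archive$issue_month)
  tgt_idx <- month_index(obs, yrs + tg$year_offset, tg$month)
  if (anyNA(tgt_idx)) stop("target months not covered by the record")
  out <- array(NA_real_, dim = c(d[1L], d[2L], length(yrs)))
  for (k in seq_along(yrs)) {
    col <- match(tgt_idx[k], tgt_all)
    if (is.na(col)) stop("window not fully covered for year ", yrs[k])
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
      cell <- (j - 1L) * d[1L] + i
      merged <- merge_window_sum(obs_cells[cell, ],
                                 archive$precip[i, j, , k],
                                 iss_idx[k], tgt_idx[k], t)
      pool <- acc_obs[cell, ]
      pool[col] <- merged
      z <- suppressWarnings(empirical_standardize(pool, pp = pp))
      out[i, j, k] <- z[col]
    }
  }
  seasonal_series(out, attr(obs, "lat"), attr(obs, "lon"), season,
                  yrs, units = "")
}

#' Multi-model ensemble mean of forecast archives
#'
#' Averages the (bias-corrected) precipitation and temperature fields of
#' several archives sharing one grid, issue calendar and lead range.
#'
#' @param archives list of `forecast_archive`s.
#' @param name ensemble name.
#' @return a `forecast_archive`.
#' @export
ensemble_mean <- function(archives, name = "ENS") {
  a <- archives[[1L]]
  for (b in archives[-1L]) {
    if (!identical(dim(b$precip), dim(a$precip)) ||
        !identical(b$years, a$years) || b$issue_month != a$issue_month)
      stop("archives do not share a grid/issue calendar")
  }
  out <- a
  out$name <- name
  out$precip <- Reduce(`+`, lapply(archives, `[[`, "precip")) /
    length(archives)
  out$temp <- Reduce(`+`, lapply(archives, `[[`, "temp")) / length(archives)
  out$alpha <- NULL
  out$bias_corrected <- all(vapply(archives, `[[`, logical(1),
                                   "bias_corrected"))
  out
}

#' Select the best-performing forecast systems
#'
#' Ranks systems by a per-system skill summary (by convention the fraction
#' of eligible area with a significant burned-area model, averaged over
#' seasons) and returns the top `k` names; ties are broken by name order
#' for determinism.
#'
#' @param skill named numeric vector, one summary value per system.
#' @param k number of systems to retain.
#' @return character vector of `k` system names.
#' @export
select_best_systems <- function(skill, k = 3L) {
  if (is.null(names(skill))) stop("`skill` must be named by system")
  k <- min(as.integer(k), length(skill))
  names(skill)[order(-skill, names(skill))][seq_len(k)]
}

#' Fit the burned-area model with forecast-driven predictors
#'
#' The forecast counterpart of [fit_fire_model_grid()]: the 18 candidate
#' predictor series come from [forecast_indicator()] (observations merged
#' with the archive's bias-corrected forecasts across the issue date)
#' instead of purely observed indices.
#'
#' @param ba_seasonal `seasonal_series` of seasonal burned-area totals.
#' @param obs observed precipitation `monthly_grid`.
#' @param archive a bias-corrected `forecast_archive`.
#' @param mask logical eligibility matrix.
#' @param ... passed to [select_best_model()].
#' @return a `fire_fit_map`.
#' @export
fit_fire_model_forecast <- function(ba_seasonal, obs, archive, mask = NULL,
                                    ...) {
  season <- attr(ba_seasonal, "season")
  years <- attr(ba_seasonal, "years")
  cand <- candidate_predictors(season)
  series <- lapply(seq_len(nrow(cand)), function(k)
    unclass(forecast_indicator(obs, archive, cand$t[k], cand$lag[k],
                               season)))
  fit_grid_core(ba_seasonal, series, cand, mask, ...)
}
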