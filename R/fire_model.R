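#' The 18 candidate predictor specifications for a season
#'
#' All combinations of accumulation window `t` in \{3, 6, 12\} months and
#' lag `m` in 0..5 months back from the season's last month `M`, i.e. the
#' same and the five preceding months, capturing both concurrent and
#' antecedent climate conditions.
#'
#' @param season a [season_spec()].
#' @param variable index variable name attached to each candidate.
#' @return data.frame with columns `t`, `lag`, `target_month`,
#'   `target_year_offset` (18 rows, ordered by `t` then `lag`).
#' @export
candidate_predictors <- function(season, variable = "SPI") {
  grid <- expand.grid(lag = 0:5, t = c(3L, 6L, 12L))[, c("t", "lag")]
  tg <- lapply(grid$lag, function(m) lag_target(season, m))
  data.frame(variable = variable, t = grid$t, lag = grid$lag,
             target_month = vapply(tg, `[[`, integer(1), "month"),
             target_year_offset = vapply(tg, `[[`, integer(1), "year_offset"))
}

#' Leave-one-out cross-validated prediction of seasonal burned area
#'
#' For every held-out year, both the burned-area series and the predictor
#' series are robustly detrended (bisquare IRLS on the training years only)
#' and standardized by the training-year mean and standard deviation; a
#' robust regression of standardized BA on the standardized predictor is
#' then fitted on the training pairs and applied - together with the
#' trained trend, mean and sd - to the held-out year. Nothing from the
#' held-out year enters its own prediction.
#'
#' The skill of the candidate model is the Pearson correlation `r` between
#' the cross-validated predictions and the (out-of-sample standardized)
#' observations, with a one-tailed test (`H1: r > 0`, a skilful forecast
#' must correlate positively) using the t transform with `n - 2` degrees of
#' freedom. The reported `beta` is the mean of the per-fold coefficients.
#'
#' @param ba numeric series of seasonal burned area (raw units), one value
#'   per year.
#' @param predictor numeric series of the candidate indicator, same length.
#' @param c,tol,maxit IRLS settings (see [robust_detrend()]).
#' @return list with `pred` and `obs_std` (standardized units), `beta`
#'   (mean per-fold slope), `beta_folds`, `r`, `p_value`, `n`.
#' @export
loocv_predict <- function(ba, predictor, c = 4.685, tol = 1e-8,
                          maxit = 50L) {
  ok <- !is.na(ba) & !is.na(predictor)
  if (sum(ok) < 8L) stop("need at least 8 paired non-missing years")
  if (!all(ok)) stop("missing years are not supported in the LOOCV core")
  res <- .loocv_cpp(ba, cbind(predictor), c = c, tol = tol, maxit = maxit)
  finish_loocv(res)
}

finish_loocv <- function(res) {
  pred <- as.numeric(res$pred)
  obs <- as.numeric(res$obs_std)
  use <- !is.na(pred) & !is.na(obs)
  n <- sum(use)
  if (n >= 3L && stats::sd(pred[use]) > 1e-12 &&
      stats::sd(obs[use]) > 1e-12) {
    r <- stats::cor(pred[use], obs[use])
    p <- one_tailed_p(r, n)
  } else {
    r <- NA_real_; p <- NA_real_
  }
  betas <- res$betas
  list(pred = pred, obs_std = obs,
       beta = colMeans(betas, na.rm = TRUE),
       beta_folds = betas, r = r, p_value = p, n = n)
}

one_tailed_p <- function(r, n) {
  r <- min(max(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  stats::pt(tt, df = n - 2, lower.tail = FALSE)
}

#' Select the best significant candidate model for one cell
#'
#' Runs [loocv_predict()] for every candidate predictor series, tests each
#' candidate's cross-validated correlation one-tailed at the 5% level, and
#' returns the candidate with the largest `r` among the significant ones -
#' or `NULL` when no candidate is significant (the cell is left
#' unmodelled). Ties in `r` are broken deterministically towards the
#' smallest accumulation window, then the smallest lag. Alternatively
#' (`significance_filter = FALSE`) the maximum-`r` candidate is taken first
#' and its own p-value decides significance.
#'
#' @param ba numeric burned-area series.
#' @param predictors named list of candidate predictor series; names are
#'   uninterpreted labels. Provide `candidates` to attach `(t, lag)`.
#' @param candidates data.frame as from [candidate_predictors()], aligned
#'   with `predictors`.
#' @param alpha significance level of the one-tailed test.
#' @param significance_filter if `TRUE` (default) maximize `r` over the
#'   significant candidates only; if `FALSE` maximize first, then test.
#' @param ... passed to [loocv_predict()].
#' @return list of class `fire_model_fit` with elements `beta`, `t`, `lag`,
#'   `r`, `p_value`, `pred`, `obs_std`, `beta_folds`, `candidate_index`,
#'   `all_r`, `all_p`; or `NULL`.
#' @export
select_best_model <- function(ba, predictors, candidates = NULL,
                              alpha = 0.05, significance_filter = TRUE,
                              ...) {
  fits <- lapply(predictors, function(x) loocv_predict(ba, x, ...))
  rs <- vapply(fits, `[[`, numeric(1), "r")
  ps <- vapply(fits, `[[`, numeric(1), "p_value")
  if (is.null(candidates))
    candidates <- data.frame(t = seq_along(predictors),
                             lag = seq_along(predictors))
  pool <- if (significance_filter) which(!is.na(ps) & ps < alpha)
          else which(!is.na(rs))
  if (!length(pool)) return(NULL)
  ord <- pool[order(-rs[pool], candidates$t[pool], candidates$lag[pool])]
  best <- ord[1L]
  if (!significance_filter && !(ps[best] < alpha)) return(NULL)
  f <- fits[[best]]
  structure(list(beta = unname(f$beta[1L]), t = candidates$t[best],
                 lag = candidates$lag[best], r = f$r, p_value = f$p_value,
                 pred = f$pred, obs_std = f$obs_std,
                 beta_folds = f$beta_folds[, 1L],
                 candidate_index = best, all_r = rs, all_p = ps),
            class = "fire_model_fit")
}

#' Two-predictor (SPI + temperature) variant of the burned-area model
#'
#' Fits `BA_std = beta * SPI + gamma * T + noise` by the same
#' cross-validated robust procedure as [loocv_predict()], with both
#' standardized predictors sharing one `(t, lag)`. A nearly collinear
#' predictor pair is flagged but the robust fit is still returned.
#'
#' @param ba numeric burned-area series.
#' @param spi_series,t_series predictor series sharing one `(t, lag)`.
#' @param c,tol,maxit IRLS settings.
#' @return as [loocv_predict()], with `beta` of length 2 (`beta`, `gamma`)
#'   and a logical `collinear` flag.
#' @export
fit_two_predictor <- function(ba, spi_series, t_series, c = 4.685,
                              tol = 1e-8, maxit = 50L) {
  ok <- !is.na(ba) & !is.na(spi_series) & !is.na(t_series)
  if (sum(ok) < 8L) stop("need at least 8 paired non-missing years")
  if (!all(ok)) stop("missing years are not supported in the LOOCV core")
  res <- .loocv_cpp(ba, cbind(spi_series, t_series), c = c, tol = tol,
                    maxit = maxit)
  out <- finish_loocv(res)
  rho <- suppressWarnings(stats::cor(spi_series, t_series))
  out$collinear <- is.na(rho) || abs(rho) > 0.999
  if (out$collinear)
    warning("predictors are (nearly) collinear; coefficients are unstable")
  out
}

#' Fit the burned-area model over a grid
#'
#' Builds the 18 candidate predictor series per cell from precomputed
#' indicator cubes (one per accumulation window) and runs
#' [select_best_model()] on every eligible cell.
#'
#' @param ba_seasonal `seasonal_series` of seasonal burned-area totals.
#' @param cubes named list of indicator `monthly_grid`s, names `"3"`, `"6"`,
#'   `"12"` (as from [compute_spi()] at each window).
#' @param mask logical eligibility matrix, e.g. from [burnable_mask()];
#'   default all cells.
#' @param ... passed to [select_best_model()].
#' @return list of class `fire_fit_map`: matrices `beta`, `t`, `lag`, `r`,
#'   `p_value`, logical `significant`, eligibility `mask`, arrays `pred` and
#'   `obs_std` `(n_lat, n_lon, n_years)`, and `years`.
#' @export
fit_fire_model_grid <- function(ba_seasonal, cubes, mask = NULL, ...) {
  season <- attr(ba_seasonal, "season")
  years <- attr(ba_seasonal, "years")
  cand <- candidate_predictors(season)
  series <- candidate_series_arrays(cubes, cand, season, years)
  fit_grid_core(ba_seasonal, series, cand, mask, ...)
}

# shared per-cell selection loop over precomputed candidate series arrays
fit_grid_core <- function(ba_seasonal, series, cand, mask = NULL, ...) {
  season <- attr(ba_seasonal, "season")
  years <- attr(ba_seasonal, "years")
  d <- dim(ba_seasonal)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  empty <- matrix(NA_real_, d[1L], d[2L])
  out <- list(beta = empty, t = empty, lag = empty, r = empty,
              p_value = empty,
              significant = matrix(FALSE, d[1L], d[2L]), mask = mask,
              pred = array(NA_real_, dim = d),
              obs_std = array(NA_real_, dim = d), years = years,
              season = season)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    if (!mask[i, j]) next
    preds <- lapply(series, function(a) a[i, j, ])
    fit <- select_best_model(ba_seasonal[i, j, ], preds, candidates = cand,
                             ...)
    if (is.null(fit)) next
    out$beta[i, j] <- fit$beta
    out$t[i, j] <- fit$t
    out$lag[i, j] <- fit$lag
    out$r[i, j] <- fit$r
    out$p_value[i, j] <- fit$p_value
    out$significant[i, j] <- TRUE
    out$pred[i, j, ] <- fit$pred
    out$obs_std[i, j, ] <- fit$obs_std
  }
  structure(out, class = "fire_fit_map")
}

# one (n_lat, n_lon, n_years) array of predictor values per candidate
candidate_series_arrays <- function(cubes, cand, season, years) {
  lapply(seq_len(nrow(cand)), function(k) {
    cube <- cubes[[as.character(cand$t[k])]]
    if (is.null(cube)) stop("no indicator cube for t = ", cand$t[k])
    unclass(indicator_series(cube, season, cand$lag[k], years))
  })
}

#' @export
print.fire_fit_map <- function(x, ...) {
  n_el <- sum(x$mask)
  n_sig <- sum(x$significant & x$mask)
  cat(sprintf("<fire_fit_map> %s: %d eligible cells, %d with a significant model (%.1f%%)\n",
              x$season$name, n_el, n_sig, 100 * n_sig / max(n_el, 1)))
  invisible(x)
}
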