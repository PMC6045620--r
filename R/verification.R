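#' Domain skill summary of a fitted burned-area model map
#'
#' Summarizes a `fire_fit_map` over the eligible (burnable) cells: the
#' percentage of eligible cells with a significant model and the mean
#' cross-validated correlation over those significant cells. Fractions are
#' cell-count based; `area_weighted = TRUE` weights cells by `cos(lat)`.
#'
#' @param fits a `fire_fit_map`.
#' @param mask optional eligibility matrix overriding the map's own.
#' @param area_weighted weight cells by the cosine of latitude.
#' @param lat latitudes per grid row (needed for area weighting).
#' @return list with `pct_significant`, `mean_r_significant`,
#'   `n_eligible`, `n_significant`.
#' @export
skill_summary <- function(fits, mask = NULL, area_weighted = FALSE,
                          lat = NULL) {
  if (is.null(mask)) mask <- fits$mask
  sig <- fits$significant & mask
  if (area_weighted) {
    if (is.null(lat)) stop("`lat` required for area weighting")
    w <- matrix(cos(lat * pi / 180), nrow(mask), ncol(mask))
    pct <- 100 * sum(w[sig]) / sum(w[mask])
  } else {
    pct <- 100 * sum(sig) / max(sum(mask), 1L)
  }
  list(pct_significant = pct,
       mean_r_significant = if (any(sig)) mean(fits$r[sig]) else NA_real_,
       n_eligible = sum(mask), n_significant = sum(sig))
}

#' Mean absolute error of standardized predictions
#' @param pred,obs numeric vectors (standardized units); pairs with missing
#'   values are dropped.
#' @return scalar MAE.
#' @export
mae <- function(pred, obs) {
  ok <- !is.na(pred) & !is.na(obs)
  mean(abs(pred[ok] - obs[ok]))
}

#' Mean error (bias) of standardized predictions
#' @inheritParams mae
#' @return scalar ME (average prediction minus observation).
#' @export
me <- function(pred, obs) {
  ok <- !is.na(pred) & !is.na(obs)
  mean(pred[ok] - obs[ok])
}

#' Climatology null-model predictions
#'
#' The reference forecast that uses no climate information: predict each
#' year's (detrended, standardized) burned area by the long-term average of
#' the remaining years. Because the standardized series has mean zero, the
#' leave-one-out average is exactly `-z_y / (n - 1)`: an affine,
#' *decreasing* function of the held-out value, so its correlation with the
#' observations is -1 by construction. This degeneracy is inherent to a
#' literal leave-one-out climatology on standardized anomalies and is why
#' the null model's correlation skill is bounded away from the fitted
#' model's; `method = "full"` instead returns the full-period mean
#' (identically zero), a flat climatology forecast.
#'
#' @param ba numeric seasonal burned-area series (raw units).
#' @param method `"loo"` (leave-one-out mean, default) or `"full"`.
#' @param detrend robustly detrend before standardizing (default `TRUE`).
#' @return list with `pred` (standardized units) and `obs_std`.
#' @export
null_model_climatology <- function(ba, method = c("loo", "full"),
                                   detrend = TRUE) {
  method <- match.arg(method)
  z <- if (detrend) standardize(robust_detrend(ba)$residuals)
       else standardize(ba)
  n <- sum(!is.na(z))
  pred <- if (method == "loo") {
    vapply(seq_along(z), function(y)
      mean(z[-y], na.rm = TRUE), numeric(1))
  } else rep(mean(z, na.rm = TRUE), length(z))
  list(pred = pred, obs_std = z)
}

#' Correlation-difference map between a model and a null model
#'
#' Per-cell difference in prediction-observation correlation between two
#' forecast systems (typically the fitted model and a climatology null),
#' with significance from a bootstrap over years: year indices are
#' resampled with replacement, both correlations recomputed on the
#' resampled pairs, and a difference is significant when the two-sided 95%
#' bootstrap interval of `delta r` excludes zero. Both correlations share
#' the same resampled years, respecting their dependence.
#'
#' @param pred_model,pred_null arrays `(n_lat, n_lon, n_years)` of
#'   predictions.
#' @param obs array of (standardized) observations, same shape.
#' @param mask logical eligibility matrix.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed (results are reproducible for a fixed seed).
#' @param conf confidence level.
#' @return list with matrices `delta_r` and logical `significant`.
#' @export
compare_to_null <- function(pred_model, pred_null, obs, mask = NULL,
                            n_boot = 1000L, seed = 1L, conf = 0.95) {
  d <- dim(obs)
  if (is.null(mask)) mask <- matrix(TRUE, d[1L], d[2L])
  delta <- matrix(NA_real_, d[1L], d[2L])
  signif <- matrix(FALSE, d[1L], d[2L])
  alpha <- (1 - conf) / 2
  safe_cor <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) return(NA_real_)
    stats::cor(a, b)
  }
  with_seed(seed, {
    for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
      if (!mask[i, j]) next
      pm <- pred_model[i, j, ]; pn <- pred_null[i, j, ]; ob <- obs[i, j, ]
      ok <- !is.na(pm) & !is.na(pn) & !is.na(ob)
      if (sum(ok) < 5L) next
      pm <- pm[ok]; pn <- pn[ok]; ob <- ob[ok]
      n <- length(ob)
      delta[i, j] <- safe_cor(pm, ob) - safe_cor(pn, ob)
      if (identical(pm, pn)) next   # identical forecasts: delta exactly 0
      db <- numeric(n_boot)
      for (b in seq_len(n_boot)) {
        idx <- sample.int(n, n, replace = TRUE)
        db[b] <- safe_cor(pm[idx], ob[idx]) - safe_cor(pn[idx], ob[idx])
      }
      db <- db[is.finite(db)]
      if (length(db) < n_boot / 2) next
      ci <- stats::quantile(db, c(alpha, 1 - alpha), names = FALSE)
      signif[i, j] <- ci[1L] > 0 || ci[2L] < 0
    }
  })
  list(delta_r = delta, significant = signif)
}

#' Spatial pattern correlation between two per-cell maps
#'
#' Pearson correlation over the eligible cells of two maps, e.g. the fitted
#' sensitivity map against the climatological annual water balance - the
#' diagnostic that links the sign of the burned-area response to how wet a
#' cell's climate is.
#'
#' @param map_a,map_b numeric matrices `(n_lat, n_lon)`.
#' @param mask logical eligibility matrix; cells missing in either map are
#'   dropped.
#' @return scalar Pearson correlation.
#' @export
spatial_pattern_correlation <- function(map_a, map_b, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(map_a), ncol(map_a))
  ok <- mask & !is.na(map_a) & !is.na(map_b)
  stats::cor(map_a[ok], map_b[ok])
}

#' Fraction of modelled cells with negative burned-area sensitivity
#'
#' Over the eligible cells that carry a significant fitted model, the
#' fraction whose sensitivity coefficient is negative (drier conditions
#' lead to more burning).
#'
#' @param fits a `fire_fit_map`.
#' @param mask optional eligibility override.
#' @return scalar fraction in `[0, 1]` (`NA` when no cell is modelled).
#' @export
beta_sign_fraction <- function(fits, mask = NULL) {
  if (is.null(mask)) mask <- fits$mask
  sel <- fits$significant & mask & !is.na(fits$beta)
  if (!any(sel)) return(NA_real_)
  mean(fits$beta[sel] < 0)
}
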