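#' Conservative block-sum remapping of burned area to a coarser grid
#'
#' Burned area is an extensive quantity, so coarsening sums the fine cells
#' that nest inside each coarse cell; the global total is conserved exactly.
#' Fine cells must nest into coarse cells by an integer factor in both
#' directions (e.g. 0.25 deg into 2.5 deg, factor 10). Missing fine cells
#' are treated as zero in the sum; the per-cell fraction of missing fine
#' cells is returned as a diagnostic attribute `missing_fraction`.
#'
#' @param ba_fine `monthly_grid` of burned area on the fine grid.
#' @param factor integer coarsening factor per dimension.
#' @return `monthly_grid` on the coarse grid with attribute
#'   `missing_fraction` (array of the same shape).
#' @export
remap_ba_sum <- function(ba_fine, factor) {
  d <- dim(ba_fine)
  factor <- as.integer(factor)
  if (d[1L] %% factor != 0L || d[2L] %% factor != 0L)
    stop("fine grid extents must be multiples of the coarsening factor")
  nlat <- d[1L] %/% factor
  nlon <- d[2L] %/% factor
  Alat <- aggregation_matrix(nlat, factor)
  Alon <- aggregation_matrix(nlon, factor)
  out <- array(0, dim = c(nlat, nlon, d[3L]))
  mis <- array(0, dim = c(nlat, nlon, d[3L]))
  for (k in seq_len(d[3L])) {
    sl <- ba_fine[, , k]
    na <- is.na(sl)
    sl[na] <- 0
    out[, , k] <- Alat %*% sl %*% t(Alon)
    mis[, , k] <- (Alat %*% na %*% t(Alon)) / factor^2
  }
  lat_c <- colMeans(matrix(attr(ba_fine, "lat"), nrow = factor))
  lon_c <- colMeans(matrix(attr(ba_fine, "lon"), nrow = factor))
  g <- monthly_grid(out, lat_c, lon_c, start = attr(ba_fine, "start"),
                    units = attr(ba_fine, "units"))
  attr(g, "missing_fraction") <- mis
  g
}

aggregation_matrix <- function(n_coarse, factor) {
  A <- matrix(0, n_coarse, n_coarse * factor)
  for (i in seq_len(n_coarse))
    A[i, ((i - 1L) * factor + 1L):(i * factor)] <- 1
  A
}

#' Bilinear remapping of an intensive field to a new regular grid
#'
#' Standard bilinear interpolation between the four surrounding source cell
#' centers; exact for fields linear in latitude and longitude. Target points
#' outside the span of source centers are clamped to the edge (nearest
#' neighbour in that dimension).
#'
#' @param field `monthly_grid` on the source grid.
#' @param lat_out,lon_out target cell-center coordinates.
#' @return `monthly_grid` on the target grid.
#' @export
remap_bilinear <- function(field, lat_out, lon_out) {
  Wlat <- linear_weights(attr(field, "lat"), lat_out)
  Wlon <- linear_weights(attr(field, "lon"), lon_out)
  d <- dim(field)
  out <- array(NA_real_, dim = c(length(lat_out), length(lon_out), d[3L]))
  for (k in seq_len(d[3L]))
    out[, , k] <- Wlat %*% field[, , k] %*% t(Wlon)
  monthly_grid(out, lat_out, lon_out, start = attr(field, "start"),
               units = attr(field, "units"))
}

# 1-d interpolation weight matrix (n_out x n_in), clamped at the edges
linear_weights <- function(x_in, x_out) {
  W <- matrix(0, length(x_out), length(x_in))
  for (i in seq_along(x_out)) {
    x <- x_out[i]
    if (x <= x_in[1L]) { W[i, 1L] <- 1; next }
    n <- length(x_in)
    if (x >= x_in[n]) { W[i, n] <- 1; next }
    j <- findInterval(x, x_in)
    f <- (x - x_in[j]) / (x_in[j + 1L] - x_in[j])
    W[i, j] <- 1 - f
    W[i, j + 1L] <- f
  }
  W
}

#' First-order conservative remapping to a new regular grid
#'
#' Area-weighted overlap averaging between regular lat-lon grids: each
#' target cell's value is the mean of the overlapping source cells weighted
#' by the spherical area of overlap (longitude extent times the difference
#' in sine of latitude). The area-weighted mean over the common domain is
#' conserved. Cell edges lie halfway between centers.
#'
#' @param field `monthly_grid` on the source grid.
#' @param lat_out,lon_out target cell-center coordinates.
#' @return `monthly_grid` on the target grid.
#' @export
remap_conservative <- function(field, lat_out, lon_out) {
  Wlat <- overlap_matrix(attr(field, "lat"), lat_out, sine = TRUE)
  Wlon <- overlap_matrix(attr(field, "lon"), lon_out, sine = FALSE)
  den <- outer(rowSums(Wlat), rowSums(Wlon))
  d <- dim(field)
  out <- array(NA_real_, dim = c(length(lat_out), length(lon_out), d[3L]))
  for (k in seq_len(d[3L]))
    out[, , k] <- (Wlat %*% field[, , k] %*% t(Wlon)) / den
  monthly_grid(out, lat_out, lon_out, start = attr(field, "start"),
               units = attr(field, "units"))
}

# 1-d overlap weights between regular cell sets; for latitude the weight of
# an overlap [a, b] is sin(b) - sin(a) (spherical band area), for longitude
# plain length
overlap_matrix <- function(x_in, x_out, sine = FALSE) {
  res_in <- cell_resolution(x_in)
  res_out <- cell_resolution(x_out)
  W <- matrix(0, length(x_out), length(x_in))
  for (i in seq_along(x_out)) for (j in seq_along(x_in)) {
    a <- max(x_out[i] - res_out / 2, x_in[j] - res_in / 2)
    b <- min(x_out[i] + res_out / 2, x_in[j] + res_in / 2)
    if (b > a)
      W[i, j] <- if (sine) sin(b * pi / 180) - sin(a * pi / 180) else b - a
  }
  W
}

cell_resolution <- function(x) {
  if (length(x) == 1L) stop("cannot infer resolution from a single center")
  dx <- diff(x)
  if (max(abs(dx - dx[1L])) > 1e-8) stop("grid is not regular")
  abs(dx[1L])
}

#' Seasonal totals of a monthly field
#'
#' Sums the three member months of the season for each season-year. DJF is
#' labelled by the calendar year of January/February, so its December comes
#' from the preceding year. Season-years whose three member months are not
#' all present in the calendar (or any of which is missing) are missing.
#'
#' @param ba `monthly_grid` (typically burned area).
#' @param season a [season_spec()].
#' @return `seasonal_series` of seasonal totals.
#' @export
seasonal_total <- function(ba, season) {
  yrs <- sort(unique(calendar_years(ba)))
  off <- season_month_year_offset(season)
  keep <- vapply(yrs, function(y)
    !anyNA(month_index(ba, y + off, season$months)), logical(1))
  yrs <- yrs[keep]
  d <- dim(ba)
  out <- array(NA_real_, dim = c(d[1L], d[2L], length(yrs)))
  for (k in seq_along(yrs)) {
    idx <- month_index(ba, yrs[k] + off, season$months)
    out[, , k] <- ba[, , idx[1L]] + ba[, , idx[2L]] + ba[, , idx[3L]]
  }
  seasonal_series(out, attr(ba, "lat"), attr(ba, "lon"), season, yrs,
                  units = attr(ba, "units"))
}

#' Burnable-cell mask
#'
#' A cell is eligible for modelling when its seasonal burned area is nonzero
#' in more than half of the available season-years: at least
#' `floor(n/2) + 1` of `n` (11 of 21 in the standard 21-year setup). The
#' mask is invariant to positive rescaling of burned area.
#'
#' @param ba_seasonal `seasonal_series` of seasonal burned-area totals.
#' @return logical matrix `(n_lat, n_lon)`, `TRUE` where eligible.
#' @export
burnable_mask <- function(ba_seasonal) {
  d <- dim(ba_seasonal)
  out <- matrix(FALSE, d[1L], d[2L])
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    v <- ba_seasonal[i, j, ]
    n <- sum(!is.na(v))
    if (n > 0L) out[i, j] <- sum(v > 0, na.rm = TRUE) >= (n %/% 2L) + 1L
  }
  out
}

#' Robust linear detrending of a yearly series
#'
#' Fits `value ~ year index` by iteratively reweighted least squares with a
#' Tukey bisquare weight function (tuning constant 4.685, the conventional
#' 95%-Gaussian-efficiency choice; tolerance 1e-8, at most 50 iterations)
#' and returns the residuals. The robust fit resists gross outliers - a
#' single wild fire year barely moves the trend estimate. On non-convergence
#' the ordinary least-squares fit is used with a warning.
#'
#' @param series numeric yearly values; missing values are ignored in the
#'   fit and propagate to the residuals.
#' @param c bisquare tuning constant.
#' @param tol,maxit IRLS convergence tolerance and iteration cap.
#' @return list with `residuals`, `slope`, `intercept`, `converged`.
#' @export
robust_detrend <- function(series, c = 4.685, tol = 1e-8, maxit = 50L) {
  ok <- !is.na(series)
  if (sum(ok) < 5L) stop("need at least 5 non-missing points to detrend")
  yr <- seq_along(series)
  X <- cbind(1, yr[ok])
  fit <- .irls_fit_cpp(X, series[ok], c = c, tol = tol, maxit = maxit)
  if (fit$fallback)
    warning("IRLS did not converge; falling back to ordinary least squares")
  co <- as.numeric(fit$coefficients)
  res <- rep(NA_real_, length(series))
  res[ok] <- series[ok] - (co[1L] + co[2L] * yr[ok])
  list(residuals = res, slope = co[2L], intercept = co[1L],
       converged = !fit$fallback)
}

#' Moment standardization (z-scores)
#'
#' Subtracts the series mean and divides by the standard deviation. A
#' degenerate (zero-variance) series returns all missing with a warning.
#'
#' @param series numeric vector.
#' @return z-scored vector.
#' @export
standardize <- function(series) {
  mu <- mean(series, na.rm = TRUE)
  sdv <- stats::sd(series, na.rm = TRUE)
  if (!is.finite(sdv) || sdv < 1e-12) {
    warning("zero-variance series cannot be standardized")
    return(rep(NA_real_, length(series)))
  }
  (series - mu) / sdv
}
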