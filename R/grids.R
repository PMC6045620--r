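#' Monthly gridded field
#'
#' Lightweight container for a single variable on a regular latitude-longitude
#' grid with a monthly calendar: a 3-d array with dimensions
#' `(lat, lon, time)` plus coordinate and calendar attributes. Coordinates
#' refer to cell centers; the grid is assumed regular (constant spacing).
#'
#' @param data numeric array of dimension `c(length(lat), length(lon), n_time)`.
#' @param lat,lon numeric vectors of cell-center coordinates (degrees).
#' @param start integer vector `c(year, month)` of the first time slice.
#' @param units character, units of the field (e.g. `"mm/month"`, `"degC"`).
#' @return an object of class `monthly_grid`.
#' @export
monthly_grid <- function(data, lat, lon, start = c(1L, 1L), units = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (lat, lon, time)")
  if (dim(data)[1L] != length(lat) || dim(data)[2L] != length(lon))
    stop("array extent does not match `lat`/`lon`")
  if (length(start) != 2L || start[2L] < 1 || start[2L] > 12)
    stop("`start` must be c(year, month) with month in 1..12")
  structure(data,
            lat = as.numeric(lat), lon = as.numeric(lon),
            start = as.integer(start), units = units,
            class = "monthly_grid")
}

#' @export
print.monthly_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<monthly_grid> %d x %d cells, %d months starting %d-%02d [%s]\n",
              d[1L], d[2L], d[3L], attr(x, "start")[1L], attr(x, "start")[2L],
              attr(x, "units")))
  invisible(x)
}

n_months <- function(g) dim(g)[3L]

#' Calendar month (1..12) of every time slice of a monthly grid
#' @param g a `monthly_grid`.
#' @return integer vector of length `dim(g)[3]`.
#' @export
calendar_months <- function(g) {
  s <- attr(g, "start")
  ((s[2L] - 1L + seq_len(n_months(g)) - 1L) %% 12L) + 1L
}

#' Calendar year of every time slice of a monthly grid
#' @param g a `monthly_grid`.
#' @return integer vector of length `dim(g)[3]`.
#' @export
calendar_years <- function(g) {
  s <- attr(g, "start")
  s[1L] + (s[2L] - 1L + seq_len(n_months(g)) - 1L) %/% 12L
}

# time index of (year, month) in the grid calendar; NA if outside
month_index <- function(g, year, month) {
  s <- attr(g, "start")
  i <- (year - s[1L]) * 12L + (month - s[2L]) + 1L
  i[i < 1L | i > n_months(g)] <- NA_integer_
  i
}

#' Seasonal per-year series on a grid
#'
#' Container for one scalar value per cell per season-year: a 3-d array
#' `(lat, lon, year)` with the season definition and the season-year labels
#' attached. By climatological convention DJF is labelled by the calendar
#' year of January/February.
#'
#' @param data numeric array `c(n_lat, n_lon, n_years)`.
#' @param lat,lon cell-center coordinates (degrees).
#' @param season a [season_spec()].
#' @param years integer vector of season-year labels.
#' @param units character.
#' @return an object of class `seasonal_series`.
#' @export
seasonal_series <- function(data, lat, lon, season, years, units = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-d array (lat, lon, year)")
  if (dim(data)[3L] != length(years))
    stop("third extent must match `years`")
  structure(data,
            lat = as.numeric(lat), lon = as.numeric(lon),
            season = season, years = as.integer(years), units = units,
            class = "seasonal_series")
}

#' @export
print.seasonal_series <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<seasonal_series> %s, %d x %d cells, years %d..%d [%s]\n",
              attr(x, "season")$name, d[1L], d[2L],
              min(attr(x, "years")), max(attr(x, "years")), attr(x, "units")))
  invisible(x)
}

#' Season definition
#'
#' The four standard meteorological seasons. `M` is the last calendar month
#' of the season (February, May, August, November); candidate climate
#' predictors are indexed by their lag back from `M`.
#'
#' @param name one of `"DJF"`, `"MAM"`, `"JJA"`, `"SON"`.
#' @return list with `name`, `months` (member calendar months, in order) and
#'   `M` (last month). For DJF, December belongs to the preceding calendar
#'   year and the season-year is the year of January/February.
#' @export
season_spec <- function(name = c("DJF", "MAM", "JJA", "SON")) {
  name <- match.arg(name)
  months <- switch(name,
                   DJF = c(12L, 1L, 2L),
                   MAM = c(3L, 4L, 5L),
                   JJA = c(6L, 7L, 8L),
                   SON = c(9L, 10L, 11L))
  list(name = name, months = months, M = months[3L])
}

# year offset of each member month relative to the season-year label
season_month_year_offset <- function(season) {
  ifelse(season$months > season$M, -1L, 0L)
}

# target (calendar month, year offset from season-year) of lag m back from M
lag_target <- function(season, lag) {
  mm <- season$M - lag
  yoff <- (mm - 1L) %/% 12L             # negative for mm <= 0
  cm <- ((mm - 1L) %% 12L) + 1L
  list(month = cm, year_offset = as.integer(yoff))
}

# run expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Write a per-cell map to CSV
#'
#' Long-format writer (`lat`, `lon`, `value`) for any per-cell matrix such as
#' the parameter maps of a fitted model.
#'
#' @param map numeric matrix `(n_lat, n_lon)`.
#' @param lat,lon cell-center coordinates.
#' @param path output file.
#' @param name column name for the value.
#' @export
write_map_csv <- function(map, lat, lon, path, name = "value") {
  df <- data.frame(lat = rep(lat, times = length(lon)),
                   lon = rep(lon, each = length(lat)),
                   value = as.vector(map))
  names(df)[3L] <- name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
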