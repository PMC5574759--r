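#' Monthly climate series container
#'
#' Holds one station variable as a year-by-month matrix plus metadata.
#' Missing values are `NA`; years must be unique and ascending.
#'
#' @param name Variable name (e.g. "streamflow").
#' @param units Measurement units.
#' @param years Integer vector of years.
#' @param values Numeric matrix, `length(years)` rows by 12 columns.
#' @param station Optional list with `id`, `lat`, `lon`.
#' @return An object of class `climate_series`.
#' @export
climate_series <- function(name, units, years, values, station = NULL) {
  years <- as.integer(years)
  values <- as.matrix(values)
  if (ncol(values) != 12L)
    stop_ringtruth("climate series needs 12 monthly columns", "invalid_series")
  if (nrow(values) != length(years))
    stop_ringtruth("row count must match years", "invalid_series")
  if (anyDuplicated(years))
    stop_ringtruth("duplicated years in climate series", "invalid_series")
  if (is.unsorted(years))
    stop_ringtruth("years must be ascending", "invalid_series")
  dimnames(values) <- list(years, sprintf("m%02d", 1:12))
  structure(list(name = name, units = units, years = years,
                 values = values, station = station),
            class = "climate_series")
}

#' @export
print.climate_series <- function(x, ...) {
  cat(sprintf("<climate_series> %s [%s], %d years (%d-%d)\n",
              x$name, x$units, length(x$years),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Regular lat/lon gridded field
#'
#' @param lat,lon Strictly monotone coordinate vectors.
#' @param time Time axis (years).
#' @param values Array `lat x lon x time`.
#' @param units Units string.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(lat, lon, time, values, units = "") {
  values <- as.array(values)
  if (length(dim(values)) != 3L ||
      !all(dim(values) == c(length(lat), length(lon), length(time))))
    stop_ringtruth("value cube dimensions must match coordinates",
                   "invalid_field")
  mono <- function(v) all(diff(v) > 0) || all(diff(v) < 0)
  if (!mono(lat) || !mono(lon) || !all(diff(time) > 0))
    stop_ringtruth("coordinate vectors must be strictly monotone",
                   "invalid_field")
  structure(list(lat = lat, lon = lon, time = as.integer(time),
                 values = values, units = units),
            class = "gridded_field")
}
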