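# CSV schemas used across the pipeline:
#   climate   year,m01..m12
#   index     year,value
#   chronology year,index,depth
#   c14       tree_id,dendro_year,fm,fm_sd
#   curve     year,fm,fm_sd
# Missing values are empty cells.  Readers validate rather than coerce.

need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_ringtruth(sprintf("%s: missing column(s) %s", what,
                           paste(miss, collapse = ", ")),
                   "schema_error")
  invisible(df)
}

check_years_sorted <- function(years, what) {
  if (anyNA(years))
    stop_ringtruth(sprintf("%s: non-numeric or empty year", what),
                   "schema_error")
  if (is.unsorted(years, strictly = TRUE))
    stop_ringtruth(sprintf("%s: years must be strictly increasing", what),
                   "order_error")
  invisible(years)
}

#' Read / write the pipeline's CSV formats
#'
#' Typed, validated readers and writers for the plain-text interchange
#' files: monthly climate (`year,m01..m12`), annual index
#' (`year,value`), chronology (`year,index,depth`), radiocarbon
#' measurements (`tree_id,dendro_year,fm,fm_sd`) and the atmospheric
#' bomb curve (`year,fm,fm_sd`).  Readers reject missing columns
#' (schema error naming the column) and unsorted years (order error);
#' empty cells become `NA`.
#'
#' @param path File path.
#' @param name,units Variable metadata for the climate series.
#' @return The matching container: a [climate_series()], data.frame,
#'   [bomb_curve()], or (for writers) the path, invisibly.
#' @name csv_io
NULL

#' @rdname csv_io
#' @export
read_climate_csv <- function(path, name = "climate", units = "") {
  df <- utils::read.csv(path, check.names = FALSE)
  cols <- c("year", sprintf("m%02d", 1:12))
  need_cols(df, cols, path)
  check_years_sorted(df$year, path)
  climate_series(name, units, df$year, as.matrix(df[, cols[-1]]))
}

#' @rdname csv_io
#' @param x Object to write.
#' @export
write_climate_csv <- function(x, path) {
  stopifnot(inherits(x, "climate_series"))
  df <- data.frame(year = x$years, x$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_index_csv <- function(path) {
  df <- utils::read.csv(path)
  need_cols(df, c("year", "value"), path)
  check_years_sorted(df$year, path)
  df[, c("year", "value")]
}

#' @rdname csv_io
#' @export
write_index_csv <- function(x, path) {
  need_cols(x, c("year", "value"), "index data")
  utils::write.csv(x[, c("year", "value")], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_c14_csv <- function(path) {
  df <- utils::read.csv(path)
  need_cols(df, c("tree_id", "dendro_year", "fm", "fm_sd"), path)
  if (any(!is.finite(df$fm)) || any(df$fm <= 0))
    stop_ringtruth(sprintf("%s: fm must be positive", path), "schema_error")
  if (any(!is.finite(df$fm_sd)) || any(df$fm_sd <= 0))
    stop_ringtruth(sprintf("%s: fm_sd must be positive", path),
                   "schema_error")
  df
}

#' @rdname csv_io
#' @export
write_c14_csv <- function(x, path) {
  need_cols(x, c("tree_id", "dendro_year", "fm", "fm_sd"), "c14 data")
  utils::write.csv(x[, c("tree_id", "dendro_year", "fm", "fm_sd")], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  need_cols(df, c("year", "fm", "fm_sd"), path)
  if (is.unsorted(df$year, strictly = TRUE))
    stop_ringtruth(sprintf("%s: curve years must be strictly increasing",
                           path), "order_error")
  bomb_curve(df$year, df$fm, df$fm_sd)
}

#' @rdname csv_io
#' @export
write_curve_csv <- function(x, path) {
  stopifnot(inherits(x, "bomb_curve"))
  utils::write.csv(data.frame(year = x$year, fm = x$fm, fm_sd = x$fm_sd),
                   path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname csv_io
#' @export
read_chronology_csv <- function(path) {
  df <- utils::read.csv(path)
  need_cols(df, c("year", "index", "depth"), path)
  check_years_sorted(df$year, path)
  df
}

#' @rdname csv_io
#' @export
write_chronology_csv <- function(x, path) {
  df <- if (inherits(x, "chronology"))
    data.frame(year = x$years, index = x$index, depth = x$depth)
  else need_cols(x, c("year", "index", "depth"), "chronology data")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
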