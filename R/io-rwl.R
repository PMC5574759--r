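#' Read a Tucson (decadal) ring-width file
#'
#' Parses the standard dendrochronology interchange format: each line is
#' a series id, the calendar year of the first value on the line, and up
#' to ten integer ring widths in units of 0.01 mm, with lines aligned on
#' decade boundaries.  A value of 999 (or the -9999 dialect) terminates a
#' series; a value of 0 encodes a ring recorded as locally absent and is
#' kept (as width 0) to preserve year alignment.  Several series per file
#' are supported.
#'
#' @param path Path to an RWL file, or a character vector of lines.
#' @return A list of [ring_series()].
#' @examples
#' lines <- c("TST01A  1990   100   200 999")
#' read_rwl(lines)
#' @export
read_rwl <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  series <- list()
  open_id <- NULL
  open_widths <- NULL
  open_first <- NULL
  open_next_year <- NULL

  finish <- function() {
    if (is.null(open_id)) return()
    if (!is.null(series[[open_id]]))
      stop_ringtruth(sprintf("duplicate series id '%s'", open_id),
                     "rwl_format_error")
    series[[open_id]] <<- ring_series(open_id, open_first, open_widths)
    open_id <<- NULL
  }

  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line)) next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) < 2L)
      stop_ringtruth(sprintf("line %d: expected id, year and values", ln),
                     "rwl_parse_error")
    id <- tok[1]
    year <- suppressWarnings(as.integer(tok[2]))
    if (is.na(year))
      stop_ringtruth(sprintf("line %d: non-numeric year field '%s'",
                             ln, tok[2]), "rwl_parse_error")
    vals <- tok[-(1:2)]
    if (!is.null(open_id) && id != open_id) finish()
    if (is.null(open_id)) {
      if (!is.null(series[[id]]))
        stop_ringtruth(sprintf("line %d: duplicate series id '%s'", ln, id),
                       "rwl_format_error")
      open_id <- id
      open_first <- year
      open_widths <- numeric(0)
      open_next_year <- year
    } else if (year != open_next_year) {
      stop_ringtruth(sprintf(
        "line %d: series '%s' expected decade year %d, found %d",
        ln, id, open_next_year, year), "rwl_format_error")
    }
    for (v in vals) {
      num <- suppressWarnings(as.integer(v))
      if (is.na(num))
        stop_ringtruth(sprintf("line %d: non-numeric width field '%s'",
                               ln, v), "rwl_parse_error")
      if (num == 999L || num == -9999L) {       # series terminator
        finish()
        break
      }
      if (num < 0L)
        stop_ringtruth(sprintf("line %d: negative width %d", ln, num),
                       "rwl_parse_error")
      open_widths <- c(open_widths, num / 100)
      open_next_year <- open_next_year + 1L
    }
  }
  finish()
  unname(series)
}

#' Write ring series in Tucson (decadal) format
#'
#' Values are written in hundredths of a millimetre, rounded half-up,
#' with the first data line of a series ending at the decade boundary and
#' a 999 terminator after the last value.
#'
#' @param series A list of [ring_series()] (or a single one).
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Invisibly, the character vector of file lines.
#' @export
write_rwl <- function(series, path = NULL) {
  if (inherits(series, "ring_series")) series <- list(series)
  out <- character(0)
  for (rs in series) {
    # round half-up; the epsilon keeps decimal inputs like 1.005 (stored
    # as 100.4999...) on the intended side of the boundary
    hund <- floor(rs$widths * 100 + 0.5 + 1e-9)
    if (any(hund > 9998))
      stop_ringtruth(sprintf(
        "series '%s': width exceeds 99.98 mm (reserved terminator values)",
        rs$series_id), "rwl_overflow_error")
    if (any(hund == 999)) {
      # 9.99 mm is unrepresentable in the 999-terminator dialect
      warning(sprintf(
        "series '%s': width 9.99 mm stored as 9.98 mm (terminator collision)",
        rs$series_id))
      hund[hund == 999] <- 998
    }
    fields <- c(sprintf("%d", hund), "999")
    yrs <- c(years_of(rs), rs$first_year + length(rs$widths))
    i <- 1L
    while (i <= length(fields)) {
      yr <- yrs[i]
      n_take <- min(10L - yr %% 10L, length(fields) - i + 1L)
      take <- fields[i:(i + n_take - 1L)]
      out <- c(out, paste0(sprintf("%-8s", rs$series_id),
                           sprintf("%4d", yr),
                           paste(sprintf("%6s", take), collapse = "")))
      i <- i + n_take
    }
  }
  if (!is.null(path)) writeLines(out, path)
  invisible(out)
}
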