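#' One measured radius of ring widths
#'
#' A radius is an ordered run of ring widths from pith to bark together
#' with the calendar year assigned to the innermost ring by ring counting
#' (bark ring anchored to the harvest year).  A width of exactly 0 marks
#' a ring recorded as locally absent at this radius (the Tucson-format
#' convention); negative widths are rejected.
#'
#' @param series_id Identifier (tree + radius code, e.g. "T03A").
#' @param first_year Calendar year of the innermost measured ring.
#' @param widths Numeric vector of ring widths in mm, pith to bark.
#' @return An object of class `ring_series`.
#' @examples
#' ring_series("T01A", 1950, c(1.2, 0.9, 1.1))
#' @export
ring_series <- function(series_id, first_year, widths) {
  widths <- as.numeric(widths)
  if (length(widths) < 1L)
    stop_ringtruth("a ring series needs at least one ring", "invalid_series")
  if (any(!is.finite(widths)) || any(widths < 0))
    stop_ringtruth("ring widths must be finite and non-negative",
                   "invalid_series")
  structure(list(series_id = as.character(series_id),
                 first_year = as.integer(first_year),
                 widths = widths),
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series> %s: %d rings, %d-%d, mean width %.2f mm\n",
              x$series_id, length(x$widths), x$first_year,
              x$first_year + length(x$widths) - 1L, mean(x$widths)))
  invisible(x)
}

years_of <- function(rs) seq(rs$first_year, by = 1L,
                             length.out = length(rs$widths))
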