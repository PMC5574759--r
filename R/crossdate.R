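#' Critical correlation for crossdating segments
#'
#' One-tailed Pearson critical value at significance `alpha` for sample
#' size `n`, via the t distribution (about 0.52 for n = 20 at p = .01).
#' @param n Segment length.
#' @param alpha One-tailed significance level.
#' @return Critical r.
#' @export
critical_r <- function(n = 20L, alpha = 0.01) {
  tq <- stats::qt(1 - alpha, df = n - 2L)
  tq / sqrt(n - 2L + tq^2)
}

#' Running-segment crossdating check of one series against the master
#'
#' The standard dating quality control: the candidate series is compared,
#' in overlapping segments (default 20 years, starts every 10), against a
#' master chronology built from all other series.  A segment fails when
#' its Pearson correlation falls below `crit_r`.  For every segment a
#' lag search over `-max_lag..max_lag` reports the shift maximizing the
#' correlation; a positive best lag means the series matches the master
#' better when its years are moved later, i.e. the series is currently
#' dated too old (too early) by that many years.
#'
#' @param series A `detrended_series` (residual index) to check.
#' @param master A `chronology` or a data.frame/list with `years` and
#'   `index`, built excluding `series`.
#' @param seg_len Segment length in years.
#' @param lag Offset between segment starts.
#' @param crit_r Critical correlation (default [critical_r()] at the
#'   segment length, one-tailed p = .01).
#' @param max_lag Half-width of the lag search window.
#' @return A `crossdate_report` data.frame: series_id, seg_start,
#'   seg_end, partial, r, pass, best_lag, best_r.  Zero rows when the
#'   overlap is shorter than one segment.
#' @export
crossdate_check <- function(series, master, seg_len = 20L, lag = 10L,
                            crit_r = critical_r(seg_len, 0.01),
                            max_lag = 10L) {
  stopifnot(inherits(series, "detrended_series"))
  myrs <- master$years
  midx <- master$index
  common <- intersect(series$years, myrs)
  empty <- structure(data.frame(series_id = character(0),
                                seg_start = integer(0), seg_end = integer(0),
                                partial = logical(0), r = numeric(0),
                                pass = logical(0), best_lag = integer(0),
                                best_r = numeric(0)),
                     class = c("crossdate_report", "data.frame"))
  if (length(common) < seg_len) return(empty)
  lo <- min(common); hi <- max(common)
  starts <- seq(lo, hi, by = lag)
  starts <- starts[starts + seg_len - 1L <= hi]
  # one trailing partial segment (>= half length) if years remain
  if (length(starts)) {
    nxt <- starts[length(starts)] + lag
    if (nxt <= hi && hi - nxt + 1L >= seg_len %/% 2L) starts <- c(starts, nxt)
  } else starts <- lo
  rows <- lapply(starts, function(st) {
    en <- min(st + seg_len - 1L, hi)
    partial <- (en - st + 1L) < seg_len
    yrs <- st:en
    sv <- series$index[match(yrs, series$years)]
    mv <- midx[match(yrs, myrs)]
    r <- safe_cor(sv, mv)
    lags <- -max_lag:max_lag
    lr <- vapply(lags, function(L) {
      # shift the series' year labels by +L before matching
      mv2 <- midx[match(yrs + L, myrs)]
      r2 <- safe_cor(sv, mv2)
      if (is.na(r2)) -Inf else r2
    }, numeric(1))
    best <- which.max(lr)
    data.frame(series_id = series$series_id, seg_start = st, seg_end = en,
               partial = partial, r = r,
               pass = !is.na(r) && r >= crit_r,
               best_lag = lags[best], best_r = lr[best])
  })
  structure(do.call(rbind, rows),
            class = c("crossdate_report", "data.frame"))
}

#' Leave-one-out master chronology
#'
#' Biweight mean chronology of all series except the one named, used as
#' the comparison master in [crossdate_check()].
#'
#' @param series_list List of `detrended_series`.
#' @param exclude_id Series id left out.
#' @param min_depth Passed to [build_chronology()].
#' @return A `chronology`.
#' @export
master_excluding <- function(series_list, exclude_id, min_depth = 2L) {
  rest <- Filter(function(s) s$series_id != exclude_id, series_list)
  if (length(rest) < 2L)
    stop_ringtruth("need at least two other series for a master",
                   "empty_chronology")
  build_chronology(rest, min_depth = min_depth)
}

#' Crossdate every series against its leave-one-out master
#'
#' @param series_list List of `detrended_series`.
#' @param ... Passed to [crossdate_check()].
#' @return A `crossdate_report` with all series' segment rows.
#' @export
crossdate_all <- function(series_list, ...) {
  reports <- lapply(series_list, function(s) {
    m <- tryCatch(master_excluding(series_list, s$series_id),
                  ringtruth_error = function(e) NULL)
    if (is.null(m)) return(NULL)
    crossdate_check(s, m, ...)
  })
  structure(do.call(rbind, reports),
            class = c("crossdate_report", "data.frame"))
}

#' @export
print.crossdate_report <- function(x, ...) {
  cat(sprintf("<crossdate_report> %d segments, %d fail (%.1f%%)\n",
              nrow(x), sum(!x$pass),
              if (nrow(x)) 100 * mean(!x$pass) else 0))
  if (nrow(x)) {
    bad <- x[!x$pass, ]
    if (nrow(bad)) {
      cat("  failing segments (positive best_lag = dated too old):\n")
      print.data.frame(utils::head(bad, 10), row.names = FALSE)
    }
  }
  invisible(x)
}
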