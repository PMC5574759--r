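#' Screen a candidate climate series for use in correlation analysis
#'
#' Runs the three admission tests applied to every annual predictor
#' before correlation analysis: Shapiro-Wilk (normality), Mann-Kendall
#' (monotone trend; implemented as Kendall's tau of the series against
#' time) and Pettitt (single change point / homogeneity).  The series
#' passes when all three are non-significant at `alpha`.
#'
#' @param x Numeric annual series (n >= 20; NAs dropped).
#' @param alpha Significance level per test.
#' @return List with `pass` (logical) and `tests` (data.frame: test,
#'   statistic, p, pass).
#' @export
screen_series <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20L)
    stop_ringtruth("screening requires at least 20 values",
                   "precondition_error")
  sw <- stats::shapiro.test(x)
  mk <- suppressWarnings(stats::cor.test(x, seq_len(n), method = "kendall"))
  pt <- pettitt_test(x)
  tests <- data.frame(
    test = c("shapiro_wilk", "mann_kendall", "pettitt"),
    statistic = c(unname(sw$statistic), unname(mk$estimate), pt$statistic),
    p = c(sw$p.value, mk$p.value, pt$p),
    stringsAsFactors = FALSE)
  tests$pass <- tests$p >= alpha
  list(pass = all(tests$pass), tests = tests)
}

# Pettitt single change-point test: K = max_k |U_k| with
# U_k = sum_{i<=k} sum_{j>k} sign(x_i - x_j); approximate two-sided
# p = 2 exp(-6 K^2 / (n^3 + n^2)).
pettitt_test <- function(x) {
  n <- length(x)
  r <- rank(x)
  # U_k = 2 * sum(r_1..k) - k * (n + 1)  (rank formulation)
  U <- 2 * cumsum(r)[-n] - seq_len(n - 1L) * (n + 1)
  K <- max(abs(U))
  p <- min(1, 2 * exp(-6 * K^2 / (n^3 + n^2)))
  list(statistic = K, p = p, change_point = which.max(abs(U)))
}

#' Aggregate a monthly climate series over a month window
#'
#' @param clim A [climate_series()].
#' @param months Integer months (1-12) within the calendar year, e.g.
#'   `10:12` for October--December.
#' @param stat `"mean"` or `"total"`.
#' @return data.frame with `year` and `value`; a year missing any
#'   selected month is `NA`.
#' @examples
#' # OND mean streamflow
#' # seasonalize(flow, months = 10:12, stat = "mean")
#' @export
seasonalize <- function(clim, months, stat = c("mean", "total")) {
  stopifnot(inherits(clim, "climate_series"))
  stat <- match.arg(stat)
  months <- as.integer(months)
  if (!length(months) || any(months < 1L | months > 12L))
    stop_ringtruth("months must be a non-empty subset of 1..12",
                   "domain_error")
  sub <- clim$values[, months, drop = FALSE]
  val <- if (stat == "mean") rowMeans(sub) else rowSums(sub)
  data.frame(year = clim$years, value = as.numeric(val))
}

# Align two annual (year, value) series on common years with pairwise
# deletion of missing values.
align_years <- function(x, y) {
  common <- intersect(x$year, y$year)
  xv <- x$value[match(common, x$year)]
  yv <- y$value[match(common, y$year)]
  ok <- is.finite(xv) & is.finite(yv)
  list(year = common[ok], x = xv[ok], y = yv[ok])
}

as_annual <- function(obj) {
  if (inherits(obj, "chronology"))
    return(data.frame(year = obj$years, value = obj$index))
  if (is.data.frame(obj)) {
    if (all(c("year", "value") %in% names(obj)))
      return(obj[, c("year", "value")])
    if (all(c("year", "index") %in% names(obj)))
      return(data.frame(year = obj$year, value = obj$index))
  }
  stop_ringtruth("cannot interpret object as an annual series",
                 "domain_error")
}

# Vectorized bootstrap Pearson correlations for case-resampled pairs.
boot_cor <- function(x, y, n_boot, seed) {
  n <- length(x)
  with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    xb <- matrix(x[idx], nrow = n)
    yb <- matrix(y[idx], nrow = n)
    xm <- colMeans(xb); ym <- colMeans(yb)
    sxy <- colSums(xb * yb) - n * xm * ym
    sxx <- colSums(xb * xb) - n * xm^2
    syy <- colSums(yb * yb) - n * ym^2
    r <- sxy / sqrt(sxx * syy)
    r[!is.finite(r)] <- NA_real_
    r
  })
}

#' Bootstrapped Pearson correlation between a chronology and a predictor
#'
#' Pearson correlation on the years common to both inputs, with a
#' nonparametric confidence interval from percentile bootstrap of
#' year-pairs (case resampling).  Significance is declared when the
#' interval excludes zero.  Deterministic for a fixed seed.
#'
#' @param chron A `chronology` or data.frame with year/value.
#' @param y Annual predictor: data.frame with `year`, `value`.
#' @param period Optional year range `c(first, last)` to restrict to.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @param label Predictor label carried into the result.
#' @param aggregation Aggregation tag carried into the result.
#' @return A one-row data.frame of class `response_result`: label,
#'   aggregation, period, n, r, ci_low, ci_high, significant.
#' @export
correlate_bootstrap <- function(chron, y, period = NULL, n_boot = 1000L,
                                seed = 1L, conf = 0.95,
                                label = "predictor",
                                aggregation = "annual") {
  cx <- as_annual(chron)
  cy <- as_annual(y)
  if (!is.null(period)) {
    cx <- cx[cx$year >= period[1] & cx$year <= period[2], ]
    cy <- cy[cy$year >= period[1] & cy$year <= period[2], ]
  }
  al <- align_years(cx, cy)
  n <- length(al$year)
  if (n < 15L)
    stop_ringtruth(sprintf(
      "only %d overlapping years (need >= 15): correlation refused", n),
      "overlap_error")
  r <- stats::cor(al$x, al$y)
  rb <- boot_cor(al$x, al$y, n_boot, seed)
  qs <- stats::quantile(rb, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  out <- data.frame(label = label, aggregation = aggregation,
                    first_year = min(al$year), last_year = max(al$year),
                    n = n, r = r, ci_low = qs[1], ci_high = qs[2],
                    significant = qs[1] > 0 | qs[2] < 0)
  class(out) <- c("response_result", "data.frame")
  out
}

#' Monthly bootstrapped correlations with a climate variable
#'
#' One [correlate_bootstrap()] per calendar month of the growth year.
#' Months whose overlap is too short are reported with `NA` and
#' `refused = TRUE` instead of aborting the rest.
#'
#' @param chron A `chronology`.
#' @param clim A [climate_series()].
#' @param period Optional year range.
#' @param n_boot,seed,conf As in [correlate_bootstrap()].
#' @return A 12-row data.frame (class `response_result`) with a
#'   `month` column and a `refused` flag.
#' @export
monthly_response <- function(chron, clim, period = NULL, n_boot = 1000L,
                             seed = 1L, conf = 0.95) {
  rows <- lapply(1:12, function(m) {
    y <- seasonalize(clim, months = m, stat = "mean")
    res <- tryCatch(
      correlate_bootstrap(chron, y, period = period, n_boot = n_boot,
                          seed = derive_seed(seed, m), conf = conf,
                          label = clim$name, aggregation = month.abb[m]),
      ringtruth_error = function(e)
        data.frame(label = clim$name, aggregation = month.abb[m],
                   first_year = NA, last_year = NA, n = NA,
                   r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                   significant = NA))
    res$month <- m
    res$refused <- is.na(res$r)
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("response_result", "data.frame")
  out
}

#' Correlation map between an annual series and a gridded field
#'
#' Per-cell Pearson correlation with a two-sided percentile-inversion
#' bootstrap p-value (`p = 2 * min(P(r* <= 0), P(r* >= 0))`, ties counted
#' half), masked at `p < alpha` (default .10).  Constant cells are
#' flagged undefined rather than fatal.
#'
#' @param x Annual series (data.frame `year`, `value`).
#' @param field A [gridded_field()].
#' @param n_boot Bootstrap replicates per cell.
#' @param seed Integer seed.
#' @param alpha Masking level.
#' @return A `field_correlation`: list with `lat`, `lon`, `r`, `p`
#'   (matrices lat x lon), `mask` (TRUE where p < alpha), `alpha`, `n`.
#' @export
field_correlate <- function(x, field, n_boot = 500L, seed = 1L,
                            alpha = 0.10) {
  stopifnot(inherits(field, "gridded_field"))
  ax <- as_annual(x)
  common <- intersect(ax$year, field$time)
  if (length(common) < 15L)
    stop_ringtruth("field and series share fewer than 15 years",
                   "overlap_error")
  xi <- ax$value[match(common, ax$year)]
  ti <- match(common, field$time)
  n <- length(common)
  nlat <- length(field$lat); nlon <- length(field$lon)
  rmat <- pmat <- matrix(NA_real_, nlat, nlon)
  idx <- with_seed(seed,
                   matrix(sample.int(n, n * n_boot, replace = TRUE),
                          nrow = n))
  xb <- matrix(xi[idx], nrow = n)
  xbm <- colMeans(xb)
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    y <- field$values[i, j, ti]
    if (!all(is.finite(y)) || stats::sd(y) == 0) next
    rmat[i, j] <- stats::cor(xi, y)
    yb <- matrix(y[idx], nrow = n)
    ybm <- colMeans(yb)
    num <- colSums(xb * yb) - n * xbm * ybm
    den <- sqrt((colSums(xb^2) - n * xbm^2) * (colSums(yb^2) - n * ybm^2))
    rb <- num / den
    rb <- rb[is.finite(rb)]
    ple <- (sum(rb < 0) + 0.5 * sum(rb == 0)) / length(rb)
    pge <- (sum(rb > 0) + 0.5 * sum(rb == 0)) / length(rb)
    pmat[i, j] <- min(1, 2 * min(ple, pge))
  }
  structure(list(lat = field$lat, lon = field$lon, r = rmat, p = pmat,
                 mask = !is.na(pmat) & pmat < alpha, alpha = alpha,
                 n = n),
            class = "field_correlation")
}

#' @export
print.field_correlation <- function(x, ...) {
  cat(sprintf(
    "<field_correlation> %d x %d cells, n = %d, %d significant at p < %.2f\n",
    length(x$lat), length(x$lon), x$n, sum(x$mask, na.rm = TRUE), x$alpha))
  invisible(x)
}

#' Write a response table / field map as CSV
#'
#' @param x A `response_result` or `field_correlation`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_response_csv <- function(x, path) {
  if (inherits(x, "field_correlation")) {
    grid <- expand.grid(lat = x$lat, lon = x$lon)
    df <- data.frame(grid, r = as.vector(x$r), p = as.vector(x$p),
                     masked = as.vector(!x$mask))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                     quote = FALSE, na = "")
  }
  invisible(path)
}
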