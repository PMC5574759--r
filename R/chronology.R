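#' Tukey biweight robust mean
#'
#' Iteratively reweighted location estimate with the bisquare weight
#' function, tuning constant `c` on the MAD scale.  If the MAD is zero
#' the median is returned (outliers then carry zero weight).  Equals the
#' arithmetic mean exactly when all inputs are equal, and always lies
#' within the range of the inputs.
#'
#' @param x Numeric vector.
#' @param const Tuning constant (default 9, the dendro convention).
#' @param tol,max_iter Convergence tolerance / iteration cap.
#' @return The robust mean (scalar).
#' @examples
#' biweight_mean(c(1, 1, 1, 1, 100))
#' @export
biweight_mean <- function(x, const = 9, tol = 1e-8, max_iter = 50L) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  if (length(x) == 1L) return(x)
  m <- stats::median(x)
  s <- stats::median(abs(x - m))
  if (s == 0) return(m)
  for (i in seq_len(max_iter)) {
    u <- (x - m) / (const * s)
    wt <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(wt) == 0) return(m)
    m_new <- sum(wt * x) / sum(wt)
    if (abs(m_new - m) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Build a mean chronology from residual series
#'
#' Averages the available residual (prewhitened, detrended) indices in
#' each calendar year with the Tukey biweight robust mean, records the
#' sample depth, and drops years with fewer than `min_depth` series.
#' Chronology-level quality statistics -- mean inter-series correlation,
#' expressed population signal and first-order autocorrelation -- are
#' attached when computable.
#'
#' @param series_list List of `detrended_series` (residual indices).
#' @param min_depth Minimum number of series required in a retained year.
#' @param biweight_const Tuning constant for [biweight_mean()].
#' @param n_trees Number of trees behind the series (for EPS); default:
#'   distinct series ids with the final radius letter stripped.
#' @return An object of class `chronology`: list with `years`, `index`,
#'   `depth`, `rbar`, `rbar_tree`, `eps`, `lag1`, `n_series`, `n_trees`.
#' @export
build_chronology <- function(series_list, min_depth = 2L,
                             biweight_const = 9, n_trees = NULL) {
  stopifnot(length(series_list) >= 1L)
  yrs <- sort(unique(unlist(lapply(series_list, function(s) s$years))))
  mat <- matrix(NA_real_, nrow = length(yrs), ncol = length(series_list))
  ids <- vapply(series_list, function(s) s$series_id, character(1))
  colnames(mat) <- make.unique(ids)
  for (j in seq_along(series_list)) {
    s <- series_list[[j]]
    mat[match(s$years, yrs), j] <- s$index
  }
  depth <- rowSums(!is.na(mat))
  keep <- depth >= min_depth
  if (!any(keep))
    stop_ringtruth("no year reaches the minimum sample depth: empty chronology",
                   "empty_chronology")
  idx <- apply(mat[keep, , drop = FALSE], 1L, biweight_mean,
               const = biweight_const)
  n_trees <- n_trees %||% length(unique(sub("[A-Z]$", "", ids)))
  rbar <- tryCatch(mean_interseries_correlation(series_list),
                   ringtruth_error = function(e) list(rbar = NA_real_,
                                                      rbar_tree = NA_real_))
  ch <- structure(list(years = yrs[keep], index = idx,
                       depth = depth[keep],
                       rbar = rbar$rbar, rbar_tree = rbar$rbar_tree,
                       eps = if (is.na(rbar$rbar)) NA_real_
                             else eps(max(rbar$rbar, 0), n_trees),
                       lag1 = NA_real_,
                       n_series = length(series_list),
                       n_trees = n_trees),
                  class = "chronology")
  ch$lag1 <- tryCatch(lag1_autocorrelation(ch),
                      ringtruth_error = function(e) NA_real_)
  ch
}

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("<chronology> %d years (%d-%d), %d series / %d trees\n",
              length(x$years), min(x$years), max(x$years),
              x$n_series, x$n_trees))
  cat(sprintf("  rbar = %.3f (tree-averaged %.3f), EPS = %.3f, lag-1 = %.3f\n",
              x$rbar, x$rbar_tree, x$eps, x$lag1))
  invisible(x)
}

#' @export
plot.chronology <- function(x, ...) {
  graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  graphics::plot(x$years, x$index, type = "l", ylab = "index", xlab = "", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::plot(x$years, x$depth, type = "s", ylab = "sample depth",
                 xlab = "year")
  invisible(x)
}

#' @export
summary.chronology <- function(object, ...) {
  cat("Residual tree-ring chronology\n")
  print(object)
  cat(sprintf("  mean index %.3f, sd %.3f, max depth %d\n",
              mean(object$index), stats::sd(object$index),
              max(object$depth)))
  invisible(object)
}

#' Mean inter-series correlation (rbar)
#'
#' Mean of pairwise Pearson correlations over all pairs of series whose
#' common years number at least `min_overlap`.  Two statistics are
#' returned: over all qualifying pairs of series, and the tree-averaged
#' variant restricted to pairs of series from different trees (series
#' ids are grouped by stripping the trailing radius letter).
#'
#' @param series_list List of `detrended_series`.
#' @param min_overlap Minimum pairwise overlap in years (default 20).
#' @return List with `rbar` (all pairs), `rbar_tree` (between-tree
#'   pairs) and `n_pairs`.
#' @export
mean_interseries_correlation <- function(series_list, min_overlap = 20L) {
  k <- length(series_list)
  if (k < 2L)
    stop_ringtruth("need at least two series for rbar", "undefined_rbar")
  ids <- vapply(series_list, function(s) s$series_id, character(1))
  tree_of <- sub("[A-Z]$", "", ids)
  rs <- c(); between <- c()
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    a <- series_list[[i]]; b <- series_list[[j]]
    common <- intersect(a$years, b$years)
    if (length(common) < min_overlap) next
    r <- safe_cor(a$index[match(common, a$years)],
                  b$index[match(common, b$years)])
    if (is.na(r)) next
    rs <- c(rs, r)
    between <- c(between, tree_of[i] != tree_of[j])
  }
  if (!length(rs))
    stop_ringtruth("no series pair overlaps enough years: rbar undefined",
                   "undefined_rbar")
  list(rbar = mean(rs),
       rbar_tree = if (any(between)) mean(rs[between]) else NA_real_,
       n_pairs = length(rs))
}

#' Expressed population signal (EPS)
#'
#' Closed form `EPS = n * rbar / (n * rbar + (1 - rbar))` for a
#' chronology of `n` trees with mean inter-series correlation `rbar`.
#' EPS is monotone non-decreasing in both arguments; the conventional
#' reliability threshold is 0.85.
#'
#' @param rbar Mean inter-series correlation in \[0, 1\] (negative values
#'   return 0 with a warning).
#' @param n Number of trees (>= 1).
#' @return EPS in \[0, 1\].
#' @examples
#' eps(0.49, 15)
#' @export
eps <- function(rbar, n) {
  if (!is.finite(rbar) || rbar < -1 || rbar > 1)
    stop_ringtruth("rbar must lie in [-1, 1]", "domain_error")
  stopifnot(n >= 1)
  if (rbar < 0) {
    warning("negative rbar: EPS reported as 0")
    return(0)
  }
  n * rbar / (n * rbar + (1 - rbar))
}

#' Running-window EPS and reliability onset
#'
#' Computes rbar, tree count and EPS in sliding windows, counting a
#' series as present when it covers at least `min_frac` of the window.
#' The reliability onset is the first window start from which EPS stays
#' at or above `threshold`.
#'
#' @param series_list List of `detrended_series`.
#' @param window Window length in years (>= 30).
#' @param step Step between window starts.
#' @param threshold EPS reliability threshold (default 0.85).
#' @param min_frac Fraction of the window a series must cover.
#' @return List with `windows` (data.frame: start, end, n_series,
#'   n_trees, rbar, eps) and `onset` (year or NA).
#' @export
running_eps <- function(series_list, window = 50L, step = 25L,
                        threshold = 0.85, min_frac = 0.8) {
  if (window < 30L)
    stop_ringtruth("running EPS window must be at least 30 years",
                   "precondition_error")
  yrs <- range(unlist(lapply(series_list, function(s) s$years)))
  starts <- seq(yrs[1], yrs[2] - window + 1L, by = step)
  if (!length(starts))
    stop_ringtruth("span shorter than one window", "precondition_error")
  rows <- lapply(starts, function(st) {
    en <- st + window - 1L
    present <- Filter(function(s)
      sum(s$years >= st & s$years <= en) >= min_frac * window, series_list)
    if (length(present) < 2L)
      return(data.frame(start = st, end = en, n_series = length(present),
                        n_trees = NA, rbar = NA, eps = NA))
    clipped <- lapply(present, function(s) {
      sel <- s$years >= st & s$years <= en
      s$years <- s$years[sel]; s$index <- s$index[sel]; s
    })
    rb <- tryCatch(mean_interseries_correlation(clipped)$rbar,
                   ringtruth_error = function(e) NA_real_)
    ids <- vapply(present, function(s) s$series_id, character(1))
    ntr <- length(unique(sub("[A-Z]$", "", ids)))
    data.frame(start = st, end = en, n_series = length(present),
               n_trees = ntr, rbar = rb,
               eps = if (is.na(rb)) NA_real_ else eps(max(rb, 0), ntr))
  })
  win <- do.call(rbind, rows)
  ok <- !is.na(win$eps) & win$eps >= threshold
  onset <- if (any(ok)) win$start[which(ok)[1]] else NA_integer_
  list(windows = win, onset = onset)
}

#' First-order autocorrelation of a chronology
#'
#' Pearson correlation of the index with itself shifted one year.
#'
#' @param chron A `chronology`, or a numeric vector.
#' @return The lag-1 correlation.
#' @export
lag1_autocorrelation <- function(chron) {
  x <- if (inherits(chron, "chronology")) chron$index else as.numeric(chron)
  n <- length(x)
  if (n < 20L)
    stop_ringtruth("need at least 20 years for lag-1 autocorrelation",
                   "precondition_error")
  if (stats::sd(x) == 0)
    stop_ringtruth("constant series: lag-1 autocorrelation undefined",
                   "domain_error")
  stats::cor(x[-n], x[-1])
}
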