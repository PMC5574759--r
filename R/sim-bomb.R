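#' Stylized atmospheric bomb-pulse radiocarbon curve
#'
#' Returns a built-in stylized Northern-Hemisphere post-bomb Fm14C curve
#' at annual (mid-year) resolution: a flat pre-1955 plateau at 0.98, a
#' strictly monotone rise to a single peak of 1.80 at 1964.5, and a
#' strictly monotone exponential decay reaching 1.05 by 2006.  The curve
#' is a documented synthetic stand-in with a constant reported SD; a real
#' atmospheric compilation can be supplied instead through
#' [read_curve_csv()].
#'
#' @param years Integer calendar years covered (mid-year points are used).
#' @param sd Constant 1-sigma uncertainty attached to every curve value.
#' @return A `bomb_curve`: list with `year` (decimal mid-years), `fm`,
#'   `fm_sd`.
#' @examples
#' crv <- gen_bomb_curve()
#' crv$year[which.max(crv$fm)]  # 1964.5
#' @export
gen_bomb_curve <- function(years = 1900:2010, sd = 0.002) {
  t <- years + 0.5
  base <- 0.98
  peak <- 1.80
  t_peak <- 1964.5
  t_rise <- 1955
  # decay rate chosen so the curve passes through 1.05 at 2006.0
  rate <- log((peak - 1.0) / (1.05 - 1.0)) / (2006.0 - t_peak)
  fm <- ifelse(t < t_rise, base,
        ifelse(t <= t_peak,
               base + (peak - base) * ((t - t_rise) / (t_peak - t_rise))^2,
               1.0 + (peak - 1.0) * exp(-rate * (t - t_peak))))
  bomb_curve(t, fm, rep(sd, length(t)))
}

#' Bomb-curve container
#'
#' @param year Strictly increasing decimal years.
#' @param fm Fraction-modern values (> 0).
#' @param fm_sd 1-sigma uncertainties (> 0).
#' @return An object of class `bomb_curve`.
#' @export
bomb_curve <- function(year, fm, fm_sd) {
  if (any(diff(year) <= 0))
    stop_ringtruth("curve time axis must be strictly increasing",
                   "invalid_curve")
  if (any(fm <= 0) || any(fm_sd <= 0))
    stop_ringtruth("curve fm and fm_sd must be positive", "invalid_curve")
  structure(list(year = as.numeric(year), fm = as.numeric(fm),
                 fm_sd = as.numeric(fm_sd)),
            class = "bomb_curve")
}

#' @export
print.bomb_curve <- function(x, ...) {
  cat(sprintf("<bomb_curve> %d points, %.1f-%.1f, peak Fm %.3f at %.1f\n",
              length(x$year), min(x$year), max(x$year),
              max(x$fm), x$year[which.max(x$fm)]))
  invisible(x)
}

# Curve value at the mid-point of a calendar year, by linear
# interpolation of the curve's time axis.
curve_at <- function(curve, year) {
  stats::approx(curve$year, curve$fm, xout = year + 0.5, rule = 2)$y
}

curve_sd_at <- function(curve, year) {
  stats::approx(curve$year, curve$fm_sd, xout = year + 0.5, rule = 2)$y
}

#' Simulate radiocarbon measurements on selected rings
#'
#' Mimics the bomb-peak validation design: on each selected tree a fixed
#' number of rings spaced a fixed number of ring positions apart is
#' sampled, and each sampled ring receives
#' `Fm = curve(true calendar year) + Normal(0, meas_sd_fm)`.
#' Both the dendro year (ring counting, which may be wrong) and the
#' hidden true year are recorded so tests can assert recovery.
#'
#' @param truth A `truth_table` from [gen_ring_series()].
#' @param curve A `bomb_curve`.
#' @param cfg The [sim_config()] (for `meas_sd_fm` and `seed`).
#' @param trees Integer ids of the trees to sample (default: all).
#' @param n_samples Rings sampled per tree.
#' @param spacing Ring positions between consecutive samples.
#' @param positions Optional explicit ring positions (pith = 1),
#'   overriding `n_samples`/`spacing`.  Default: `n_samples` positions
#'   stepping `spacing` inward from the anchor ring.
#' @param anchor_year Dendro year of the bark-most sampled ring; `NULL`
#'   anchors at the bark.  Anchoring shortly after the spike
#'   concentrates the samples on the rise and decay of the bomb pulse,
#'   the informative part of the curve.
#' @return A data.frame with columns tree, position, dendro_year,
#'   true_year, fm, fm_sd.
#' @export
gen_14c_measurements <- function(truth, curve, cfg, trees = NULL,
                                 n_samples = 8, spacing = 10,
                                 positions = NULL, anchor_year = NULL) {
  stopifnot(inherits(truth, "truth_table"), inherits(curve, "bomb_curve"))
  trees <- trees %||% unique(truth$rings$tree)
  out <- list()
  for (tr in trees) {
    rings <- truth$rings[truth$rings$tree == tr, ]
    m <- nrow(rings)
    top <- if (is.null(anchor_year)) m
           else {
             hit <- which(rings$dendro_year == anchor_year)
             if (length(hit)) hit[1] else m
           }
    pos <- if (!is.null(positions)) positions
           else sort(seq(from = top, by = -spacing,
                         length.out = n_samples))
    if (any(pos < 1L | pos > m))
      stop_ringtruth(sprintf(
        "tree %d: requested ring position outside 1..%d", tr, m),
        "selection_error")
    sel <- rings[match(pos, rings$position), ]
    fm_true <- curve_at(curve, sel$true_year)
    noise <- with_seed(derive_seed(cfg$seed, 5000L + tr),
                       stats::rnorm(length(pos), sd = cfg$meas_sd_fm))
    out[[length(out) + 1L]] <-
      data.frame(tree = tr, position = sel$position,
                 dendro_year = sel$dendro_year, true_year = sel$true_year,
                 fm = fm_true + noise, fm_sd = cfg$meas_sd_fm)
  }
  do.call(rbind, out)
}
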