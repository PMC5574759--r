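#' Candidate calendar years for one radiocarbon measurement
#'
#' Finds every calendar year whose (annually interpolated) curve value
#' lies within `k_sigma` combined standard deviations of the measured
#' fraction modern: `|fm - curve(y)| <= k_sigma * sqrt(fm_sd^2 +
#' curve_sd^2)`.  Contiguous matching years collapse to runs reported
#' with their center and half-width.  A run touching the start of the
#' curve lies on the pre-bomb plateau, where the curve is flat and the
#' match constrains the date only as "at or before the rise": it is
#' flagged open-ended.  A measurement above the curve maximum plus
#' tolerance yields zero runs (flagged, not fatal).
#'
#' @param fm Measured fraction modern.
#' @param fm_sd Its 1-sigma uncertainty.
#' @param curve A [bomb_curve()].
#' @param k_sigma Match tolerance in combined sigmas (default 2).
#' @return data.frame with columns start, end, center, half_width,
#'   open_start (zero rows if no year matches).
#' @export
candidate_years <- function(fm, fm_sd, curve, k_sigma = 2) {
  stopifnot(inherits(curve, "bomb_curve"), fm_sd > 0)
  years <- floor(min(curve$year)):floor(max(curve$year))
  # a ring grown in year y draws carbon over the whole season, so year y
  # matches when the tolerance band overlaps the curve's range across
  # [y, y+1] (interval matching; midpoint-only evaluation can slip
  # through the band on the steep limbs)
  c_lo <- stats::approx(curve$year, curve$fm, xout = years, rule = 2)$y
  c_mid <- curve_at(curve, years)
  c_hi <- stats::approx(curve$year, curve$fm, xout = years + 1, rule = 2)$y
  cmin <- pmin(c_lo, c_mid, c_hi)
  cmax <- pmax(c_lo, c_mid, c_hi)
  cs <- curve_sd_at(curve, years)
  tol <- k_sigma * sqrt(fm_sd^2 + cs^2)
  hit <- (fm + tol) >= cmin & (fm - tol) <= cmax
  if (!any(hit))
    return(data.frame(start = integer(0), end = integer(0),
                      center = numeric(0), half_width = numeric(0),
                      open_start = logical(0)))
  rl <- rle(hit)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  runs <- which(rl$values)
  out <- data.frame(start = years[starts[runs]], end = years[ends[runs]])
  out$center <- (out$start + out$end) / 2
  out$half_width <- (out$end - out$start) / 2
  out$open_start <- out$start == years[1]
  out
}

#' Sequence-constrained calendar-date assignment for a tree's samples
#'
#' Given a tree's radiocarbon samples ordered pith to bark, chooses one
#' candidate calendar year per sample so that assigned years are
#' strictly increasing along the ring order and the total absolute
#' offset from the dendro years is minimal (dynamic program over the
#' candidate years).  Samples whose only candidates lie on the open
#' pre-bomb plateau are reported as bounds (`plateau = TRUE`, assigned
#' year NA) and excluded from the optimization, mirroring the
#' qualitative treatment such samples admit.  A sample whose dendro year
#' lies within +/-1 year of its assigned year is flagged coincident;
#' samples where the optimum is not unique are flagged ambiguous.
#'
#' Candidate sets on the two bomb-curve limbs can be several years
#' apart; the ring count between consecutive samples disambiguates
#' them, because a tree lays down at least one ring per year: between
#' two sampled rings the number of elapsed calendar years can exceed
#' the number of counted rings only by the (few) rings locally absent
#' from the measured radius.  The dynamic program therefore also
#' enforces `delta(assigned) <= delta(position) + allow_missing`.
#'
#' @param samples data.frame with columns `position` (pith = 1),
#'   `dendro_year`, `fm`, `fm_sd` for one tree.
#' @param curve A [bomb_curve()].
#' @param k_sigma Match tolerance passed to [candidate_years()].
#' @param allow_missing Maximum uncounted (locally absent) rings allowed
#'   per sampled interval in the ring-count constraint.
#' @return A `c14_assignment` data.frame: position, dendro_year, fm,
#'   assigned_year, offset (`assigned_year - dendro_year` in years;
#'   positive means the dendro date is too old, i.e. that many excess
#'   rings were counted after this ring), coincident, ambiguous,
#'   plateau, no_candidate.
#' @export
assign_tree_dates <- function(samples, curve, k_sigma = 2,
                              allow_missing = 2L) {
  req <- c("position", "dendro_year", "fm", "fm_sd")
  need_cols(samples, req, "c14 samples")
  samples <- samples[order(samples$position), , drop = FALSE]
  n <- nrow(samples)
  cand <- vector("list", n)
  plateau <- no_cand <- logical(n)
  for (i in seq_len(n)) {
    runs <- candidate_years(samples$fm[i], samples$fm_sd[i], curve, k_sigma)
    closed <- runs[!runs$open_start, , drop = FALSE]
    plateau[i] <- nrow(runs) > 0 && all(runs$open_start)
    no_cand[i] <- nrow(runs) == 0
    cand[[i]] <- if (nrow(closed))
      unlist(lapply(seq_len(nrow(closed)),
                    function(k) closed$start[k]:closed$end[k]))
    else integer(0)
  }
  usable <- which(!plateau & !no_cand)
  assigned <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  if (length(usable)) {
    sel <- dp_monotone(cand[usable],
                       samples$dendro_year[usable],
                       samples$position[usable], allow_missing)
    assigned[usable] <- sel$years
    ambiguous[usable] <- sel$ambiguous
  }
  out <- data.frame(position = samples$position,
                    dendro_year = samples$dendro_year,
                    fm = samples$fm,
                    assigned_year = assigned,
                    offset = assigned - samples$dendro_year,
                    coincident = !is.na(assigned) &
                      abs(samples$dendro_year - assigned) <= 1L,
                    ambiguous = ambiguous,
                    plateau = plateau,
                    no_candidate = no_cand)
  class(out) <- c("c14_assignment", "data.frame")
  out
}

# Minimal-total-|offset| strictly increasing assignment via dynamic
# programming over candidate years.  Errors when no monotone selection
# exists, naming the first violating pair of ring positions.
dp_monotone <- function(cand, dendro, positions, allow_missing = 2L) {
  m <- length(cand)
  cost <- vector("list", m)     # minimal cost ending with cand[[i]][j]
  tie <- vector("list", m)      # was that minimum attained twice?
  for (i in seq_len(m)) {
    ci <- cand[[i]]
    own <- abs(dendro[i] - ci)
    if (i == 1L) {
      cost[[i]] <- own
      tie[[i]] <- rep(FALSE, length(ci))
      next
    }
    prev_y <- cand[[i - 1L]]
    prev_c <- cost[[i - 1L]]
    prev_t <- tie[[i - 1L]]
    cost[[i]] <- rep(Inf, length(ci))
    tie[[i]] <- rep(FALSE, length(ci))
    max_step <- positions[i] - positions[i - 1L] + allow_missing
    for (j in seq_along(ci)) {
      ok <- prev_y < ci[j] & (ci[j] - prev_y) <= max_step
      if (!any(ok)) next
      cc <- prev_c[ok]
      best <- min(cc)
      cost[[i]][j] <- best + own[j]
      tie[[i]][j] <- sum(cc == best) > 1L || any(prev_t[ok][cc == best])
    }
    if (all(!is.finite(cost[[i]])))
      stop_ringtruth(sprintf(
        "no strictly increasing date assignment between ring positions %d and %d",
        positions[i - 1L], positions[i]), "infeasible_assignment")
  }
  # backtrack the optimum
  years <- integer(m)
  amb <- logical(m)
  jbest <- which.min(cost[[m]])
  if (sum(cost[[m]] == min(cost[[m]])) > 1L) amb[m] <- TRUE
  years[m] <- cand[[m]][jbest]
  amb[m] <- amb[m] || tie[[m]][jbest]
  if (m > 1L) for (i in (m - 1L):1L) {
    ok <- cand[[i]] < years[i + 1L] &
      (years[i + 1L] - cand[[i]]) <=
        positions[i + 1L] - positions[i] + allow_missing
    resid <- cost[[i]]
    resid[!ok] <- Inf
    jbest <- which.min(resid)
    if (sum(resid == min(resid)) > 1L) amb[i] <- TRUE
    years[i] <- cand[[i]][jbest]
    amb[i] <- amb[i] || tie[[i]][jbest]
  }
  list(years = years, ambiguous = amb)
}

#' @export
print.c14_assignment <- function(x, ...) {
  cat(sprintf(
    "<c14_assignment> %d samples, %d coincident (+/-1 yr), %d plateau-bounded\n",
    nrow(x), sum(x$coincident), sum(x$plateau)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Excess ring formation rate per decade
#'
#' For each consecutive pair of dated samples the excess is the number
#' of counted rings between them minus the number of assigned calendar
#' years, normalized per decade of assigned time.  Mean and population
#' SD (divisor n) across pairs are returned.
#'
#' @param assignment A `c14_assignment` (plateau/unassigned samples are
#'   skipped).
#' @param interval Optional assigned-year range `c(first, last)` to
#'   restrict the pairs used.
#' @return List with `mean`, `sd`, `rates` (per-pair rates),
#'   `n_pairs`, and `sd_convention = "population"`.
#' @export
excess_per_decade <- function(assignment, interval = NULL) {
  a <- assignment[!is.na(assignment$assigned_year), , drop = FALSE]
  if (!is.null(interval))
    a <- a[a$assigned_year >= interval[1] &
             a$assigned_year <= interval[2], , drop = FALSE]
  if (nrow(a) < 2L)
    stop_ringtruth("need at least two dated samples in the interval",
                   "undefined_error")
  a <- a[order(a$position), ]
  d_rings <- diff(a$position)
  d_years <- diff(a$assigned_year)
  rates <- (d_rings - d_years) / d_years * 10
  m <- mean(rates)
  list(mean = m, sd = sqrt(mean((rates - m)^2)), rates = rates,
       n_pairs = length(rates), sd_convention = "population")
}

#' Cumulative dating mismatch along a sampled sequence
#'
#' Running sum of absolute per-interval ring-count mismatches, ordered
#' bark to pith; the total at the oldest boundary is the headline
#' cumulative mismatch.
#'
#' @param mismatches Signed per-interval mismatch counts (rings), bark
#'   to pith.
#' @return List with `running` (cumulative absolute sums) and `total`.
#' @examples
#' cumulative_mismatch(c(4, -3))$total   # 7
#' @export
cumulative_mismatch <- function(mismatches) {
  stopifnot(is.numeric(mismatches))
  running <- cumsum(abs(mismatches))
  list(running = running,
       total = if (length(running)) running[length(running)] else 0)
}

#' Per-tree offset summary for the validation report
#'
#' @param assignments Named list of `c14_assignment` (one per tree).
#' @return data.frame: tree, n_dated, mean_abs_offset, max_abs_offset,
#'   excess_mean, excess_sd.
#' @export
offset_summary <- function(assignments) {
  rows <- lapply(names(assignments), function(id) {
    a <- assignments[[id]]
    dated <- a[!is.na(a$offset), , drop = FALSE]
    ex <- tryCatch(excess_per_decade(a),
                   ringtruth_error = function(e) list(mean = NA, sd = NA))
    data.frame(tree = id, n_dated = nrow(dated),
               mean_abs_offset = if (nrow(dated)) mean(abs(dated$offset))
                                 else NA_real_,
               max_abs_offset = if (nrow(dated)) max(abs(dated$offset))
                                else NA_real_,
               excess_mean = ex$mean, excess_sd = ex$sd)
  })
  do.call(rbind, rows)
}
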