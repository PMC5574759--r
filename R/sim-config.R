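#' Configuration for the synthetic floodplain-forest simulation
#'
#' Bundles every parameter of the synthetic-data generator: stand layout,
#' the negative-exponential age trend, the strength of the shared
#' hydroclimatic growth signal, ring-level noise, the rates at which
#' intra-annual (extra) rings and locally absent rings occur, and the
#' radiocarbon measurement uncertainty.
#'
#' The defaults describe a stand of 15 trees measured on 31 radii over
#' 1830--2006, with a lognormal ring-noise SD calibrated so that the mean
#' inter-series correlation of the detrended series is close to 0.5, and
#' intra-annual ring formation that is frequent early on but ceases after
#' `stabilization_year` (older trees form fewer sub-annual bands).  Extra
#' rings are driven by stand-wide intra-annual stress years shared by all
#' trees, so the trees stay mutually crossdatable even when their calendar
#' dates drift from the truth; locally absent (wedging) rings are
#' independent per radius.
#'
#' @param n_trees Number of trees in the stand.
#' @param radii_per_tree Candidate radii counts per tree; each tree is
#'   assigned one of these at random (default 2 or 3).
#' @param span Length-2 integer vector, first and last calendar year of
#'   the simulation (trees are harvested in the last year).
#' @param age_trend Named vector `c(A, k, c)` of the negative-exponential
#'   growth curve `A * exp(-k * age) + c` (mm, 1/yr, mm).
#' @param beta Dimensionless sensitivity of log ring width to the
#'   standardized October--December streamflow signal.
#' @param sigma_ring Lognormal SD of per-radius ring-width noise.
#' @param p_extra Per-year probability of a stand-wide intra-annual stress
#'   year before `stabilization_year`; in such a year every tree splits
#'   its increment into two anatomically indistinguishable rings.
#' @param p_extra_recent Same probability from `stabilization_year`
#'   onwards (default 0: recent rings are annual).
#' @param stabilization_year Calendar year after which extra-ring
#'   formation drops to `p_extra_recent`.
#' @param p_missing Per-radius, per-year probability that a ring is
#'   locally absent (wedging) on that radius.
#' @param mark_absent If `TRUE` (default) locally absent rings are
#'   detected during the circumference evaluation -- as wedging rings
#'   are on full cross sections -- and recorded as 0-width rings, so
#'   year alignment is preserved; if `FALSE` they are silently dropped
#'   and shift the radius' ring-counted dates.
#' @param meas_sd_fm 1-sigma uncertainty of a fraction-modern radiocarbon
#'   measurement (dimensionless Fm units; 0.003 = 0.3\%).
#' @param coupling Coupling of the ENSO-like index to streamflow (index
#'   units; negative: warm phase lowers flow).
#' @param phi_index AR(1) coefficient of the ENSO-like annual index.
#' @param climate_noise Named vector of monthly noise SDs for
#'   `precip` (mm), `temp` (deg C) and `flow` (m3/s).
#' @param start_stagger Trees germinate uniformly within this many years
#'   after the span start, so sample depth builds up gradually.
#' @param seed Master integer seed; every random draw in the generator
#'   derives from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_trees = 5, span = c(1950, 2006), seed = 1)
#' cfg$beta
#' @export
sim_config <- function(n_trees = 15,
                       radii_per_tree = c(2, 3),
                       span = c(1830, 2006),
                       age_trend = c(A = 4, k = 0.02, c = 0.5),
                       beta = 0.3,
                       sigma_ring = 0.35,
                       p_extra = 0.3,
                       p_extra_recent = 0,
                       stabilization_year = 1980,
                       p_missing = 0.02,
                       mark_absent = TRUE,
                       meas_sd_fm = 0.003,
                       coupling = -0.6,
                       phi_index = 0.5,
                       climate_noise = c(precip = 60, temp = 0.3, flow = 150),
                       start_stagger = 80,
                       seed = 1L) {
  cfg <- list(n_trees = as.integer(n_trees),
              radii_per_tree = as.integer(radii_per_tree),
              span = as.integer(span),
              age_trend = unlist(age_trend),
              beta = beta,
              sigma_ring = sigma_ring,
              p_extra = p_extra,
              p_extra_recent = p_extra_recent,
              stabilization_year = as.integer(stabilization_year),
              p_missing = p_missing,
              mark_absent = isTRUE(mark_absent),
              meas_sd_fm = meas_sd_fm,
              coupling = coupling,
              phi_index = phi_index,
              climate_noise = unlist(climate_noise),
              start_stagger = as.integer(start_stagger),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  at <- cfg$age_trend
  if (length(cfg$span) != 2L || diff(cfg$span) + 1L < 40L)
    stop_ringtruth("`span` must cover at least 40 years", "invalid_config")
  if (cfg$n_trees < 1L)
    stop_ringtruth("`n_trees` must be at least 1", "invalid_config")
  if (any(cfg$radii_per_tree < 1L))
    stop_ringtruth("`radii_per_tree` must be positive", "invalid_config")
  if (cfg$p_extra < 0 || cfg$p_extra >= 1 ||
      cfg$p_extra_recent < 0 || cfg$p_extra_recent >= 1)
    stop_ringtruth("extra-ring probabilities must lie in [0, 1)",
                   "invalid_config")
  if (cfg$p_missing < 0 || cfg$p_missing >= 1)
    stop_ringtruth("`p_missing` must lie in [0, 1)", "invalid_config")
  if (!all(c("A", "k", "c") %in% names(at)) ||
      at[["A"]] <= 0 || at[["k"]] <= 0 || at[["c"]] < 0)
    stop_ringtruth("`age_trend` needs A > 0, k > 0, c >= 0",
                   "invalid_config")
  if (cfg$meas_sd_fm <= 0)
    stop_ringtruth("`meas_sd_fm` must be positive", "invalid_config")
  if (cfg$sigma_ring < 0)
    stop_ringtruth("`sigma_ring` must be non-negative", "invalid_config")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic stand configuration\n")
  cat(sprintf("  %d trees, radii per tree in {%s}, years %d-%d\n",
              x$n_trees, paste(x$radii_per_tree, collapse = ","),
              x$span[1], x$span[2]))
  cat(sprintf("  age trend A=%.2f mm, k=%.3f /yr, c=%.2f mm\n",
              x$age_trend[["A"]], x$age_trend[["k"]], x$age_trend[["c"]]))
  cat(sprintf("  beta=%.2f, sigma_ring=%.2f\n", x$beta, x$sigma_ring))
  cat(sprintf("  p_extra=%.2f (%.2f after %d), p_missing=%.3f\n",
              x$p_extra, x$p_extra_recent, x$stabilization_year,
              x$p_missing))
  cat(sprintf("  Fm14C measurement SD = %.4f, seed = %d\n",
              x$meas_sd_fm, x$seed))
  invisible(x)
}

#' Write / read a simulation configuration as JSON
#'
#' Field names in the file mirror the `sim_config()` arguments exactly,
#' so a configuration round-trips unchanged.
#' @param cfg A `sim_config` object.
#' @param path File path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sim_config"))
  x <- unclass(cfg)
  # keep field names of named vectors in the JSON objects
  x$age_trend <- as.list(x$age_trend)
  x$climate_noise <- as.list(x$climate_noise)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(sim_config, raw)
}
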