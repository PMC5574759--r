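# Seasonal cycles of the simulated site: a wet-season floodplain with
# May--November rains, a ~1 degC temperature amplitude, and streamflow
# peaking in November--December.
site_cycles <- function() {
  list(
    precip = c(130, 110, 120, 200, 360, 380, 370, 360, 370, 400, 390, 180),
    temp   = c(26.8, 27.1, 27.4, 27.5, 27.5, 27.4, 27.3, 27.2,
               26.9, 26.7, 26.6, 26.6),
    flow   = c(1500, 1100, 900, 1000, 1800, 2200, 2300, 2400,
               2500, 2700, 2950, 2900)
  )
}

# Per-index-unit climate anomalies: a warm (positive) index year lowers
# precipitation and streamflow and slightly raises temperature.
site_loadings <- function(coupling) {
  list(precip = coupling * 60,
       temp   = -coupling * 0.2,
       flow   = coupling * 300)
}

#' Generate synthetic station climate and an ENSO-like index
#'
#' Produces an AR(1) annual climate index (warm phase positive) and three
#' monthly station series -- precipitation, temperature and streamflow --
#' built as a fixed seasonal cycle plus an index-coupled anomaly plus
#' white monthly noise.  With `coupling = 0` and zero noise every monthly
#' series equals its seasonal cycle exactly.  Output is reproducible for
#' a fixed `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with components `index` (data.frame `year`, `value`)
#'   and `series` (named list of [climate_series()]: `precip`, `temp`,
#'   `flow`).
#' @examples
#' clim <- gen_climate(sim_config(seed = 7))
#' clim$series$flow
#' @export
gen_climate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  years <- seq(cfg$span[1], cfg$span[2])
  n <- length(years)
  if (n < 2L)
    stop_ringtruth("simulation span must cover at least 2 years",
                   "invalid_config")
  cycles <- site_cycles()
  loads <- site_loadings(cfg$coupling)
  noise_sd <- cfg$climate_noise
  if (length(noise_sd) == 1L && is.null(names(noise_sd)))
    noise_sd <- c(precip = noise_sd, temp = noise_sd, flow = noise_sd)

  with_seed(derive_seed(cfg$seed, 1L), {
    phi <- cfg$phi_index
    innov_sd <- sqrt(max(1 - phi^2, 1e-12))
    z <- numeric(n)
    z[1] <- stats::rnorm(1)
    if (n > 1) for (t in 2:n) z[t] <- phi * z[t - 1] + stats::rnorm(1, sd = innov_sd)

    make_var <- function(var, units, station) {
      vals <- matrix(rep(cycles[[var]], each = n), nrow = n) +
        loads[[var]] * z +
        matrix(stats::rnorm(n * 12L, sd = noise_sd[[var]]), nrow = n)
      climate_series(var, units, years, vals, station)
    }
    series <- list(
      precip = make_var("precip", "mm",
                        list(id = "SIM-P", lat = 7.2, lon = -77.0)),
      temp = make_var("temp", "degC",
                      list(id = "SIM-T", lat = 7.8, lon = -77.1)),
      flow = make_var("flow", "m3/s",
                      list(id = "SIM-Q", lat = 5.9, lon = -77.0))
    )
    list(index = data.frame(year = years, value = z), series = series)
  })
}

#' Generate a gridded field sharing a signal with a target series
#'
#' Builds a synthetic lat/lon field in which cells inside a rectangular
#' "teleconnected" region carry a scaled copy of `x` plus noise while the
#' remaining cells are pure noise -- the standard construction for testing
#' field-correlation masking.
#'
#' @param x Numeric annual series providing the shared signal.
#' @param years Years matching `x`.
#' @param nlat,nlon Grid size.
#' @param region Integer vector `c(lat1, lat2, lon1, lon2)` of the
#'   signal-bearing cell block (indices).
#' @param effect Correlation-scale effect size of the shared signal in
#'   the region (0..1).
#' @param seed Integer seed.
#' @return A [gridded_field()].
#' @export
gen_gridded_field <- function(x, years, nlat = 8, nlon = 10,
                              region = c(2, 4, 3, 6), effect = 0.8,
                              seed = 1L) {
  stopifnot(length(x) == length(years), effect >= 0, effect <= 1)
  xs <- as.numeric(scale(x))
  with_seed(seed, {
    cube <- array(stats::rnorm(nlat * nlon * length(x)),
                  dim = c(nlat, nlon, length(x)))
    for (i in region[1]:region[2])
      for (j in region[3]:region[4])
        cube[i, j, ] <- effect * xs +
          sqrt(1 - effect^2) * stats::rnorm(length(x))
    gridded_field(lat = seq(0, by = 1, length.out = nlat),
                  lon = seq(-90, by = 1, length.out = nlon),
                  time = years, values = cube, units = "z-score")
  })
}
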