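# Shared fixtures, generated in code.

# Small stand used by several module tests.
small_sim <- function(seed = 11, ...) {
  cfg <- sim_config(n_trees = 6, span = c(1920, 2006), seed = seed, ...)
  clim <- gen_climate(cfg)
  sim <- gen_ring_series(cfg, clim$series$flow)
  list(cfg = cfg, clim = clim, sim = sim)
}

# Detrend + prewhiten a list of ring series, skipping ones too short.
residual_series <- function(series) {
  out <- list()
  for (s in series) {
    n <- length(s$widths)
    if (n < 12L) next
    out[[length(out) + 1L]] <- prewhiten(detrend(s))
  }
  out
}

# A strictly increasing synthetic dating curve where every fm value maps
# to exactly one calendar year: fm = 1 + 0.005 * (year - 1900).
monotone_curve <- function() {
  yrs <- 1900:2010
  bomb_curve(yrs + 0.5, 1 + 0.005 * (yrs - 1900), rep(1e-4, length(yrs)))
}

# Amplitude of the period-P component of x, measured by least squares on
# sine/cosine regressors (independent of the smoother implementation).
sinusoid_amplitude <- function(x, period) {
  t <- seq_along(x)
  s <- sin(2 * pi * t / period)
  co <- cos(2 * pi * t / period)
  fit <- stats::lm(x ~ s + co)
  sqrt(sum(stats::coef(fit)[c("s", "co")]^2))
}
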