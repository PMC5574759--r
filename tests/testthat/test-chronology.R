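test_that("spline growth curve interpolates a constant exactly", {
  rs <- ring_series("C", 1900, rep(5, 80))
  expect_equal(fit_spline_growth(rs), rep(5, 80), tolerance = 1e-9)
  expect_error(fit_spline_growth(ring_series("C", 1900, rep(5, 9))),
               "shorter than 10")
  expect_error(fit_spline_growth(1:20 * 0), "positive widths")
})

test_that("spline amplitude transfer is 0.5 +/- 0.05 at the design wavelength", {
  n <- 300
  for (phase in c(0, 1.3)) {
    w <- 5 + sin(2 * pi * (1:n) / 60 + phase)
    crv <- fit_spline_growth(w, wavelength = 60, response = 0.5)
    amp <- sinusoid_amplitude(crv - mean(crv), 60)
    expect_gt(amp, 0.45)
    expect_lt(amp, 0.55)
  }
  # high-frequency variance passes through to the index
  w10 <- 5 + sin(2 * pi * (1:n) / 10)
  amp10 <- sinusoid_amplitude(fit_spline_growth(w10) - 5, 10)
  expect_lt(amp10, 0.1)
})

test_that("spline transfer is monotone increasing in period", {
  n <- 600
  amps <- sapply(c(20, 60, 200), function(per) {
    w <- 5 + sin(2 * pi * (1:n) / per)
    sinusoid_amplitude(fit_spline_growth(w) - mean(w), per)
  })
  expect_true(all(diff(amps) > 0))
  expect_gt(amps[2], 0.45)
  expect_lt(amps[2], 0.55)
})

test_that("ratio detrending follows its definition", {
  rs <- ring_series("D", 1900, rep(2.5, 40))
  d <- detrend(rs, curve = rep(2.5, 40))
  expect_equal(d$index, rep(1, 40))
  crv <- rep(2.5, 40); w <- rep(2.5, 40); w[10] <- 5
  d2 <- detrend(ring_series("D", 1900, w), curve = crv)
  expect_equal(d2$index[10], 2)
  # floor applied with a warning for near-zero curve values
  expect_warning(detrend(ring_series("D", 1900, rep(1, 40)),
                         curve = c(rep(1, 39), 1e-6)), "floored")
})

test_that("detrending lognormal noise centers the index at one", {
  # the spline tracks the conditional mean width, so the ratio index is
  # centered at 1 in the arithmetic mean (the geometric mean sits at
  # exp(-sigma^2/2), a property of the lognormal, not a bias)
  set.seed(77)
  sigma <- 0.3
  for (rep in 1:5) {
    n <- 1000
    w <- exp(rnorm(n, sd = sigma)) * 2
    d <- detrend(ring_series("L", 1000, w))
    se <- sqrt(exp(sigma^2) * (exp(sigma^2) - 1)) / sqrt(n)
    expect_lt(abs(mean(d$index) - 1), 2 * se + 0.01)
    expect_lt(abs(mean(log(d$index)) + sigma^2 / 2), 3 * sigma / sqrt(n) + 0.01)
  }
})

test_that("prewhitening removes AR structure and guards short input", {
  set.seed(5)
  ok <- 0
  for (i in 1:20) {
    x <- as.numeric(arima.sim(list(ar = 0.7), 300)) / 5 + 1
    d <- structure(list(series_id = "A", years = 1:300, index = x,
                        curve = rep(1, 300), ar_order = NA_integer_,
                        ar_coefs = numeric(0)),
                   class = "detrended_series")
    pw <- prewhiten(d, max_order = 5)
    r1 <- cor(pw$index[-1], pw$index[-length(pw$index)])
    if (pw$ar_order >= 1 && abs(r1) < 0.1) ok <- ok + 1
    # mean preserved by re-centering
    expect_equal(mean(pw$index), mean(d$index), tolerance = 1e-8)
  }
  expect_gte(ok, 18)

  short <- structure(list(series_id = "A", years = 1:10, index = rnorm(10),
                          curve = rep(1, 10), ar_order = NA_integer_,
                          ar_coefs = numeric(0)),
                     class = "detrended_series")
  expect_error(prewhiten(short, max_order = 5), "too short")
})

test_that("white noise mostly selects low AR orders and stays white", {
  set.seed(6)
  orders <- replicate(60, {
    d <- structure(list(series_id = "A", years = 1:200,
                        index = rnorm(200) / 10 + 1,
                        curve = rep(1, 200), ar_order = NA_integer_,
                        ar_coefs = numeric(0)),
                   class = "detrended_series")
    pw <- prewhiten(d, max_order = 10)
    expect_lt(abs(cor(pw$index[-1], pw$index[-length(pw$index)])), 0.2)
    pw$ar_order
  })
  # AIC occasionally overfits white noise, but order 0 dominates
  expect_gt(mean(orders == 0), 0.5)
  expect_gt(mean(orders <= 1), 0.75)
})

test_that("biweight mean matches a direct iteration oracle and bounds", {
  # independent oracle: literal fixed-point iteration of the bisquare
  # weight formula
  oracle <- function(x, c = 9) {
    m <- median(x); s <- median(abs(x - m))
    if (s == 0) return(median(x))
    for (i in 1:200) {
      u <- (x - m) / (c * s)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      m2 <- sum(w * x) / sum(w)
      if (abs(m2 - m) < 1e-10) break
      m <- m2
    }
    m
  }
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(sample(3:30, 1), mean = 1, sd = 0.4)
    expect_equal(biweight_mean(x), oracle(x), tolerance = 1e-6)
    expect_gte(biweight_mean(x), min(x))
    expect_lte(biweight_mean(x), max(x))
  }
  expect_equal(biweight_mean(rep(3.2, 7)), 3.2)
  out <- biweight_mean(c(1, 1, 1, 1, 100))
  expect_lt(out, mean(c(1, 1, 1, 1, 100)))
  expect_gte(out, 0.9); expect_lte(out, 1.2)
})

test_that("chronology of identical series equals the input and guards depth", {
  mk <- function(id) structure(
    list(series_id = id, years = 1950:1999,
         index = sin(1:50 / 3) / 5 + 1, curve = rep(1, 50),
         ar_order = 0L, ar_coefs = numeric(0)),
    class = "detrended_series")
  ch <- build_chronology(list(mk("T01A"), mk("T02A"), mk("T03A")))
  expect_equal(ch$index, sin(1:50 / 3) / 5 + 1, tolerance = 1e-9)
  expect_equal(ch$depth, rep(3, 50))
  expect_equal(ch$rbar, 1, tolerance = 1e-12)

  one_year <- function(id, yr) structure(
    list(series_id = id, years = yr, index = 1, curve = 1,
         ar_order = 0L, ar_coefs = numeric(0)),
    class = "detrended_series")
  expect_error(build_chronology(list(one_year("A", 1990),
                                     one_year("B", 1995)),
                                min_depth = 2),
               "empty chronology|sample depth")
})

test_that("rbar handles sign cases and independent noise", {
  t <- 1:100
  s1 <- structure(list(series_id = "T01A", years = t,
                       index = sin(t / 4) + 2, curve = rep(1, 100),
                       ar_order = 0L, ar_coefs = numeric(0)),
                  class = "detrended_series")
  s2 <- s1; s2$series_id <- "T02A"; s2$index <- -sin(t / 4) + 2
  expect_equal(mean_interseries_correlation(list(s1, s2))$rbar, -1,
               tolerance = 1e-10)

  set.seed(12)
  wn <- lapply(1:8, function(i) structure(
    list(series_id = sprintf("T%02dA", i), years = 1:200,
         index = rnorm(200) / 10 + 1, curve = rep(1, 200),
         ar_order = 0L, ar_coefs = numeric(0)),
    class = "detrended_series"))
  rb <- mean_interseries_correlation(wn)
  # 28 pairs of independent series: rbar near zero
  expect_lt(abs(rb$rbar), 2 / sqrt(200))
  expect_error(mean_interseries_correlation(list(s1)), "two series")
})

test_that("EPS closed form and monotonicity", {
  expect_equal(eps(1, 5), 1)
  expect_equal(eps(0, 10), 0)
  # direct arithmetic: 15 * .49 / (15 * .49 + .51)
  expect_equal(eps(0.49, 15), 7.35 / 7.86, tolerance = 1e-12)
  expect_gt(eps(0.49, 15), 0.85)
  expect_error(eps(1.2, 5), "rbar")
  expect_warning(e0 <- eps(-0.1, 5), "negative")
  expect_equal(e0, 0)
  # monotone non-decreasing in rbar and n
  rb <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(sapply(rb, eps, n = 10)) >= 0))
  expect_true(all(diff(sapply(2:30, function(n) eps(0.3, n))) >= 0))
})

test_that("running EPS finds a constructed signal onset", {
  set.seed(21)
  yrs <- 1900:2000
  common <- rnorm(length(yrs))
  common[yrs < 1950] <- 0          # shared signal only from 1950
  series <- lapply(1:8, function(i) structure(
    list(series_id = sprintf("T%02dA", i), years = yrs,
         index = common + rnorm(length(yrs), sd = 0.45) + 1,
         curve = rep(1, length(yrs)), ar_order = 0L,
         ar_coefs = numeric(0)),
    class = "detrended_series"))
  out <- running_eps(series, window = 50, step = 25, threshold = 0.85)
  expect_false(is.na(out$onset))
  expect_lte(abs(out$onset - 1950), 25)

  # identical series: every window EPS = 1; impossible threshold: none
  ident <- lapply(series, function(s) { s$index <- common + 1; s })
  out2 <- running_eps(ident, threshold = 0.85)
  expect_true(all(abs(out2$windows$eps - 1) < 1e-9, na.rm = TRUE))
  expect_true(is.na(running_eps(ident, threshold = 1.01)$onset))
  expect_error(running_eps(series, window = 20), "at least 30")
})

test_that("lag-1 autocorrelation closed forms and AR recovery", {
  expect_equal(lag1_autocorrelation(rep(c(1, -1), 20)), -1)
  expect_error(lag1_autocorrelation(rep(2, 30)), "constant")
  expect_error(lag1_autocorrelation(rnorm(10)), "20 years")
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = -0.2), 2000))
  est <- lag1_autocorrelation(x)
  expect_gt(est, -0.25); expect_lt(est, -0.15)
})
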