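test_that("screening admits clean series and rejects trend / step change", {
  set.seed(50)
  expect_error(screen_series(rnorm(15)), "at least 20")

  # clean i.i.d. normal series pass at close to the nominal joint rate
  passes <- replicate(200, screen_series(rnorm(100))$pass)
  p_nominal <- 0.95^3
  se <- sqrt(p_nominal * (1 - p_nominal) / 200)
  expect_lt(abs(mean(passes) - p_nominal), 3 * se + 0.03)

  # a 3-sigma linear drift trips the trend test
  trend_fail <- replicate(100, {
    x <- rnorm(100) + seq(0, 3, length.out = 100)
    !screen_series(x)$tests$pass[2]
  })
  expect_gte(mean(trend_fail), 0.95)

  # a 2-sigma step at the midpoint trips the homogeneity test
  step_fail <- replicate(100, {
    x <- rnorm(100) + rep(c(0, 2), each = 50)
    !screen_series(x)$tests$pass[3]
  })
  expect_gte(mean(step_fail), 0.90)
})

test_that("seasonalize aggregates months per definition", {
  cfg <- sim_config(n_trees = 2, span = c(1960, 2006), seed = 1)
  clim <- gen_climate(cfg)$series$precip
  ann <- seasonalize(clim, 1:12, "total")
  expect_equal(ann$value, unname(rowSums(clim$values)))

  const <- climate_series("temp", "degC", 1990:1999,
                          matrix(27, 10, 12))
  expect_equal(seasonalize(const, 10:12, "mean")$value, rep(27, 10))

  vals <- matrix(1, 3, 12); vals[2, 11] <- NA
  cs <- climate_series("x", "", 1997:1999, vals)
  ond <- seasonalize(cs, 10:12, "mean")
  expect_true(is.na(ond$value[ond$year == 1998]))
  expect_false(anyNA(ond$value[ond$year != 1998]))
  expect_error(seasonalize(cs, integer(0)), "non-empty")
})

test_that("bootstrap correlation: identity, construction and refusal", {
  ch <- structure(list(years = 1950:2006,
                       index = sin(1:57 / 5) / 4 + rnorm(57, sd = 0.1) + 1),
                  class = c("chronology"))
  self <- data.frame(year = ch$years, value = ch$index)
  r1 <- correlate_bootstrap(ch, self, seed = 3)
  expect_equal(r1$r, 1)
  expect_true(r1$significant)

  set.seed(51)
  neg <- data.frame(year = ch$years,
                    value = -ch$index + rnorm(57, sd = 0.05))
  r2 <- correlate_bootstrap(ch, neg, seed = 3)
  expect_lt(r2$r, -0.9)
  expect_true(r2$significant)
  expect_lt(r2$ci_high, 0)
  expect_true(r2$ci_low <= r2$r && r2$r <= r2$ci_high + 1e-12 ||
                r2$r >= r2$ci_low)

  expect_error(correlate_bootstrap(ch, self, period = c(2000, 2006)),
               "overlapping years")
})

test_that("bootstrap is seed-deterministic and affine-invariant", {
  set.seed(52)
  ch <- structure(list(years = 1950:2006, index = rnorm(57) + 1),
                  class = "chronology")
  y <- data.frame(year = 1950:2006, value = rnorm(57))
  a <- correlate_bootstrap(ch, y, seed = 7)
  b <- correlate_bootstrap(ch, y, seed = 7)
  expect_identical(a, b)
  # Pearson correlation is invariant to affine rescaling of either side
  y2 <- transform(y, value = -3 * value + 100)
  c2 <- correlate_bootstrap(ch, y2, seed = 7)
  expect_equal(abs(c2$r), abs(a$r), tolerance = 1e-12)
  expect_equal(c2$ci_low, -a$ci_high, tolerance = 1e-12)
})

test_that("bootstrap confidence intervals shrink with overlap length", {
  set.seed(53)
  widths <- sapply(c(30, 100), function(n) {
    median(replicate(25, {
      ch <- structure(list(years = seq_len(n), index = rnorm(n) + 1),
                      class = "chronology")
      y <- data.frame(year = seq_len(n), value = rnorm(n))
      r <- correlate_bootstrap(ch, y, n_boot = 400, seed = sample.int(1e6, 1))
      r$ci_high - r$ci_low
    }))
  })
  expect_lt(widths[2], widths[1])
})

test_that("monthly response finds the driving season and refuses short months", {
  # decouple the shared index so only the OND months' own anomalies
  # drive growth: the month discrimination is then unambiguous
  cfg <- sim_config(n_trees = 2, span = c(1950, 2006), coupling = 0,
                    seed = 10)
  clim <- gen_climate(cfg)$series$flow
  ond <- seasonalize(clim, 10:12, "mean")
  set.seed(55)
  chron <- structure(list(years = ond$year,
                          index = as.numeric(scale(ond$value)) +
                            rnorm(nrow(ond), sd = 0.4)),
                     class = "chronology")
  resp <- monthly_response(chron, clim, n_boot = 400, seed = 2)
  expect_equal(nrow(resp), 12)
  top <- resp$month[order(-abs(resp$r))][1:3]
  expect_true(all(top %in% 10:12))

  # truncate the chronology so no month reaches 15 overlapping years
  short <- structure(list(years = 1995:2006, index = rnorm(12) + 1),
                     class = "chronology")
  resp2 <- monthly_response(short, clim, n_boot = 100, seed = 2)
  expect_true(all(resp2$refused))
})

test_that("field correlation concentrates significance in the signal region", {
  set.seed(54)
  yrs <- 1951:2000
  x <- data.frame(year = yrs, value = rnorm(50))
  g <- gen_gridded_field(x$value, yrs, nlat = 8, nlon = 10,
                         region = c(2, 4, 3, 6), effect = 0.8, seed = 5)
  fc <- field_correlate(x, g, n_boot = 400, seed = 6)
  in_region <- fc$mask[2:4, 3:6]
  out_region <- fc$mask[-(2:4), -(3:6)]
  expect_gte(mean(in_region), 0.8)
  expect_lte(mean(out_region), 0.2)

  # single-cell grid equal to the series: perfect correlation
  g1 <- gridded_field(1, 1, yrs, array(x$value, c(1, 1, 50)))
  fc1 <- field_correlate(x, g1, n_boot = 200, seed = 1)
  expect_equal(fc1$r[1, 1], 1)
  expect_true(fc1$mask[1, 1])

  # constant cell flagged undefined, not fatal
  g2 <- gridded_field(1:2, 1, yrs,
                      array(c(rep(1, 50), rnorm(50)), c(2, 1, 50))[c(1, 2), , ,
                                                                   drop = FALSE])
  vals <- array(NA_real_, c(2, 1, 50))
  vals[1, 1, ] <- 1
  vals[2, 1, ] <- rnorm(50)
  g2 <- gridded_field(1:2, 1, yrs, vals)
  fc2 <- field_correlate(x, g2, n_boot = 100, seed = 2)
  expect_true(is.na(fc2$r[1, 1]))
  expect_false(fc2$mask[1, 1])
})
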