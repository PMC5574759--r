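test_that("candidate years collapse to runs with correct limb structure", {
  crv <- gen_bomb_curve()
  peak_fm <- max(crv$fm)

  at_peak <- candidate_years(peak_fm, 1e-4, crv, k_sigma = 2)
  expect_equal(nrow(at_peak), 1)
  expect_false(at_peak$open_start)
  expect_true(at_peak$start <= 1964 && at_peak$end >= 1964)

  mid <- candidate_years(1.40, 0.003, crv, k_sigma = 2)
  closed <- mid[!mid$open_start, ]
  expect_equal(nrow(closed), 2)   # ascending and descending limb
  expect_true(closed$end[1] < 1964.5 && closed$start[2] > 1964.5)
  expect_true(all(closed$center == (closed$start + closed$end) / 2))

  plateau <- candidate_years(0.975, 0.003, crv, k_sigma = 2)
  expect_equal(nrow(plateau), 1)
  expect_true(plateau$open_start)

  none <- candidate_years(2.5, 0.003, crv, k_sigma = 2)
  expect_equal(nrow(none), 0)
})

test_that("error-free synthetic trees date coincident with zero offsets", {
  cfg <- sim_config(n_trees = 3, span = c(1940, 2006), p_extra = 0,
                    p_missing = 0, start_stagger = 0,
                    meas_sd_fm = 0.0005, seed = 13)
  clim <- gen_climate(cfg)
  sim <- gen_ring_series(cfg, clim$series$flow)
  crv <- gen_bomb_curve()
  meas <- gen_14c_measurements(sim$truth, crv, cfg, trees = 1,
                               n_samples = 5, spacing = 10)
  a <- assign_tree_dates(meas, crv)
  dated <- a[!a$plateau, ]
  expect_true(all(dated$offset == 0))
  expect_true(all(dated$coincident))
})

test_that("inserted extra rings appear as decreasing offsets toward the bark", {
  # 70-ring tree, years 1940..2004, with the years 1966..1970 doubled
  # (5 extra rings).  Bark-anchored counting dates every ring pith-side
  # of the extras 5 years too old; rings bark-side of them are correct.
  yrs <- 1940:2004
  true_years <- sort(c(yrs, 1966:1970))
  m <- length(true_years)
  dendro <- 2004 - (m - seq_len(m))
  crv <- gen_bomb_curve()
  pos <- c(match(1960, true_years),          # below the extras
           match(1980, true_years), match(1990, true_years),
           match(2000, true_years))
  samples <- data.frame(position = pos,
                        dendro_year = dendro[pos],
                        fm = approx(crv$year, crv$fm,
                                    xout = true_years[pos] + 0.5)$y,
                        fm_sd = 0.002)
  a <- assign_tree_dates(samples, crv)
  expect_equal(a$assigned_year, true_years[a$position])
  expect_equal(a$offset, c(5, 0, 0, 0))
  # offsets are non-increasing pith -> bark when only extras occur
  expect_true(all(diff(a$offset) <= 0))
})

test_that("assignment is permutation-safe and rejects impossible orders", {
  crv <- monotone_curve()
  samples <- data.frame(position = c(10, 30, 50),
                        dendro_year = c(1950, 1970, 1990),
                        fm = 1 + 0.005 * (c(1951, 1972, 1991) - 1900),
                        fm_sd = 1e-4)
  a <- assign_tree_dates(samples, crv)
  expect_equal(a$assigned_year, c(1951, 1972, 1991))
  shuffled <- samples[c(3, 1, 2), ]
  expect_identical(assign_tree_dates(shuffled, crv), a)

  bad <- data.frame(position = c(10, 30),
                    dendro_year = c(1950, 1970),
                    fm = 1 + 0.005 * (c(1990, 1960) - 1900),
                    fm_sd = 1e-4)
  expect_error(assign_tree_dates(bad, crv), "strictly increasing")
})

test_that("excess per decade follows the hand-arithmetic oracle", {
  # pairs engineered for per-decade excesses 4 and 6
  a <- data.frame(position = c(1, 15, 31),
                  dendro_year = c(1960, 1974, 1990),
                  fm = 1, assigned_year = c(1960, 1970, 1980),
                  offset = c(0, 4, 10), coincident = FALSE,
                  ambiguous = FALSE, plateau = FALSE,
                  no_candidate = FALSE)
  ex <- excess_per_decade(a)
  expect_equal(ex$rates, c(4, 6))
  expect_equal(ex$mean, 5)
  expect_equal(ex$sd, 1)   # population SD
  expect_equal(ex$sd_convention, "population")

  expect_error(excess_per_decade(a[1, ]), "two dated samples")
  zero <- a; zero$assigned_year <- zero$dendro_year
  zero$position <- c(1, 15, 31); zero$assigned_year <- c(1960, 1974, 1990)
  ex0 <- excess_per_decade(zero)
  expect_equal(ex0$mean, 0); expect_equal(ex0$sd, 0)
})

test_that("cumulative mismatch sums absolute interval mismatches", {
  expect_equal(cumulative_mismatch(c(4, -3))$total, 7)
  expect_equal(cumulative_mismatch(c(0, 0, 0))$total, 0)
  expect_equal(cumulative_mismatch(c(2, -2, 2))$total, 6)
  expect_equal(cumulative_mismatch(c(2, -2, 2))$running, c(2, 4, 6))
})

test_that("dating recovery works across seeded trees with extras", {
  crv <- gen_bomb_curve()
  recovered <- 0; total <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n_trees = 1, span = c(1940, 2006), p_extra = 0.3,
                      p_missing = 0, stabilization_year = 1980,
                      start_stagger = 0, meas_sd_fm = 0.003, seed = seed)
    clim <- gen_climate(cfg)
    sim <- gen_ring_series(cfg, clim$series$flow)
    meas <- gen_14c_measurements(sim$truth, crv, cfg, trees = 1,
                                 n_samples = 5, spacing = 10)
    a <- assign_tree_dates(meas, crv, k_sigma = 2)
    dated <- !a$plateau & !a$no_candidate & !is.na(a$assigned_year)
    truth <- meas$true_year[match(a$position[dated], meas$position)]
    recovered <- recovered + sum(a$assigned_year[dated] == truth)
    total <- total + sum(dated)
  }
  expect_gt(total, 30)
  expect_gte(recovered / total, 0.95)
})
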