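#' Generate ring-width series with known dating errors
#'
#' Simulates every tree in the stand over the configured span.  The wood
#' laid down by a tree in calendar year t has expected width
#' `(A * exp(-k * age) + c) * exp(beta * z_t)` where `z_t` is the
#' standardized October--December streamflow of that year, multiplied by
#' lognormal noise per radius.  In a stand-wide intra-annual stress year
#' (probability `p_extra` before `stabilization_year`, `p_extra_recent`
#' after) each tree splits the year's increment into two rings at a
#' uniform random proportion in \[0.3, 0.7\], so total wood per year is
#' conserved; the proportion is a property of the stress year, shared by
#' all trees, because the within-year climate pattern sets where the
#' band forms.  The second ring is flagged "extra" and shares the true
#' calendar year of its predecessor.  Each observed ring is additionally
#' dropped from a given radius with probability `p_missing` (a locally
#' absent, "wedging" ring).
#'
#' Ring counting assigns calendar years the way a field worker would:
#' the bark-side ring carries the harvest year and counting proceeds
#' inward, so extra rings push older rings to earlier (too-old) dendro
#' dates and missing rings do the opposite on the affected radius.
#' With `p_extra = p_missing = 0` every dendro year equals the true year.
#'
#' @param cfg A [sim_config()].
#' @param flow A [climate_series()] of monthly streamflow covering the
#'   configured span (typically `gen_climate(cfg)$series$flow`).
#' @return A list with `series` (list of [ring_series()], one per radius)
#'   and `truth` (a `truth_table`: `$rings` with per-tree columns
#'   tree, position, true_year, flag, dendro_year; `$absent` with
#'   tree, series_id, position of locally absent rings; `$trees` with
#'   tree, start_year, n_radii).
#' @examples
#' cfg <- sim_config(n_trees = 4, span = c(1920, 2006), seed = 3)
#' sim <- gen_ring_series(cfg, gen_climate(cfg)$series$flow)
#' length(sim$series)
#' @export
gen_ring_series <- function(cfg, flow) {
  stopifnot(inherits(cfg, "sim_config"), inherits(flow, "climate_series"))
  years <- seq(cfg$span[1], cfg$span[2])
  if (!all(years %in% flow$years))
    stop_ringtruth("climate series does not cover the simulation span",
                   "invalid_config")
  harvest <- cfg$span[2]
  ond <- seasonalize(flow, months = 10:12, stat = "mean")
  ond <- ond[match(years, ond$year), "value"]
  if (anyNA(ond))
    stop_ringtruth("streamflow has missing OND values inside the span",
                   "invalid_config")
  z <- if (stats::sd(ond) > 0) as.numeric(scale(ond)) else rep(0, length(ond))

  at <- cfg$age_trend

  # Stand-wide intra-annual stress years, shared by every tree so that
  # the stand remains internally crossdatable while drifting from the
  # true calendar.
  p_year <- ifelse(years < cfg$stabilization_year,
                   cfg$p_extra, cfg$p_extra_recent)
  ev <- with_seed(derive_seed(cfg$seed, 2L), {
    hit <- stats::runif(length(years)) < p_year
    # split proportion is a property of the stress year (the within-year
    # climate pattern), shared by every tree
    list(extra = hit, prop = stats::runif(length(years), 0.3, 0.7))
  })
  extra_year <- ev$extra
  prop_year <- ev$prop

  all_series <- list()
  rings_list <- list()
  absent_list <- list()
  tree_rows <- list()

  for (tree in seq_len(cfg$n_trees)) {
    tseed <- derive_seed(cfg$seed, 100L + tree)
    res <- with_seed(tseed, {
      start <- cfg$span[1] +
        if (cfg$start_stagger > 0)
          sample.int(min(cfg$start_stagger,
                         diff(cfg$span) - 39L) + 1L, 1L) - 1L
        else 0L
      n_radii <- if (length(cfg$radii_per_tree) == 1L) cfg$radii_per_tree
                 else sample(cfg$radii_per_tree, 1L)
      tyears <- seq(start, harvest)
      idx <- match(tyears, years)
      age <- tyears - start
      trend <- at[["A"]] * exp(-at[["k"]] * age) + at[["c"]]
      mu <- trend * exp(cfg$beta * z[idx])

      # tree-level ring sequence: split years carry two rings
      split <- extra_year[idx]
      prop <- prop_year[idx]
      true_year <- rep(tyears, times = 1L + split)
      flag <- unlist(lapply(seq_along(tyears), function(i)
        if (split[i]) c("annual", "extra") else "annual"))
      share <- unlist(lapply(seq_along(tyears), function(i)
        if (split[i]) c(prop[i], 1 - prop[i]) else 1))
      year_of_ring <- rep(seq_along(tyears), times = 1L + split)
      m <- length(true_year)
      dendro_year <- harvest - (m - seq_len(m))

      radii <- vector("list", n_radii)
      absent <- vector("list", n_radii)
      for (r in seq_len(n_radii)) {
        noise <- exp(stats::rnorm(length(tyears), sd = cfg$sigma_ring))
        w_year <- mu * noise
        w_ring <- w_year[year_of_ring] * share
        gone <- stats::runif(m) < cfg$p_missing
        # never drop every ring of a radius
        if (all(gone)) gone[m] <- FALSE
        sid <- sprintf("T%02d%s", tree, LETTERS[r])
        if (cfg$mark_absent) {
          # wedging ring caught on the cross section: keep a 0-width
          # placeholder so alignment is preserved
          w_out <- w_ring
          w_out[gone] <- 0
          radii[[r]] <- ring_series(sid, harvest - (m - 1L), w_out)
        } else {
          kept <- w_ring[!gone]
          radii[[r]] <- ring_series(sid, harvest - (length(kept) - 1L),
                                    kept)
        }
        absent[[r]] <- if (any(gone))
          data.frame(tree = tree, series_id = sid,
                     position = which(gone)) else NULL
      }
      list(start = start, n_radii = n_radii, radii = radii,
           absent = do.call(rbind, absent),
           rings = data.frame(tree = tree, position = seq_len(m),
                              true_year = true_year, flag = flag,
                              dendro_year = dendro_year))
    })
    all_series <- c(all_series, res$radii)
    rings_list[[tree]] <- res$rings
    absent_list[[tree]] <- res$absent
    tree_rows[[tree]] <- data.frame(tree = tree, start_year = res$start,
                                    n_radii = res$n_radii)
  }

  truth <- structure(list(rings = do.call(rbind, rings_list),
                          absent = do.call(rbind, absent_list),
                          trees = do.call(rbind, tree_rows),
                          harvest_year = harvest),
                     class = "truth_table")
  list(series = all_series, truth = truth)
}

#' @export
print.truth_table <- function(x, ...) {
  n_extra <- sum(x$rings$flag == "extra")
  cat(sprintf("<truth_table> %d trees, %d rings (%d extra), %d locally absent\n",
              nrow(x$trees), nrow(x$rings), n_extra,
              if (is.null(x$absent)) 0L else nrow(x$absent)))
  invisible(x)
}
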