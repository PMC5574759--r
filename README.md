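# ringtruth

Tools for building tropical tree-ring chronologies and for asking the
question classical dendrochronology cannot answer on its own: **are the
rings actually annual?**

Many tropical trees — floodplain species especially — form intra-annual
growth bands that are anatomically indistinguishable from annual ring
boundaries, plus rings that are locally absent around part of the stem.
Because those errors are driven by stand-wide climate stress, the trees
still crossdate against each other, the chronology still clears the
conventional quality statistics, and it can still correlate
significantly with climate records — while its calendar dates drift by
years to decades.  `ringtruth` implements the full analysis chain for
detecting this failure mode, with an independent arbiter: the
atmospheric radiocarbon bomb pulse.

## What's in the package

* **Chronology construction** — smoothing-spline detrending with a
  prescribed frequency response (50% at 60 years, solved analytically
  from the transfer function `H(P) = 1/(1 + 16λ sin⁴(π/P))`), AIC-selected
  AR prewhitening, Tukey biweight robust mean, mean inter-series
  correlation r̄, the expressed population signal
  `EPS = n·r̄ / (n·r̄ + (1 − r̄))` with running-window reliability onset,
  and running-segment crossdating against leave-one-out masters with a
  ±10-year lag search.
* **Climate response** — series screening (Shapiro–Wilk, Mann–Kendall,
  Pettitt), monthly/seasonal/annual Pearson correlations with
  percentile-bootstrap confidence intervals, and gridded-field
  correlation maps masked at p < .10.
* **Stochastic response function** — the structural time-series model
  `I_t = μ_t + α_t·X_t + ε_t` with an integrated-random-walk trend and a
  random-walk response weight, estimated by Kalman filtering with
  maximum-likelihood noise variances (Rcpp core), smoothed 95% bands,
  explained variance, and a signal-stability onset.
* **Bomb-pulse validation** — candidate calendar years per Fm¹⁴C
  measurement against an atmospheric curve, a sequence-constrained
  assignment (strictly increasing years, elapsed years bounded by ring
  counts) that resolves the curve's two-limb ambiguity, per-tree offset
  statistics (excess rings per decade, cumulative mismatch).
* **Synthetic stand generator** — floodplain trees with a shared
  October–December streamflow growth signal, stand-wide intra-annual
  ring events, per-radius wedging rings, and bomb-pulse ¹⁴C signatures
  with ground truth, so the whole chain is testable offline.
* **I/O** — Tucson RWL (decadal) read/write, CSV schemas for climate,
  index, chronology, ¹⁴C and curve data.

## Worked example

Run the whole pipeline on a simulated stand (15 trees, 1830–2006,
intra-annual ring probability 0.3 before 1980):

```r
library(ringtruth)
cfg <- pipeline_config(out_dir = "run1", seed = 1)
run <- run_pipeline(cfg)
print(run)
```

```
ringtruth pipeline report
=========================
chronology: 1789-2006, rbar=0.542, EPS=0.947 (onset 1814), lag1=0.138
crossdating: 10.0% of segments flagged, 0 series persistently misdated -> pass
climate: OND streamflow r=0.442 [0.086, 0.810] (significant)
stm: var explained 44.0% (smoothed), stability onset none
radiocarbon offsets per tree:
 tree n_dated mean_abs_offset max_abs_offset excess_mean excess_sd
  T01       5             2.2              6    1.974206  1.601714
  T02       5             2.2              6    1.974206  1.601714
  T03       5             2.2              6    1.974206  1.601714
verdict: dendro-valid but 14C-refuted
```

Reading the report: the chronology crossdates cleanly (no series shows a
persistent lag), its expressed population signal (0.947) is well above
the 0.85 reliability threshold, and it carries a significant positive
correlation with October–December streamflow — everything a classical
workflow would accept as proof of annual rings.  Yet the bomb-pulse
stage finds that ring-counted dates run up to 6 years too old
(`max_abs_offset`), with roughly 2 excess rings per decade of assigned
time: the trees formed more than one ring in some years, and the
package's verdict line says so.  The chronology dates extend before
1830 for the same reason — extra rings inflate inward ring counts.

Individual stages are plain functions if you want them separately:
`detrend()`, `prewhiten()`, `build_chronology()`, `running_eps()`,
`crossdate_check()`, `correlate_bootstrap()`, `field_correlate()`,
`fit_stm()` (a classed fit with `print`/`summary`/`coef`/`plot`/
`simulate` methods), `candidate_years()`, `assign_tree_dates()`.  The
methods vignette (`vignettes/validating-tropical-chronologies.Rmd`)
documents the models, defaults and numerical choices.

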