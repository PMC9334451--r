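---
title: "Methods: phosphene vision simulation, reading-acuity psychometrics, and session-type learning-rate decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphene vision simulation and learning-rate decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosvpl)
```

This vignette is the package's own account of the models it implements:
what is assumed, which knobs matter, what the synthetic-data generator
does and does not emulate, and where genuinely open design choices were
settled.

## 1. The phosphene field

A visual prosthesis is simulated as a set of `n` phosphenes — discrete
light spots — covering the visual field, denser and smaller toward the
point of regard. The exact layout algorithms used in published simulators
are typically bespoke, so `generate_field()` uses an explicit,
two-parameter construction:

* local density is proportional to a cortical-magnification-style profile
  `M(e) = 1/(e + e2)`, where `e` is eccentricity in degrees and `e2`
  (default 2°) sets how quickly density falls off;
* eccentricities are drawn by seeded rejection sampling against that
  profile (radial pdf ∝ `e/(e + e2)`), angles uniformly;
* each phosphene's Gaussian radius `sigma_deg` is a fixed fraction
  (`sigma_frac`, default 0.4) of the *expected* local nearest-neighbour
  spacing `0.5/sqrt(density)` (the Poisson-process mean). Using the
  expected rather than the realized spacing makes sigma deterministic and
  exactly non-decreasing in eccentricity, which in turn makes the
  size-vs-eccentricity invariant assertable without a jitter tolerance.

The default field has 1000 phosphenes over an 80° span. Degrees-to-pixels
conversion is never inferred from viewing geometry: `screen_geometry()`
carries an explicit `deg_per_px` (default 0.025, i.e. a 1600-px-wide
panel subtending 40°). Pixel origin is top-left with y downward, and
field coordinates use the same axis directions centred on the point of
regard, so a single translation maps between the two.

```{r field, eval = FALSE}
field <- generate_field(n = 1000, field_span = 80, seed = 1)
autoplot(field)
phosphenes_on_screen(field, gaze_px = c(800, 450), screen_geometry())
```

With these defaults roughly a third of the field lands on the monitor for
a central gaze; the count drops as gaze approaches an edge. On-monitor
counts depend strongly on `e2`, `field_span` and `deg_per_px`, so they
should be read as order-of-magnitude descriptions of a layout, not as
reproducible constants.

## 2. Veridical encoding and the renderer

Each phosphene is used twice per frame: as a *filter* measuring the mean
image luminance under its gaze-translated footprint, and as a *display*
element drawn as a unit-peak 2D Gaussian scaled by that luminance.
Summing the Gaussians and clipping to `[0, 1]` gives the rendered frame.
Three choices here were genuinely open and are fixed as follows:

* **Sampling footprint.** The averaging region for the filter half is not
  uniquely determined by the verbal definition. Default: a
  Gaussian-weighted mean with the *same* sigma as the display Gaussian,
  truncated at 3σ — a self-consistent filter/display pair. A uniform disc
  of radius 2σ is available via `footprint = "disc"`.
* **Composition of overlapping phosphenes.** Additive, then clipped.
  Max-compositing is the main alternative; additive was chosen because it
  keeps the renderer linear in the image below clipping, a property the
  test suite exploits.
* **Gaze between samples.** Hold-last-value, no interpolation:
  `render_sequence()` uses the most recent valid gaze sample at or before
  each frame time, and flags frames whose nominal sample was invalid
  (blinks, track loss).

Gaussians are truncated at 3σ for speed; the truncation error is below
1.2% of a blob's mass and identical in filter and display. Rendering is
offline (frames plus a gaze log in, frames out); no real-time loop or
eye-tracker integration is attempted. Color is reduced to luminance
before rendering.

`schedule_frames()` handles the mismatch between a monitor refresh rate
and a lower video frame rate with an integer accumulator: frame `i`
occupies `round(i·r) − round((i−1)·r)` refreshes, `r = monitor_hz /
video_fps`, so repetitions are always `floor(r)` or `ceil(r)` and the
running total tracks real time to within one refresh. At 144 Hz over
23.96 fps (`r = 6.01`) frames repeat 6 times with a 7-repeat about every
4.2 s.

## 3. Reading-acuity psychometrics

A reading test shows three-line sentences at font sizes 0.9–1.4 logMAR
(each font twice per test). `score_trial()` is a deterministic stand-in
for experimenter scoring: tokens are lower-cased, punctuation-stripped
and matched *positionally* — a transposed word does not score. Bag-of-
words matching was rejected because it credits order errors that a human
scorer following the text would not.

`fit_acuity()` fits accuracy versus font size with a logistic whose
asymptotes are fixed at 0 and 100%, by maximum likelihood on word counts;
the 50% crossing is the equivalent acuity. Implementation notes:

* The ML fit is a weighted quasibinomial GLM on per-font proportions.
  Point estimates are identical to binomial ML on the word counts, and
  the quasi family accepts non-integer "counts", so noiseless expected
  profiles fit cleanly. Fixing the asymptotes (rather than fitting lapse
  rates) is the stable choice at 24 words per font.
* **Censoring, not failure.** All-correct profiles return
  `censored = "low"` with the bound at the smallest tested font
  ("acuity < 0.9"); all-wrong profiles return `censored = "high"`.
  Midpoints outside the tested range set `extrapolated`. Censored fits
  are excluded from span improvements (with a logged count) rather than
  imputed.
* **Uncertainty.** A seeded nonparametric bootstrap over sentences gives
  a percentile CI; 1000 resamples is the recommended setting. The
  function default is `boot = 0` because the recovery harness fits ~50
  psychometric curves per simulated cohort and the CI is not consumed
  there; pass `boot = 1000` when reporting a single subject's acuity.

Pooled accuracy and speed are unweighted means over fonts, matching the
equal-trials-per-font design. `logmar_from_snellen()` implements
`log10(denominator/numerator)`.

## 4. The syncopated design and the decoder

`build_schedule()` constructs the 23-session design: session 1 is an
intake acuity check, sessions 2–22 hold the 21 videos, and reading tests
fall at 6 of 8 positions (sessions 2, 5, ..., 20, 23), with every subject
keeping the first and last positions and skipping two non-adjacent
intermediates. That skip rule is exactly what produces three short
(3-video) and two long (6-video) spans per subject; skips are balanced so
each intermediate position retains 5 or 6 of 8 subjects. The generator
finds a balanced assignment by seeded search over the 10 admissible skip
patterns; `inst/extdata/syncopated_schedule_synthetic.csv` ships one such
assignment (synthetic — it is *a* constraint-satisfying solution, not a
transcription of any particular experiment's table).

The decoder assumes additivity and one modelling convention worth making
explicit: the reading test that *closes* a span is assumed to measure the
span without contributing to it — its own influence lands on later
measurements. Hence a short span contains one reading influence plus
three videos (`y1 = 3βV + βR`), a long span one plus six
(`y2 = 6βV + βR`), and

```{r decode}
decode_rates(-0.025, -0.035)
```

`decode_rates()` on a spans table pools all span improvements into
`y1`/`y2` means before decoding (the headline convention); with
`per_subject = TRUE` it additionally decodes each subject's own
`(y1, y2)` pair, which is what the recovery harness uses to build
t-intervals. With 6 tests per subject the final test influences nothing,
so `attribute_gains()` defaults to 5 reading influences against 21
videos; both conventions are reachable through its arguments.

`rates_from_regression()` is the model-free cross-check: OLS of acuity on
cumulative task minutes (each predictor alone and jointly), with
per-session conversions via mean session lengths (defaults 13.6 min
reading, 24.7 min video). On noiseless additive data the joint-model
conversion reproduces the decoder exactly; on noisy data the two
predictors are strongly correlated by design, so the regression route is
a sign-and-magnitude check, not a replacement.

## 5. Gaze metrics

`path_length()` sums Euclidean distances between consecutive valid
samples, normalised to screen widths. No smoothing or saccade detection
is applied — the raw scan path is the quantity of interest. Invalid
samples are dropped and segments are never bridged across a dropped run
or an interval longer than `max_gap_ms` (default 100 ms), preventing
blink jumps from inflating the length. `demeaned_correlation()` removes
each subject's mean from both paired series before pooling, so stable
between-subject differences (e.g. an always-restless subject) cannot
masquerade as a session-by-session association; the degrees of freedom
are `n_pairs − 2`.

## 6. The synthetic cohort generator

`gen_cohort()` emulates exactly the structure the analysis assumes:

* baseline acuities `N(1.28, 0.04²)` logMAR across subjects;
* latent acuity changes additively by `beta_R = −0.015` after each
  reading test and `beta_V = −0.00333` after each video (defaults);
* at each test the latent value is jittered by session-level noise
  `N(0, noise_sd²)` with `noise_sd = 0.04` logMAR, and every word is an
  independent Bernoulli draw from a logistic psychometric (slope 15 per
  logMAR) at that jittered value — so measurement noise has both a
  binomial floor and a session-level component;
* sentence durations follow a gamma per-word reading-time model (mean
  2.5 s/word), putting pooled phosphene-view speeds in the single-digit
  WPM range.

Defaults were chosen once to represent the study conditions this package
models. The slope default (15/logMAR) reproduces pooled accuracies in the
30–50% range over fonts 0.9–1.4 at those acuities; the `noise_sd` anchor
is taken from between-subject spread because no within-subject single-
test noise magnitude is available — it is an anchor, flagged as such, not
a fitted quantity. An exponential-saturation latent variant
(`latent_model = "saturating"`) exists, off by default, for
model-misspecification experiments.

What the generator does *not* emulate: sentence abandonment and partial
reading strategies, forgetting between sessions, motivation drift,
dropout, real video content (toy frames are drifting gratings), and the
real MNREAD corpus (synthetic sentences control only word count and
three-line layout). Passing tests therefore demonstrate correctness of
the pipeline under its own assumptions, not robustness to the many ways
real reading data violate them.

## 7. Validation results computed by this package

`recovery_experiment()` runs generate → fit → sort spans → decode per
replicate. With the default configuration it shows (and the test suite
and acceptance script recompute):

* **Unbiasedness**: mean decoded `beta_R` and `beta_V` over 200+
  replicates sit within two standard errors of the generating values;
  in the noiseless limit recovery is exact to machine precision.
* **Decoder identity**: encoding any rate pair to `(y1, y2)` and decoding
  recovers it to machine precision (the system is its own inverse).
* **Per-replicate ordering**: the probability that a single 8-subject
  cohort decodes `|beta_R| > |beta_V|` is about 84–85% under the default
  noise. This is a power statement, not a bug: the per-replicate
  population decode has a standard deviation of ≈0.034 on `beta_R`
  (measured across replicates), dominated by per-test measurement noise
  (binomial floor ≈0.017 logMAR plus the 0.04 session component), so a
  single small cohort recovers the *sign* structure reliably at the
  population-mean level but not with 95% per-replicate certainty. The
  t-interval coverage of the per-subject decode is ≈93% against a
  nominal 95%, slightly anticonservative because adjacent spans share an
  endpoint measurement.

Problem sizes used throughout the suite — 200–500 Monte-Carlo replicates,
1000-phosphene fields, 10-phosphene renderer oracles on 40×30-px toy
screens, 10⁴-pair decoder identity sweeps — were chosen to keep each
statistical check's own Monte-Carlo error an order of magnitude below the
tolerance it asserts.

## 8. Known limitations

* The renderer is offline and ignores display latency, gamma and
  anti-aliasing; latency robustness cannot be studied with it.
* The phosphene layout is a stylised two-knob construction; it reproduces
  center-weighting but no published electrode map.
* The decoder is exactly linear: any true saturation of learning within
  the studied window biases both decoded rates toward zero (the
  saturating generator variant exists to quantify this).
* Censored acuities remove spans rather than contributing bounds; a
  survival-style treatment of censored psychometric midpoints is out of
  scope.
* Scan-path metrics operate on whatever sampling rate the trace carries;
  no resampling is performed, so traces compared across systems should be
  pre-resampled by the caller.
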