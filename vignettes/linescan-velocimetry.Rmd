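---
title: "Measuring blood velocity from line-scan images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring blood velocity from line-scan images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kymoradon)
```

## The measurement

Line-scan imaging repeatedly scans a single line along a blood vessel.
Stacking the successive scans as rows produces a space-time image
(kymograph): columns are position along the vessel, rows are time.  A red
blood cell (RBC) moving along the vessel appears as a dark diagonal streak
against the fluorescently labelled plasma, and the streak angle theta,
measured here from the time (vertical) axis, encodes the velocity:

    v = (dx / dt) * tan(theta)

with `dx` the spatial resolution in um/pixel and `dt` the line period in
ms/line, so `v` comes out in mm/s.  `theta = 0` is stagnant flow (vertical
streaks); `|theta| -> 90` degrees means streaks too close to horizontal to
measure.  Positive theta denotes displacement toward increasing column
index; which physical direction that is depends on the scan path and is left
to the user.

`kymoradon` estimates theta as the angle at which the Radon projection of
the (filtered) image has maximal variance across ray offsets, using a
coarse-to-fine iterative search, and provides the surrounding measurement
calculus: how precise an angle step is needed for a target velocity
sensitivity, what precision the pixel grid can support at all, and how to
re-plan acquisition speed to put streaks near the 45-degree sweet spot.

## Pre-processing: why a vertical Sobel filter

Real line-scan data carry two artifact families (both are reproduced by the
synthetic generator):

* **time-invariant vertical bands** — the scan path leaves the vessel, so
  some columns are dark in every line;
* **time-varying horizontal bands** — heartbeat- and respiration-driven
  tissue motion modulates whole lines slowly (3–8 Hz in large mammals).

Temporal (vertical) demeaning — subtracting each column's mean over time,
`vertical_demean()` — removes the first family exactly and does nothing
about the second.  Convolving with the 3x3 vertical Sobel operator
(`sobel_filter_time()`) differentiates along time: it suppresses everything
that varies slowly in time (both artifact families) while enhancing the
sharp plasma–RBC junctions that bound each streak.  Whole-image demeaning
(`whole_image_demean()`) is provided as the weakest baseline.

Two consequences matter downstream.  First, a vertically filtered image has
essentially zero projection variance at exactly 0 degrees, so the angle
search must not evaluate 0 (see the search schedule below).  Second,
genuinely vertical streaks — stagnant flow — are themselves suppressed;
such windows are flagged invalid rather than measured.

Implementation notes: true convolution with the kernel as written (the
orientation only flips the output sign, which the variance never sees); the
output is cropped to the valid interior rather than padded, because padded
borders would bias the projection variance; the kernel is fixed at 3x3 —
two-photon streak edges are only a pixel or two wide, and a taller kernel
would blur line-to-line contrast rather than enhance it.

## The Radon engine

`radon_projection()` integrates the image along parallel rays at a given
angle, one ray per integer offset from the image center, sampling at unit
steps with bilinear interpolation (zero outside the raster).
`variance_profile()` turns that into the search criterion.  Numerical
choices that are deliberate:

* **Short-ray exclusion.**  Rays whose effective length through the raster
  is at most half the longest ray are dropped: zero-padded corner stubs
  otherwise distort the variance at oblique angles.
* **Ray-length normalization.**  Each kept ray sum is divided by the ray's
  in-image bilinear weight (its effective length), so a featureless image
  produces an exactly flat profile at every angle.  Without this, ray-length
  variation masquerades as structure.  `radon_projection()` itself returns
  raw sums, so the projection remains a discrete line integral (its bins sum
  to the image mass).
* **Half-pixel offset sampling.**  The variance search samples ray offsets
  at 0.5-pixel spacing.  With 1-pixel bins the variance peak aliases to the
  bin grid, producing systematic angle biases up to ~0.35 degrees on
  100-line windows that hold only a few streaks; half-pixel offsets reduce
  that to ~0.02 degrees at twice the cost.
* **Tie-breaking.**  Exact variance ties resolve to the smallest `|theta|`,
  then the earlier position in the angle list, so degenerate symmetric
  inputs behave deterministically.
* Angles are always reduced modulo 180 into [-90, 90); the profile is
  180-degree periodic, so nothing is lost.

The agreement between this interpolating engine and an independent
brute-force implementation (explicit pixel rotation with nearest-bin
accumulation) is part of the test-suite; agreement with any *other*
implementation at the 0.01-degree level is not guaranteed, since the
discretization scheme is a free choice.

## The iterative angle search

A traditional search at step `delta` over the full 180-degree range costs
`ceiling(180 / delta)` Radon transforms.  The iterative search
(`iterative_radon()`) instead evaluates four angles per iteration:

* iteration 1: `{-67.5, -22.5, +22.5, +67.5}` — a 45-degree step spanning
  180 degrees.  The phase is chosen to avoid both 0 (the Sobel null) and
  the wrap point at -90; any phase is mathematically admissible.
* iteration i >= 2: `c + {-1.5, -0.5, +0.5, +1.5} * s_i` around the running
  best angle `c`, with `s_2 = 45` degrees and `s_i` halving thereafter.
  This stencil reproduces the canonical resolution sequence
  `delta_i = 45 / 2^(i-1)` exactly.

The best (angle, variance) pair over **all** evaluations so far is carried
forward: an iteration whose four candidates all underperform leaves the
center unchanged, so the search can recover from a locally misleading
refinement.  A candidate that lands exactly on 0 degrees is nudged to
`sign * s_i / 100` (its variance would be the Sobel null anyway); the nudge
is recorded in the trace.  Repeated angles across iterations are *not*
cached: the transform count is exactly `4 * iterations`, matching the
closed-form budget arithmetic (`iterations_needed()`,
`transform_count_iterative()`, `count_ratio()`).

Reaching a 1-degree step takes 7 iterations = 28 transforms against 180
traditionally (6.4x); 0.01 degrees takes 56 against 18,000.  The speed-up
grows without bound as the step shrinks, because the iterative count is
logarithmic in `1/delta`.  Note the ratio is monotone along the schedule's
achievable steps `45 / 2^k`; between them the ceiling in the iteration count
makes it locally jagged.

Structureless windows (constant after filtering, stagnant-flow verticals)
yield a result flagged `valid = FALSE` instead of an error — long in-vivo
recordings contain unusable segments and the pipeline must continue.

## Precision planning

`precision_report()` bundles the pixel-resolution limits for a geometry: the
streak extents `ws = min(w, ceiling(h tan(theta0)))`,
`hs = min(h, ceiling(w cot(theta0)))`; the single-streak limit `delta_s1`
(the angle change produced by offsetting a streak end by one pixel along its
longer dimension); the packing bound `ns` on how many streaks fit at a
minimum spacing; and the aggregate limit `delta_n = delta_s1 / ns`.  Real
images may hold fewer streaks than `ns`, so attainable precision lies
between `delta_n` and `delta_s1`.  The default minimum inter-streak spacing
is `ds = 4` um, a typical capillary RBC spacing; override it for your
preparation.  Degenerate angles use the conventions `(ws, hs) = (1, h)` at 0
and `(w, 1)` at 90 degrees, negative angles are handled by symmetry, and
`ns` is floored at 1 (with a warning) so `delta_n` stays defined.

The velocity side of the calculus: a fractional velocity change dv/v
corresponds to `tan(theta1)/tan(theta0) - 1`, and the angle step needed to
resolve a target dv/v (`angle_change_for_dv()`) is largest at `theta0 = 45`
degrees — the reason to re-plan acquisition speed with `speed_factor()` /
`rescaled_angle()` so streaks land near 45 degrees.  Speeding up by
`k = tan(theta)` lands exactly on 45.

## The windowed pipeline

`estimate_trace()` cuts a long recording into overlapping windows (default
100 lines with a 25-line hop, configurable), filters each window, runs the
iterative search, and converts angles to velocities.  The precision target
is either a fixed angle step or a fractional velocity change; in the latter
case each window first runs a 7-iteration pre-pass (0.7-degree step), then
converts the target dv/v to the window's required step via the angle it
found — the requirement depends on the angle, so it is computed per window —
and the same search is deepened in place if more iterations are needed.
Provisional angles below 0.5 degrees are clamped to 0.5 for that conversion,
since the required step vanishes with the angle itself.  Window timestamps
are the window-center line times; a short tail that cannot fill a window is
dropped.

Per-window failures are flagged, never fatal.  Estimates that land within a
margin of +/-90 degrees are flagged by `flag_outliers()` — on
artifact-dominated windows the residual horizontal structure wins the
variance race, and those failures cluster tightly at the horizontal limit.
`smooth_trace()` offers a centered moving average over a time span (for
example a span covering several cardiac cycles to suppress heartbeat
pulsation); band-pass separation of stimulus-evoked from cardiac components
is out of scope.

## The synthetic generator, and what passing tests do (and do not) show

`generate_streak_image()` renders dark bands along lines at a known angle on
a bright background — RBCs are dark against labelled plasma; an inverted
option covers RBC-labelled preparations.  Bands have a trapezoidal
perpendicular profile with 1-pixel anti-aliased edges, matching the
pixel-or-two edge sharpness of two-photon streaks.  Defaults: 112x215
pixels, 4-pixel-wide streaks 12 pixels apart, contrast 0.6 on background
1.0, no noise — a clean mid-density capillary kymograph.  Noise is additive
Gaussian, seeded and reproducible.  `add_static_band()` and
`add_motion_artifact()` inject the two artifact families; the motion
artifact is a smooth quasi-periodic row darkening (raised-cosine pulses with
seeded center jitter) whose period should be chosen to emulate 3–8 Hz at
your line period — e.g. ~250 lines at 1 ms/line.

`generate_sequence()` concatenates epochs with different angles as one
continuous RBC train: the spacing measured along the scan axis is fixed by
the first epoch and the streak phase advances across boundaries, as real
cells do when flow speed steps.  The perpendicular spacing in later epochs
therefore deviates from the nominal value by the ratio of the cosines.

What the generator does **not** emulate: shot noise and detector statistics,
RBC deformation and overlap, scanner flyback, focus drift, and the
irregular cell spacing of real flow.  Passing tests therefore demonstrate
the algorithm's geometric correctness and its relative robustness ordering
(Sobel vs demeaning), not absolute in-vivo error rates: published in-vivo
failure percentages are dataset-specific and are reproduced here only as
qualitative orderings.

## Test design and problem sizes

Property tests run on images of 48–216 pixels per side and sequences of
2,000–3,000 lines — large enough that every streak-geometry regime appears,
small enough that the whole suite runs in well under a minute.  Oracles are
independent by construction: closed-form identities for the planning
calculus, an exhaustive coarse-then-fine grid argmax for the iterative
search, and a nearest-bin rotation oracle for the projection engine.  Two
empirical notes from this calibration work are worth keeping in mind when
extrapolating:

* near-vertical streaks need temporal extent — at 2 degrees a window of 144
  lines still shows ~0.07-degree bias because the streak sweeps only ~5
  pixels of space; ~216 lines suffice for 0.05-degree accuracy;
* recovery under noise degrades below ~15 degrees of streak angle as the
  noise standard deviation approaches the streak contrast (the temporal
  gradient that survives Sobel filtering is proportional to the angle):
  at a contrast-to-noise ratio of 5 roughly one window in fifteen collapses
  to a spurious high-angle noise peak, which the +/-90 outlier flag does not
  always catch.  Fast flows (angles near 45–85 degrees) are unaffected.

## A worked example

```{r example}
# simulate a vessel at 42 degrees, recover it blind
img <- generate_streak_image(synthetic_spec(theta = 42, width = 112,
                                            height = 300, noise_sd = 0.05,
                                            seed = 7))
res <- iterative_radon(sobel_filter_time(img), target_delta = 0.1)
res

# what velocity is that at 0.47 um/px and 0.9 ms/line, and how precise?
velocity_from_angle(res$theta, dx = 0.47, dt = 0.9)
dv_from_angle_change(res$theta, res$theta + res$achieved_delta)
```
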