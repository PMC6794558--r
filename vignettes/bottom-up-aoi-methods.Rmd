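---
title: "Bottom-up AOI analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up AOI analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazeaoi)
```

`gazeaoi` turns raw binocular gaze samples into per-participant relative
fixation durations (RFD) over *a posteriori* areas of interest — AOIs
derived from the observed fixation density rather than drawn by hand.
This vignette explains each stage's model and assumptions, the parameters
that matter, the numerical choices, what the synthetic generator does and
does not emulate, and the known limitations.

## Coordinate conventions and geometry

All coordinates are screen-raster pixels: origin at the top-left corner,
x rightward, y downward, 0-based, with the on-screen region the half-open
rectangle `[0, W) × [0, H)`. `screen_geometry()` couples the raster to
the physical screen and viewing distance; `pixels_per_degree()` converts
visual angle to pixels as `raster · distance · tan(1°) / physical_size`,
so parameters expressed in degrees (noise, merge radius) transfer across
setups. Off-screen samples are retained through event detection — velocity
estimation needs the complete kinematic record — and are only excluded
when fixations are pooled for clustering and when RFD is computed.
Sampling rate is carried as metadata only; every computation uses actual
timestamps, so irregular sampling is handled transparently.

## Event detection

**Cyclopean fusion.** Where both eyes are valid, coordinates are averaged;
where one eye is missing, the other eye's coordinates are substituted.
No temporal interpolation is performed across samples where both eyes are
missing: fabricating gaze positions inside blinks or track losses would
bias downstream velocities.

**Velocity.** `compute_velocity()` is the point-to-point speed
`√(Δx² + Δy²)/Δt` in px/s over consecutive valid samples; pairs spanning a
missing sample are dropped. Before velocity computation the positions are
boxcar-smoothed over `smooth_window = 3` samples (config-exposed; 1
disables). At 250 Hz, isotropic measurement noise of σ = 0.3° (≈12 px at
the default geometry) produces raw sample-to-sample speeds of the same
order as genuine saccades; a 3-sample average suppresses most of that
noise while displacing event edges by at most about one sample per side.

**Adaptive threshold.** Each participant × trial gets its own threshold,
so the classifier automatically becomes more conservative for noisier
recordings. The density of log₁₀ velocity is smoothed
(`stats::density`, normal-reference bandwidth); if two substantial modes
appear (both ≥ 5% of the peak density, separated by a valley at most 0.8×
the lower peak), the threshold is the density minimum between the two
highest modes (`adaptive_bimodal`). Otherwise — near-constant series,
too few positive velocities (a noiseless recording's slow mode sits at
exactly zero, invisible on a log scale), or no clear bimodality — the
robust fallback `median(v) + 5·mad(v)` is used and tagged
`fallback_robust`. The method tag is stored with each result so the
branch taken is auditable.

**Classification and edge refinement.** Maximal runs of sub-threshold
velocities become candidate fixations. Because the velocity stage sees
smoothed positions, each candidate's boundaries are then *refined* on the
unsmoothed cyclopean trace (`refine_edges = TRUE`): the fixation's core
position and noise scale are estimated robustly (medians over interior
samples; the Rayleigh-median relation converts a median distance into a
σ), and each boundary grows or shrinks to the contiguous block of samples
within 3σ of the core, never crossing a neighbouring event. Two-stage
detect-then-refine keeps the robustness of velocity thresholding while
restoring sample-level edge precision.

**Noise floor and merging.** Candidates shorter than `min_fixation_ms`
(default 60 ms = 15 samples at 250 Hz, a conservative floor for
noise-induced runs) are discarded. Successive fixations separated by at
most `merge_max_gap_ms = 75` ms with centroids within
`merge_max_dist_deg = 0.7°` are merged — such pairs are usually one
fixation split by a noise spike or a micro-event. Merging iterates to a
fixed point, which makes it idempotent by construction. Fixation position
is the duration-weighted centroid of member samples (trapezoidal weights),
which always lies inside the samples' bounding box.

## Fixation-density centroids (mean shift)

Fixations from all participants are pooled per stimulus (each fixation
counts once by default; `weight_by_duration` enables duration weighting)
and clustered by Gaussian-kernel mean shift: every point iterates to the
kernel-weighted local mean of all points until the step falls below
`tol = 1e-3` px or `max_iter = 500`. Each trajectory converges on a mode
of the kernel density estimate; converged locations closer than
`bandwidth/2` are grouped (connected components) into one centroid, and
every input point is assigned to the centroid its trajectory reached —
no point is discarded (`min_cluster_size = 1` by default). Centroids are
reported in reading order (y, then x), which makes results invariant to
input-point order.

**Bandwidth.** The default is a capped normal-reference rule:
`h = 2 · σ̂ · n^(-1/6)`, with σ̂ the root mean of the two marginal
variances, capped at `max_bandwidth = 60` px. The factor 2 oversmooths
slightly relative to the density-estimation optimum, which is the right
trade-off for mode *seeking*: at the optimum, sample-level density
wiggles routinely produce spurious modes on a single cluster. The cap
matters for pooled multi-AOI data, whose global dispersion reflects the
distance *between* areas of interest, not the scale of any one of them;
60 px ≈ 1.5° at the default geometry, the natural spatial scale of a
single AOI. Below the cap the bandwidth scales with the data
(equivariant under coordinate scaling); a `fixed_bandwidth` overrides the
rule entirely. The rule is a scalar (isotropic kernel) — a full plug-in
bandwidth matrix is out of scope.

## Voronoi AOIs

`build_voronoi()` partitions the screen into one convex cell per
centroid — all screen locations closer to that centroid than to any
other. Cells are computed by clipping the screen rectangle against the
perpendicular-bisector half-planes (Sutherland–Hodgman), which handles
the unbounded outer regions and guarantees exact tiling: polygon areas
sum to `W·H` to floating-point precision. A single centroid owns the
whole screen; duplicate centroids are rejected as degenerate.

Cell naming is deliberately manual and auditable (`label_cells()`), as in
practice an experimenter names cells from their position over the
stimulus; unnamed cells default to `Background`, so "background" is
defined by the data density rather than by a drawn region. Several cells
may share a label; RFD pools them. `anchor_label_map()` mechanizes the
common case of naming centroids by proximity to known stimulus landmarks.
Fixations are assigned to cells by nearest centroid, which coincides with
polygon containment for a Voronoi partition — both implementations exist
and their agreement is tested — with boundary ties broken to the lowest
cell index (boundaries carry zero measure, so the rule only matters for
determinism).

## Relative fixation duration

For each participant × stimulus,
`RFD(label) = Σ duration of on-screen fixations in cells with that label /
Σ duration of all on-screen fixations`. The denominator is on-screen
fixation time, not trial wall time, so RFD measures the *distribution* of
attention over the screen, conditional on looking at it. Off-screen
fixations enter neither side; participants with zero on-screen time get
explicit missing values rather than zeros. Because the cells tile the
screen, RFD over all labels (including `Background`) sums to exactly 1 —
a conservation property tested to 1e-9 — and relabeling two cells to a
common name sums their RFDs exactly. The package ends at the tidy long
table plus descriptive group summaries (mean, n−1 SD): mixed-design
ANOVA, post-hoc tests and effect sizes are standard downstream routines,
and re-implementing them here would add nothing.

## The synthetic generator

`generate_trace()` emulates a 250 Hz binocular screen tracker: planted
fixations at fixed positions, constant-velocity linear saccades between
them, independent per-eye isotropic Gaussian noise (specified in degrees),
a small horizontal interocular offset, and per-eye Bernoulli sample
dropout. `generate_experiment()` layers a multi-group design on top:
per-group dwell-propensity maps over semantic anchor regions, individual
propensities jittered around the group means, and complete truth tables
(planted fixations, intended labels, intended RFD).

Default conditions used throughout the tests mirror a typical
infant/child screen-tracking session: 250 Hz, noise σ = 0.3°, 2% per-eye
dropout, fixation durations 150–400 ms, saccade durations 30–60 ms.
`random_fixation_plan()` enforces a minimum step of 250 px between
consecutive fixations: via the oculomotor main sequence, a 30–60 ms
saccade corresponds to an amplitude of several degrees, so sub-degree
"saccades" with those durations would be kinematically inconsistent.

What the generator does *not* emulate: drift and microsaccades within
fixations, smooth pursuit (the dynamic stimuli of real studies elicit
it), vergence, pupil-size artefacts, main-sequence velocity profiles
(saccades are linear ramps), and spatially correlated calibration error.
Passing tests therefore demonstrate the pipeline's correctness under its
stated model — stationary fixations plus fast transitions and white
measurement noise — not performance on pursuit-rich recordings; on real
video stimuli, slow pursuit segments will be absorbed into fixations or
split by the threshold, as with any velocity-based classifier.

## Problem sizes and determinism

The validation suite uses 50 seeded traces for planted-fixation recovery,
100 seeded replicates for mode-count recovery (K = 1…5, 80 points per
cluster), 10⁵ Monte-Carlo points for partition checks, 10⁴ for
assignment duality, and a 3-group × 2-condition experiment with n = 30
participants per group (plus 50–100 lighter two-group replicates for the
sign of planted group differences) — sizes chosen to give stable
pass/fail behaviour on a single CPU in minutes. All randomness flows
through explicit seeds; generation restores the caller's RNG state, and
identical seeds give byte-identical traces and tables.

## Known limitations

- The adaptive threshold assumes the velocity distribution is dominated
  by the fixation mode; recordings that are mostly saccade or track loss
  trigger the robust fallback.
- The bandwidth cap (60 px) is calibrated to the default geometry; for
  very different viewing distances it should be rescaled via
  `pixels_per_degree()`.
- Cells are clipped to the full screen rectangle. If a stimulus is
  displayed with a border band, pass a geometry describing the stimulus
  raster instead.
- Labeling is manual by design; there is no automatic face/object
  detection.
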