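---
title: "Scoring head-fixation stress from facial landmarks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring head-fixation stress from facial landmarks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facestress)
```

## The problem and the data model

A head-fixed mouse cannot be assessed with whole-body behaviour, so stress
has to be read off the face: orbital tightening (squinting), reduced nose
and ear motion (freezing), and abnormal ear posture (folds, asymmetric
movement) are the established grimace-scale cues. `facestress` assumes
those cues have already been localised by a markerless pose tracker that
emits, per video frame, an (x, y) position and a confidence
("likelihood") in [0, 1] for seven landmarks: both ears, upper and lower
eyelid of each eye, and the nose.

The universal container is the `trajectory_table`: one row per frame,
columns `<landmark>.x/.y/.likelihood`, image coordinates (origin top-left,
y downward, pixels), with the frame rate attached as metadata because the
exchange formats store none. The supported frame-rate range is 30–60
frames/s, default 30. Two dialects are read and written: the 3-header-row
CSV (`scorer` / `bodyparts` / `coords` rows, then a frame index and
x, y, likelihood triplets) and an HDF5 layout carrying the same column
hierarchy. CSV numbers are written at 17 significant digits so a
round-trip is value-exact.

### Cleaning

Trackers emit garbage coordinates at low confidence, so every pipeline
entry point first applies `clean_trajectories()`: points below the
likelihood threshold (default 0.6) are replaced by per-coordinate linear
interpolation between the nearest confident neighbours when the gap is at
most `max_gap_frames` (default 5 frames, i.e. ~170 ms at 30 fps — about
the longest span over which facial motion is plausibly linear), and
otherwise flagged missing (`NA`). Runs touching the session edges cannot
be interpolated and are flagged missing regardless of length. Cleaning is
idempotent and never alters a confident point; a landmark with no
confident frame at all is an error rather than a silent guess.

## Per-window metrics

All heuristics operate on consecutive non-overlapping 2-second windows
(`window_s`, default 2.0 s); a final partial window is kept when at least
half full, with its shortfall recorded in `valid_fraction`. Distances are
standard Euclidean distances in pixels; every motion quantity is then
normalised by the body scale `S`, the session-median inter-ear distance —
the only stable, large baseline among the seven landmarks — which makes
all downstream scores invariant to camera distance, resolution, and
translation (property-tested under ×0.5, ×3 rescaling and translation at
tolerance 1e-9).

* **Eye aperture and squints.** The aperture is the per-frame distance
  between the eyelid pair. The open-eye baseline `B` is the 75th
  percentile of the aperture series: high enough to be untouched by the
  very closures being detected, low enough to ignore wide-eye outliers.
  Closure epochs are maximal runs with aperture `< closure_fraction × B`
  (default 0.4, a relative threshold so the rule survives camera changes).
  Epoch duration classifies the epoch: under `blink_max_s` (1.0 s) it is a
  blink and never contributes to stress; at or above it, a squint. The
  boundary itself is classified squint, since blinks are strictly
  sub-second events. Epoch detection runs on the raw aperture series —
  durations are the classification criterion and smoothing would blur
  them; a 1-second moving-average companion series is returned for
  display and trend summaries.
* **Nose.** Per window, the maximum range of motion is the diameter of
  the visited point set (maximum pairwise distance). The diameter, rather
  than displacement from the window's first frame, makes the value
  independent of where the window boundary happens to fall and guarantees
  it never exceeds the travel distance (the cumulative path length over
  consecutive non-missing positions, with gaps bridged by a single
  segment). The activity index is the arithmetic mean of the two
  scale-normalised components, `A = (R/S + T/S)/2`: the simplest
  dimensionless combination that is strictly monotone in both, zero only
  for a stationary point.
* **Ears.** Each ear gets the same activity index. Asymmetry is
  `|A_L − A_R| / (A_L + A_R)`, defined as 0 when both activities are 0
  (two still ears are symmetric); unilateral ear movement is a
  discomfort cue. A fold is flagged when an ear is both immobile (window
  range below `fold_range_threshold × S`, default 0.05) and displaced
  (window-mean position more than `fold_displacement_threshold × S`,
  default 0.15, from the ear's session-median position). Both predicates
  are needed: a still ear in its usual place is just calm.
* **Freezing.** A window freezes when the nose and both ear activity
  indices all drop below `freeze_activity_threshold` (default 0.145,
  placed in the empirical gap between frozen and relaxed activity under
  the default simulator geometry: frozen sessions stay below ~0.12,
  relaxed ears above ~0.17 and the relaxed nose above ~0.40).

## From metrics to the 0–10 score

Each of the five features (two ears, two eyes, nose) is mapped to [0, 10]
by a piecewise-linear calibration (`default_calibration()`), clamped at
the knot range:

* Eyes: the maximum of a squint-coverage map (fraction of the window
  inside squint-kind epochs; 0 → 0, 0.5+ → 10) and a relative-aperture
  map (window-mean aperture / baseline; sustained narrowing scores even
  when no single epoch is detected).
* Nose and ears: inverted activity maps — immobility scores high,
  because during head fixation the stressed face is the still face.
  Ears additionally receive `+delta_fold` (default 4) when folded and
  `+delta_asym × asymmetry` (default 2).

The scale direction is a modelling commitment: the nose map treats *low*
activity as stress (freezing), which is correct for fixation stress but
would mis-rank, e.g., pain-induced agitation; the maps are knot lists in
the configuration precisely so a lab can recalibrate them.

Knot positions were placed against the simulator's measured
activity-index distributions so that a textbook relaxed session scores
below 2 and a textbook combined-stress session above 8 under the default
geometry; they are not fitted to any labelled data (none ships with the
package) and are fully overridable.

The per-window total is the weighted mean `Σ wᵢ sᵢ / Σ wᵢ` over features
with positive weight and a non-missing score. Weights default to 1;
setting a weight to 0 is exactly equivalent to deleting the feature, and
windows with missing features renormalise over the remainder rather than
imputing — the same semantics the ablation analysis exploits. The
session mean weights windows by `valid_fraction`, so sparse windows count
less. Status is an even tercile split: okay below 10/3, caution from 10/3
up to (excluding) 20/3, stressed above; the boundaries belong to the
higher band. The scale is standardised to 0–10 everywhere (some
observational protocols quote 1–10; the bottom point is simply never
reached by a calm animal under this calibration).

## Live evaluation

The live monitor mirrors the batch pipeline on a per-frame sliding basis:
a trailing 2-second buffer (tumbling windows would delay feedback), a
rolling 60-second horizon for the open-eye baseline, body scale, and ear
reference positions, and configuration-constant fallbacks during
warm-up. Live cleaning masks low-likelihood points without interpolating
(interpolation would need future frames). Out-of-order frames are
dropped with a warning; index gaps register missing frames and lower
`valid_fraction`. Memory is bounded by the rolling horizon regardless of
stream length, and emission is a pure function of the buffered frames, so
replaying a message log reproduces the emission log bit for bit.

`score_trailing_window()` is the batch reference for this path: both it
and the monitor call the same single-window core, so the final emission
of a replayed table equals the batch trailing-window score (tested at
1e-9). The displayed status additionally applies hysteresis — a switch
requires `hysteresis_frames` (default 15, half a second) consecutive
agreeing frames — because a per-frame indicator that flickers between
bands is useless to the experimenter; the instantaneous classification is
always available as `status_raw`.

## The session simulator

`simulate_session()` exists so that every pipeline stage is testable
against known ground truth without any recording. It emulates what a
keypoint tracker outputs, not what a camera sees: per-state reflected
Gaussian random walks for nose and ears (reflection keeps walks inside
anatomically plausible boxes), eyelid pairs whose aperture collapses
during closure events, Poisson-timed sub-second blinks (uniform 0.2–0.5 s
durations, with a 0.5 s refractory gap so closures never merge),
intermittent sustained squints (uniform 1.5–4 s, separated by 1–2.5 s
open gaps — squints clipped below 1 s by a state boundary are discarded so
the event log stays consistent with the duration rule), near-zero step
noise when frozen, one ear pinned at an offset when folded, isotropic
Gaussian jitter on every point (sd 0.3 px), and independent Bernoulli
dropouts (rate 0.02) whose likelihood falls below 0.5 and whose
coordinates are scattered, as a confused tracker's are. The default
geometry approximates a 1080p front-camera framing (inter-ear ≈ 200 px,
open aperture 24 px) at 30 fps, but no test relies on absolute pixels —
all assertions are scale-invariant.

What the simulator deliberately does not model: pixel appearance,
whisker/cheek cues, pupil size, breathing, 3-D nose motion (a front
camera sees X/Y only), tracker error correlated with pose, and
habituation dynamics across days (graded cohorts approximate this by
mixing stressed time fractions). Passing tests therefore demonstrate
that the pipeline recovers the constructs it defines, under
tracker-like noise — not that those constructs capture everything a real
stressed mouse does.

`make_validation_cohort()` assigns each simulated mouse a stressed-time
fraction and returns the true profile, which the validation statistics
consume: min-max profile normalisation onto [0, 10] (affine, so it never
changes a correlation), Pearson r with the two-sided t-transform p,
Cohen's kappa with unweighted/linear/quadratic agreement weights
(linear by default, suiting an ordinal 1–10 scale; more than two raters
are reduced to the mean over all pairs, since the statistic is
intrinsically pairwise), and the Monte Carlo identity-shuffle test:
permute the mouse-id assignment of one profile, recompute Pearson r
under each of `n_sim` permutations (default 10000), and report the
add-one estimator `p = (1 + #{null ≥ observed}) / (n_sim + 1)`, which is
never exactly zero and matches exhaustive enumeration at n = 7 within
binomial error.

## Numerical choices and degenerate inputs

* Quantiles use the default interpolating definition (type 7); medians
  of duplicated samples are exact, which the window-concatenation
  property relies on.
* Piecewise-linear maps clamp outside their knot range (no
  extrapolation), then to [0, 10].
* Ties: a closure of exactly `blink_max_s` is a squint; a total exactly
  at a status threshold takes the higher band; asymmetry 0/0 is 0.
* Errors, not guesses: an all-missing aperture series, a landmark with
  zero confident frames, a constant profile under min-max rescaling, a
  zero-variance correlation input, thresholds out of order, and a
  schedule that contradicts the session duration all raise informative
  errors.
* Kappa with a single category used by every rater is 1 under perfect
  agreement and an error otherwise (chance agreement is 1, so the usual
  ratio is undefined).
* Determinism: the simulator is bit-reproducible from its seed; scoring
  contains no randomness; the Monte Carlo accepts an explicit seed.

## Problem sizes in the shipped tests

The test suite and the acceptance script run entirely on simulated data:
sessions of 3–60 s at 30 fps, cohorts of 5–7 mice, 25–50 sessions per
condition for separation and detector-recovery checks, 1000-case
geometry and aggregation oracles, 500 random closure traces, the full
5040-permutation enumeration at n = 7, and 200-repetition null
calibration for the permutation p-values. These sizes were chosen as the
smallest at which the stochastic properties under test are stable.

## Known limitations

* The calibration is heuristic, not learned; absolute scores should be
  read as a consistent ordinal scale, not a physiological unit.
* A session consisting almost entirely of eye closure pushes the
  75th-percentile baseline toward the closed aperture; the relative
  closure threshold then under-detects squints. The live mode's rolling
  baseline has the same property. Sessions should include some open-eye
  time, which head-fixation protocols in practice do.
* The ear-fold test needs the session (or rolling) median to reflect the
  unfolded posture; an ear folded for an entire session is reported as
  immobile but cannot be flagged displaced.
* Only X/Y motion is observable; depth motion of the nose is invisible
  to a front camera.
* The scorer trusts the tracker's likelihoods; systematically confident
  but wrong tracking is indistinguishable from behaviour.
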