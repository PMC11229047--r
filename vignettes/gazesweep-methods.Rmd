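---
title: "Analysing room-clearance visual search with gazesweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing room-clearance visual search with gazesweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazesweep)
```

## The problem

Tactical room clearance ("close-quarter battle") is taught with a
prescribed visual routine: enter, check the near corners beside the door,
then sweep the walls systematically towards the back of the room. Trained
searchers show a characteristic oculomotor signature — fewer, longer
fixations, a predictable segment-to-segment scan, and saccades that keep
going in the same direction — while novices produce short fixations and a
scan that keeps doubling back on itself. `gazesweep` implements the full
measurement chain for quantifying that signature from head-mounted
eye-tracker recordings of simulated room-clearance trials, together with
a synthetic-data generator so that every stage can be exercised and
validated without any recordings.

Gaze is represented throughout in 2D angular coordinates on the unwrapped
room-wall surface: azimuth runs around the room with the entry door at
the two ends of the `[-180, 180]` degree strip, elevation is vertical.
All the downstream quantities (dispersion, saccadic angle, AOI
transitions) are defined in this plane, which is also how gaze traces from
such experiments are conventionally visualised. Time is in seconds with
t = 0 at room entry; that alignment is a package convention — entry-time
offsets can be supplied per trial where logs differ.

## Preprocessing

Raw 120 Hz azimuth/elevation samples pass through, in order:

1. **Gap handling.** Invalid runs (blinks, tracking loss) no longer than
   `max_interp = 0.075` s are linearly interpolated; longer gaps split the
   trace into independent segments. The limit is deliberately below the
   100 ms minimum fixation duration, so interpolation alone can never
   fabricate a fixation.
2. **Three-frame median filter**, which removes single-sample tracker
   glitches while leaving ramps untouched.
3. **Zero-phase second-order Butterworth low-pass**, applied forward and
   backward, once with a 30 Hz cut-off (the *fixation stream*) and once
   with 50 Hz (the *saccade stream*). Both streams derive from the same
   median-filtered input and stay sample-aligned with it.

Two numerical details matter. The filter is run on the signal minus its
initial value: the forward–backward passes start from a zero internal
state, and the start-up transient scales with the absolute signal level
(wall coordinates reach ±180 degrees), so removing the DC level first
keeps edge transients at the level of the signal's own variation. The
signal is also extended by odd reflection over at least three filter
time-constants before filtering. The effective magnitude response is the
squared magnitude of the one-pass design; `butterworth_response()` gives
the exact analytic curve of the implemented (bilinear, prewarped) filter,
which is what the tests compare against — at 55 Hz this differs from the
continuous-time textbook curve because of frequency warping near Nyquist,
and the implemented discrete response is the honest reference for the
implemented filter.

## Event detection

**Fixations** use dispersion-threshold identification (I-DT): maximal
contiguous runs whose spatial extent `(max-min azimuth) + (max-min
elevation)` stays within 1 degree and whose duration reaches 100 ms. The
window grows greedily from the earliest admissible start. Because a noise
spike can transiently break the dispersion budget of one true fixation,
consecutive detections separated by less than 75 ms *and* less than the
dispersion threshold in centroid distance are rejoined; a genuine saccade
always moves the centroid further than that, and 75 ms is below the
shortest possible intervening fixation. Event boundaries are placed at
the midpoints between samples, so a run of *m* samples has duration
*m*/rate — the unbiased estimate of the underlying interval under uniform
sampling phase.

**Saccades** are flagged where the acceleration magnitude (central
second differences of the 50 Hz stream, combined across both channels)
exceeds five times the trial's median absolute acceleration. The
threshold is adaptive per trial; a floor of 50 deg/s² guards the rule on
nearly noiseless signals, where the median collapses to numerical
precision (any genuine saccade peaks three to four orders of magnitude
higher). Candidate onsets and offsets are refined to the nearest
acceleration extremum at or outside the threshold crossing; refinement
extrema must themselves reach the threshold and must lie within 50 ms of
the crossing, which joins the two suprathreshold lobes flanking a
saccade's mid-flight acceleration zero without ever chaining across a
fixation. Events with total displacement under 0.1 degree are discarded
(the direction angle is numerically unstable at zero displacement), and
events crossing gap boundaries never arise because detection runs per
contiguous segment.

Fixation and saccade detection run on separately filtered streams, as is
conventional, and are not reconciled against each other by default;
`reconcile_events()` (or `detect_events(reconcile = TRUE)`) optionally
truncates fixations at saccade boundaries and re-applies the duration
floor.

Known measurement properties, visible in the noiseless recovery tests:
the smoothing filter blends 1–2 samples at each event edge, and the slow
tails of a small-amplitude raised-cosine saccade fit inside the
dispersion budget, so individual boundary samples can migrate between a
fixation and an adjacent small saccade. Duration errors stay within a few
samples per event and several milliseconds on the trial mean.

## Scanpath metrics

* **Mean fixation duration** and **fixation count**.
* **Search rate**: number of fixations divided by their mean duration —
  high values mean many short fixations.
* **Gaze transition entropy**: Shannon conditional entropy, in bits, of
  first-order transitions between the 12 wall-segment AOIs,
  `H = -Σ_i p(i) Σ_{j≠i} p(j|i) log2 p(j|i)`, with `p(i)` estimated as
  the marginal source distribution of observed transitions (row totals
  over total transitions) and `0·log 0 = 0`. Consecutive fixations on the
  same AOI are collapsed first, so self-transitions are excluded and the
  maximum is `log2(n-1)`. Implemented as standard (non-negative)
  conditional entropy; `p(j|i)` is the probability of fixating AOI *j*
  conditional on the previously fixated AOI *i*. Target AOIs are excluded
  from the transition alphabet by default (`entropy_alphabet = "all"`
  includes them); sequences with fewer than two transitions score 0.
* **Saccadic angle** θ = atan2 of the displacement components, wrapped to
  `(-180, 180]` (0 rightward, 180 leftward), and **intersaccadic angle**
  θ_d, the wrapped difference between successive saccade directions.
* **Antipersistent percentage**: the share of |θ_d| strictly greater than
  90 degrees. The 90-degree boundary is inclusive on the persistent side
  ("within 90 degrees in either direction").
* **Time to fixate first target**: latency from entry to the first raw
  gaze sample inside any target polygon (the gaze vector, not a detected
  fixation, mirroring how a VR environment logs acquisition).
* **Search-order compliance**: a trial is compliant when the earliest
  fixation on a near-corner segment precedes the earliest fixation on a
  back-wall segment. The trained routine starts at the near corner, so
  "back wall first" is scored as a violation; trials that fixate a near
  corner but never the back wall count as compliant, trials that fixate
  neither do not. The reading is flag-invertible (`invert = TRUE`)
  because the verbal definition of such proxy measures is ambiguous;
  per-trial booleans aggregate to a percentage of trials.

AOI assignment is polygon containment of the fixation centroid; points on
a shared boundary go to the lower-numbered segment, and target polygons
take precedence only when requested. Which segments carry the
`near_corner` and `back_wall` roles is part of the layout object, since
it varies with room configuration; the default layout tags the outermost
segment on each side of the door and the two central (opposite) segments.

## The statistics stage

Each metric is aggregated to participant × phase means and analysed with
a 3 (group: feed-forward training, feed-back training, control) × 2
(time: pre, post) mixed ANCOVA, fitted as a split-plot decomposition:
participant means carry the between-participant stratum (group, and
optionally a participant-level covariate such as recruitment pool), and
pre-to-post differences carry the within stratum (time, group × time,
and — when the covariate is retained — a covariate × time term, matching
standard repeated-measures ANCOVA software). With N participants, g
groups and no covariate the error dfs are N − g in both strata; a
retained covariate costs one more in each, so the reference cohort of 38
gives F(1,35)/F(2,35) without and F(1,34)/F(2,34) with the covariate.
Effects use unweighted (type III) marginal means — the sum-coded
intercept test for time — which matches how unbalanced designs are
analysed in the field's standard software. Effect sizes are partial eta
squared, `SS_effect / (SS_effect + SS_error)`, labelled as such. With a
two-level within factor there is nothing for a sphericity correction to
do.

The covariate follows a retention rule: it is kept only if its
between-stratum p-value is below alpha, otherwise the model is refit
without it; retention is therefore a pure function of that p-value, and
the refitted model is identical to a plain mixed ANOVA on the same rows.
Participants missing either phase are removed listwise.

When the interaction reaches the criterion (by default within 0.01 of
alpha, since interactions just beyond the threshold are conventionally
still explored; set `posthoc_band = 0` for strict gating), the post-hoc
battery runs: pairwise between-group pooled-variance t-tests at pre and
at post, and within-group paired t-tests of pre versus post, Holm-adjusted
within each of the three families.

## The synthetic-data generator

The generator is organised around one behavioural parameter,
`sweep_persistence`: the probability that the next fixation continues the
current sweep to the adjacent wall segment. At 1 the walk is a single
ordered sweep around the room (wrapping to the far end after a complete
pass, like a carriage return); at 0 every transition reverses the sweep
direction and jumps to a uniformly chosen segment on the new side.
Starting position follows the same discipline: persistent searchers enter
at a near corner, undisciplined ones start anywhere. This one dial
reproduces the full expert/novice contrast: low versus high transition
entropy, persistent versus antipersistent saccades, and compliant versus
non-compliant search order.

Fixation durations are truncated normal (expert 0.40 ± 0.08 s, novice
0.28 ± 0.08 s, floor 0.1 s — typical search-task values, with experts
showing the longer fixations associated with trained performance).
Centroids are uniform in azimuth within the segment and concentrated near
eye level in elevation (search is mostly horizontal). Saccades get
raised-cosine position profiles — smooth, analytically differentiable,
with exactly one acceleration maximum (onset) and one minimum (offset) —
whose peak velocity scales linearly with amplitude (30 deg/s per degree),
fixing the duration at π/(2·30) ≈ 52 ms. Rendering samples the event
sequence at 120 Hz, adds isotropic Gaussian jitter (default 0.1 degree,
the precision class of consumer HMD eye trackers), and marks blink
windows invalid rather than moving gaze. The final fixation extends to
the end of the trial, matching what the renderer emits after the last
movement. Trials default to 15 s, a plausible single-room search
duration.

`generate_study()` builds a full cohort — by default 12/13/13 analysed
participants in the three arms, 38 in all, with a two-level participant
pool drawn at the reference cohort's 26:40 proportion and 20 trials per
phase — by giving each participant a latent skill that linearly blends the
novice and expert profiles and persists across phases. That persistent
skill is what induces the within-participant correlation a mixed design
relies on. Group × phase effects are injected as additive shifts on named
metrics *after* metric computation, so an injected shift is recovered
exactly in expectation. Metrics are computed directly on the ground-truth
events (no rendering), which keeps a full study affordable; the rendered
path is exercised separately by the detection tests and the end-to-end
discrimination check. `simulate_metric_dataset()` is a further shortcut —
a Gaussian participant-random-intercept model for a single metric — used
for the calibration studies (type-I error over thousands of replicates,
power curves), where scanpath simulation would add nothing.

What the generator does *not* emulate: head movement and vestibular
coupling, smooth pursuit, main-sequence curvature (velocity saturation at
large amplitudes), calibration drift, tracker bias, or any coupling
between search behaviour and the shooting-performance outcomes (those are
drawn from simple independent parametric models and passed through).
Passing tests therefore demonstrate that the measurement chain is
faithful to its definitions and recovers known structure under realistic
noise — not that real recordings are this clean.

## Problem sizes and numerical choices

The test suite and acceptance script choose sizes that keep every run in
the minutes range while leaving Monte-Carlo error well below the margins
being tested: 50 seeds for event-detection recovery, 2000 replicates for
type-I calibration at the reference cell sizes, 20 seed pairs for the
end-to-end expert/novice contrast, exhaustive enumeration of 3-AOI
sequences to length 8 (with random coverage of lengths 9–12) for the
entropy oracle. Entropy's `0·log 0` convention, the inclusive 90-degree
persistence boundary, the lower-numbered-AOI tie-break on shared polygon
edges, the 0.1-degree minimum saccade displacement, and the treatment of
sequences with fewer than two transitions (entropy 0, antipersistence NA)
are all fixed and tested degenerate-input rules.

## Limitations

* The dispersion convention (spatial extent, az-range + el-range) is one
  of several in use; dispersion values are not directly comparable across
  conventions.
* The acceleration-threshold detector is adaptive per trial; with very
  few saccades in a trial the median absolute acceleration shifts and so
  does the effective threshold. Applying it per participant instead is a
  one-line change but is not the default.
* The split-plot ANCOVA assumes the covariate acts at the participant
  level; time-varying covariates are out of scope, as are random-slope
  mixed models, Bayesian re-analyses and equivalence tests.
* Compliance and entropy are defined over the segment alphabet of the
  supplied layout; results are only comparable across rooms whose
  layouts use the same segmentation logic.
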