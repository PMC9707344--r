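---
title: "Measuring neurological screening tests from pose time series: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neurological screening tests from pose time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`neurokin` quantifies four brief motor examinations — finger tapping (FT),
finger-to-finger (FTF), forearm roll (FR) and stand-up-and-walk (SAW) — from
per-frame human-pose keypoints. This vignette explains the measurement model,
the tunable parameters and their defaults, the synthetic data generator used
for validation, and the numerical choices that required a decision.

## Data model

A *recording* holds one or more *pose sequences*, each an N x K x D array of
keypoint coordinates at a fixed frame rate, keyed by skeleton tree (`H2` 2D
hand, `B2` 2D body, `B3` 3D body) and side. Every joint is addressed by name
through a `skeleton_spec`, never by a hard-coded index, so other pose
estimators can be mapped in by supplying a different name-to-index table. On
ingestion of image-coordinate data the y axis is flipped to mathematical y-up
so that "vertical position" and amplitudes increase upward everywhere.
Keypoints below a detector-confidence threshold (default 0.1) are treated as
missing.

## Pre-processing

Three steps, in order:

1. **Truncation** to the frames where the test is actually performed
   (explicit window, supplied by the operator or the file's metadata).
2. **Normalization** by a reference length: the forearm (wrist-elbow
   distance, median over frames, averaged over the two arms) for upper-limb
   tests; the pelvis-neck distance for gait. Taking the per-frame median
   makes the reference robust to sporadic pose errors; averaging the two
   forearms avoids biasing left-right asymmetry features toward either side.
   After this step all coordinates are in body-scaled units and every feature
   is invariant to the subject's distance from the camera.
3. **Smoothing**, per keypoint and axis: linear interpolation across missing
   gaps up to 0.1 s (longer gaps flag the sequence unreliable, the signal to
   exclude a recording), then a running median, then a Savitzky-Golay
   polynomial filter.

Filter windows are configured in seconds and converted to odd frame counts.
Defaults: median 0.05 s (3 frames at 60 fps), Savitzky-Golay 0.117 s
(7 frames) of order 3. The windows are deliberately short. A running median
of width `k` truncates the peak of a sinusoid of frequency `f` by roughly
`1 - cos(pi f (k - 1) / fs)`; at 3 Hz and 60 fps a 5-frame median already
costs ~5% of the amplitude, and the amplitude features read peak-to-trough
excursions directly. The 3-frame median still rejects single-frame pose
spikes — the main artifact it exists for — and the order-3 Savitzky-Golay
window suppresses frame jitter while passing cubic trends (hence first and
second derivatives) essentially unchanged.

## Shared kinematic primitives

**Asymmetry.** `Asym(f_r, f_l) = |f_r - f_l| / (f_r + f_l)`, scale-free in
[0, 1], undefined (NA) when both sides are zero. Asymmetries are evaluated on
the per-side means across cycles.

**Correlation.** The Pearson correlation of two equal-length series; constant
series make it undefined rather than zero.

**Cycle detection.** Local extrema are found with plateau handling, then
pruned: adjacent extremum pairs whose rise/fall is below a fraction (default
0.2) of the signal's global range are removed smallest-first, which enforces
strict min/max alternation; consecutive same-type extrema closer than a
minimum period (default 0.15 s upper limb, 0.3 s gait, covering the 1-4 Hz
physiologic band) are merged, keeping the more extreme one. Signals whose
global range is below an absolute floor (default 0.05 normalized units)
contain no movement — a static limb shows only residual keypoint noise, and
a purely relative prominence rule would happily segment that noise into
"cycles". Cycles run between consecutive boundary extrema (minima by
default; maxima where the movement's natural anchor is the top of the
excursion, as in FTF). The per-cycle period is the boundary spacing;
frequency its reciprocal; amplitude the difference between the cycle's
opposite extremum and its starting boundary value.

**Sub-frame extremum refinement.** Sampled extrema sit up to half a frame off
the true peak, and the detected frame's value is biased by noise order
statistics. Amplitude measurements therefore refine each extremum value by a
local quadratic fit over about 10% of the cycle around the detected frame.
This matters at the fast end of the band: at 3 Hz frame quantization alone
costs ~0.8% of the amplitude.

**Path smoothness.** For an ordered trajectory segment, both coordinates are
fit as quadratic polynomials of the normalized chord-length parameter and
`PS` is the ratio of the actual polyline length to the fitted polyline
length. The ratio is floored at 1: a quadratic curve traversed at the
constant speed the chord-length parameter implies would have to be a straight
line, so the fit cannot reproduce an arbitrary exact quadratic arc perfectly
and the raw ratio can dip a few 1e-4 below 1; such values carry no
information about tremor, which only ever lengthens the numerator.

**Velocity angle.** The direction `atan2(dy/dt, dx/dt)` of a fingertip's
velocity, unwrapped within each cycle. Two numerical hazards required
decisions. First, the direction is undefined wherever the motion stops — at
the turning points of every cycle — and near-zero velocities produce
arbitrary angles; samples below 10% of the cycle's peak speed are masked and
bridged by interpolation, and the velocity components are pre-smoothed with a
short moving average (5 frames) because direction estimates at low speed are
the noisiest. Second, at a true reversal the angle flips by exactly pi with
no preferred sign, so the branch chosen would otherwise be a coin flip from
noise; gaps are classified as reversal vs. slow spot by the sign of the dot
product of mean velocities on the two sides, and reversals advance the angle
by +pi by convention. This makes the angle series reproducible across cycles,
which is exactly what its feature (all-pairs cycle correlation) measures.

**Alignment.** `align_and_cc` searches integer lags for the maximum
correlation. In its default form the series are shifted and only the overlap
is correlated. For gait symmetry the stride is one period of a cyclic signal
and the physiologic right-left offset is half a stride; shifting would
discard exactly half the data at the relevant lag, which in practice hides
waveform differences between a braced and a free knee. Stride comparisons
therefore use circular alignment (rotation), correlating the full length at
every admissible lag.

## Test-specific features

**FT.** Cycles of the thumb-tip-to-index-tip distance per hand; amplitude,
period, frequency, per-cycle maxima of |speed| and |acceleration|, tapping
rate (cycles per second of recording), asymmetries of the per-side means, and
wrist/elbow stability. The stability index is the mean (over frames) of the
right-left joint distance divided by the magnitude of the right joint's
position; as a raw image coordinate that denominator would depend on where
the subject stands in the frame, so the origin is shifted to the pelvis
first, making it a body-anchored quantity.

**FTF.** Cycles are segmented on the vertical coordinate of the mid-index
joint of the *dominant* hand (the one with the larger vertical excursion) and
both hands are sliced on the same boundaries — the test is bimanual and the
cycle definition ("highest to lowest and back") does not say which hand
anchors it. Each cycle splits at its lowest point into two half-cycles, per
which average speed (path length over duration) and path smoothness are
computed. Mirror symmetries are `S_x = CC(x_l, -x_r)` and
`S_y = CC(y_l, -y_r)` of the whole trajectories. The velocity-angle series of
each cycle is resampled to a common length (100) and all cycle pairs are
correlated; the mean and SD summarize cycle-to-cycle consistency.

**FR.** Cycles of each wrist's vertical coordinate; amplitude is the
per-cycle vertical range, rolling speed is amplitude over half the period,
rolling rate is cycles per second, plus period, speed/acceleration maxima,
asymmetries and elbow stability.

**SAW.** The smoothed global pelvis track is segmented by velocity
thresholding. Differentiating frame-level positions amplifies keypoint noise
far above the thresholds, so velocities are smoothed with a 0.15 s moving
average first. Stand-up starts where pelvis speed first exceeds `v_su`
(default 0.3 units/s), walked back to near-zero speed, and ends when speed
stays below `v_su` for 0.25 s with the pelvis within 5% of its standing
plateau; the duration is the time to stand. Turns are intervals of
|horizontal velocity| below `v_walk` (default 0.2 units/s) lasting at least
0.2 s, bounded on both sides by sustained walking in opposite directions
(sustained means an above-threshold run of at least 0.5 s — isolated noise
excursions while standing do not qualify as walking). Walk segments fill the
gaps. Step events are the extrema of the feet-distance series within walk
segments: maxima are step lengths, minima step widths, inter-maximum times
step times. Extrema within 0.2 s of a detected turn are discarded: steps
blur into the turn there, but the detected turn already extends into the
deceleration, so a wider guard begins consuming genuine edge steps. Cadence
and walking speed are per-walk-segment step counts and pelvis path lengths
over duration. For symmetry, each stride (two steps) yields the right and
left knee-angle series — the angle at the knee between the knee-to-hip and
knee-to-foot vectors — resampled to 100 points and circularly aligned within
half a stride; the same procedure on the feet's horizontal positions gives
step symmetry.

## Classification

Features are assembled one row per recording. Cross-validation is either
video-wise (stratified by label) or subject-wise (whole subjects per fold; 20
subjects give the 16/4 train/test split). Median imputation and z-scoring are
fitted on training folds only; a canary test (a feature equal to the label,
then neutralized in test folds only) verifies there is no leakage. Models:
random forest (500 trees), a gradient boosting machine and XGBoost (200
rounds, depth 3, learning rate 0.1; the latter with row/column subsampling),
ridge logistic regression (penalty 1/n), RBF-SVM (cost 1, gamma = 1/d on
standardized features) and a single-hidden-layer MLP (64 units). Metrics
(accuracy, precision, recall, specificity, F1, AUC, average precision;
positive class = abnormal) are averaged over folds. PCA projections fix each
component's sign by its largest-magnitude loading; random-forest Gini
importances are normalized to sum to one.

The device-distance analysis uses each subject's four recordings (normal and
abnormal on each of two devices): per feature, the two intra-class
cross-device distances (A-A, N-N) and the averaged cross-label distances
(N-A) are normalized by the maximum N-A across subjects. Robustness to the
capture device shows as intra-class mass near zero.

## The synthetic generator

The generator reproduces the study conditions under which such tests are
recorded: 15 s upper-limb tests and a 45 s SAW at 60 fps, with isotropic
keypoint noise of 1% of the reference length. Impairment presets quantify
physical manipulations as parameter changes: FT, one hand's amplitude x0.4
and frequency x0.6 (a rubber band restricting the fingers); FR, both
frequencies x0.6 and one radius x0.5 (a wrist brace); FTF, a 6 Hz tremor of
0.05 units perpendicular to the finger path; SAW, the braced knee's flexion
capped at half its range with step length x0.7. Three modelling details
matter for validity:

* The FT fingertip separation keeps a small contact gap (0.05 units):
  fingertip keypoints sit on the finger pads and never coincide, and a zero
  true separation would bias the measured (noisy, non-negative) distance
  upward at contact.
* The synthetic tremor's phase drifts as a random walk. Physiological tremor
  is quasi-periodic; a tremor phase-locked to the movement cycle would be
  perfectly reproducible across cycles and invisible to the cycle-consistency
  features.
* The knee brace caps the flexion profile and widens/delays the swing bump
  rather than merely scaling it: correlation-based symmetry is
  scale-invariant, so a pure amplitude scaling would be (correctly) invisible
  to it; a rigid brace distorts the waveform, and so does the model.

Cohorts mirror the study design: each subject performs the test normally and
impaired, each captured on two devices (four recordings per subject), with
per-subject lognormal random effects (sd 0.1) on speed and amplitude applied
to both conditions — the impairment is relative to the subject's own
baseline — and smaller per-device jitter (sd 0.02).

The generator does *not* emulate pose-estimator failure modes beyond
isotropic jitter and missing keypoints: no occlusion streaks, no left-right
identity swaps, no view-dependent foreshortening, no rolling-shutter or
compression artifacts, and its kinematics are stylized (sinusoidal openings,
exact antiphase gait). Passing tests therefore demonstrate that the feature
definitions measure what they claim on well-posed input and that the pipeline
is robust to camera distance, translation, mirroring and moderate noise —
not that classification accuracy on real clinical video will match the
synthetic numbers.

## Problem sizes and determinism

The validation suite recovers commanded parameters over a 3x3 grid of
frequency (1-3 Hz) and amplitude (0.5-1.5 units), checks oracle equivalence
of extrema-based frequency against the FFT on 50 seeded signals, and runs
end-to-end classification on 20-subject cohorts (80 recordings per test) —
sizes chosen to exercise every code path at comfortable statistical margins
while keeping a full run in a few minutes. Every stochastic step is seeded:
identical seeds reproduce recordings, features, fold assignments and reports
bit-identically.

## Known limitations

* Gait parameters are in body-scaled units, not meters; absolute-unit gait
  requires calibration the pose input does not carry.
* The stand-up end ("full standing") is operationalized as a speed drop plus
  a 5% height plateau criterion; other definitions shift time-to-stand by up
  to ~0.1 s.
* Step events come from feet-distance extrema only; heel-strike/toe-off
  events are not detected.
* The left/right labels of the pose input are trusted as given; no
  re-identification is attempted.
* Severity grading is out of scope: labels are binary normal/abnormal.
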