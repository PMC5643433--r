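---
title: "Methods: oculomotor and vital-sign analysis for VR stimulation studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oculomotor and vital-sign analysis for VR stimulation studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuvr)
```

## The setting

`icuvr` implements the analysis pipeline of a head-mounted-display (HMD)
virtual-reality stimulation protocol for intensive-care settings: participants
lie in an ICU bed and watch three five-minute nature videos through an HMD
with a built-in 60 Hz eye tracker, while a bedside monitor records heart
frequency (HF, beats/min), mean arterial pressure (MAP, mmHg), respiratory
frequency (RF, breaths/min) and oxygen saturation (SpO2, %). A visual target
is superimposed at the beginning, middle and end of each video; afterwards a
17-item questionnaire (1–5 rating scale) measures usability, cybersickness,
immersion, presence and related constructs.

The scientific questions the pipeline answers are: (1) do vital signs decline
over the stimulation (a relaxing effect), and does the decline differ between
participants; (2) does the visual target change oculomotor behaviour
(processing vs search); (3) are the questionnaire scales significantly above
or below the scale midpoint of 2.5?

Raw recordings from such studies are typically not shareable, so the package
ships synthetic-data generators that emulate the statistical structure of
every stream with full ground truth. All recovery and property tests run
against those generators; what they demonstrate is that the pipeline's
*algorithms* are correct at the study's operating conditions, not that any
particular clinical dataset behaves like the simulation.

## Eye-image processing

Eyes-closed frames must be excluded before gaze analysis. The chain is

1. **denoise**: Gaussian filter (sigma = 0.5 px) then an 8 x 8 median filter.
   An even-sized window has no central pixel; we use offsets −3..+4 around the
   target pixel with replicated borders, and average the two central order
   statistics. This convention shifts edges by about half a pixel, well inside
   the 2 px centre tolerance used downstream.
2. **edges**: Canny operator — Sobel gradients, non-maximum suppression with
   bilinear interpolation of the gradient magnitude along the gradient
   direction (the interpolated variant keeps thinned rings 8-connected),
   hysteresis with `low = 0.4 * high`. The operator's thresholds are not part
   of the protocol definition, so by default `high` is derived per frame by
   Otsu's method on the gradient-magnitude histogram, with an absolute floor
   (`canny_min_gradient`, default 20 intensity units) so a featureless
   closed-lid frame does not promote sensor noise to edges. Fixed thresholds
   can be supplied instead.
3. **morphology**: connected components (8-connectivity) with fewer than 50
   pixels are removed; a component of exactly 50 pixels is retained ("fewer
   than 50" is strict).
4. **pupil detection**: a circular Hough transform over a radius grid
   (default 10–80 px, step 1). Every edge pixel votes along the circle of
   candidate centres; the score of a candidate is the best accumulator cell
   normalised by the circle circumference, so a complete one-pixel ring
   scores near 1. A circle is accepted when the score reaches 0.3 of the
   perfect-circle score — a concrete, testable rule for a decision the
   protocol leaves open; the frame is classified eyes-closed exactly when no
   circle is accepted.

The 8 x 8 median filter, the 8-connected labeling and the Hough accumulator
are implemented in C++ within the package; no installed R imaging package
provides an even-window median, 8-connected labeling, Canny or a circular
Hough transform (the Gaussian filter and Otsu threshold come from EBImage).

On the synthetic frame generator (dark disc on a brighter background,
uniform lid for closures, additive Gaussian noise up to SD 10), the chain
recovers centres within 2 px and radii within 10%, and classifies closure
with 100% accuracy across 200 frames — the generator has none of the
eyelash occlusion, specular glints or partial lids of real eye cameras, so
these figures are upper bounds on real-data performance.

## Gaze events and windowed features

Gaze is resampled to a uniform 60 Hz grid (linear interpolation; a resampled
point is valid only if both bracketing inputs are valid). Runs of more than
20 consecutive invalid frames (0.33 s) are removed — strictly more, a run of
exactly 20 is retained and linearly interpolated through. Deleted runs leave
timestamp gaps; fixation windows never span a gap larger than `max_gap_s`
(default 0.1 s).

Fixations are detected with the dispersion-threshold (I-DT) algorithm:
a window grows while its dispersion, `(max x − min x) + (max y − min y)`,
stays within 2 degrees, and is emitted as a fixation when it spans at least
100 ms (inclusive: a 100 ms stable cluster is a fixation, a 99 ms cluster is
not). Inter-fixation intervals become saccade events; their amplitude is the
Euclidean distance between the flanking fixation centroids, robust to
intra-saccade noise, and their duration is the interval length (degenerate
back-to-back intervals are assigned one sample period). The implementation
is the classic window-growing formulation in C++, and the test suite checks
it against an independent brute-force oracle that recomputes dispersion from
scratch at every step.

Four features are computed on a 60 s moving window (n − 30 s to n + 30 s)
with a configurable step (1/60 s by default): fixation duration (total
fixation time per second of window coverage, ms/s), fixations per second,
mean saccade amplitude (deg; missing when the window holds no saccade), and
the fixation/saccade ratio. The ratio is defined as total fixation time over
total saccade time in the window — a duration ratio, chosen because the
quantity is described in the field as the balance between information
processing and search activity; windows without saccade time emit a missing
value rather than an arbitrary number. Windows are truncated at trace
boundaries and normalised by their actual coverage, which avoids discarding
30 s at each end at the cost of noisier edge windows.

## The gaze generator

The generator alternates fixations (centroid plus isotropic Gaussian jitter)
with "exploration" intervals in which gaze travels at constant speed
(30 deg/s) along piecewise-straight legs, turning 30–120 degrees at leg
boundaries. Three geometric constraints make the ground truth recoverable by
I-DT and were chosen deliberately:

- exploration speed must exceed 20 deg/s so that no 100 ms span of travel
  stays within the 2-degree dispersion criterion;
- legs have a 0.25 s minimum duration so no 100 ms span contains two turns
  (two quick turns can fold the path inside the criterion);
- within-fixation jitter defaults to SD 0.15 degrees. At 60 Hz the expected
  dispersion of a 200 ms window grows like ~6.4 sigma, so an SD of
  0.3 degrees would put typical fixations right at the 2-degree criterion
  and split them; 0.15 keeps typical dispersion near 1 degree, comparable to
  the within-fixation precision of a consumer HMD tracker whose absolute
  accuracy is 0.5–1 degree.

Target-present epochs (20 s at the beginning, middle and end of each 300 s
video) lengthen fixations (mean 290 vs 210 ms) and shorten exploration
(mean 0.3 vs 1.0 s), so fixation counts and durations rise and the net gaze
shift between fixations falls — the direction of the target effects the
models are meant to detect. The absent-state defaults put the pooled
windowed features near free-viewing values for dynamic natural scenes in a
wide field of view (~0.8 fixations/s, ~170 ms/s fixation time, ~14 degree
shifts). Blinks are short invalid gaps (well under the 20-frame limit) plus
occasional long closures (0.6–1.5 s) that exercise the gap-removal rule.

What the generator does not emulate: smooth pursuit of moving scene content,
head-movement compensation (the HMD is head-fixed), tracker dropout bursts,
and any dependence of blink rate on the stimulus.

## Vital signs

Raw vitals are aggregated per participant to two-minute medians (median of
the samples in the preceding 120 s; the even-count median is the midpoint of
the two central values; empty bins propagate missing values). Each video
then contributes three analysis points — begin, middle, end — by assigning
the median record nearest in time to the video's 0%, 50% and 100% marks,
ties broken toward the earlier record; only records inside the video's span
are candidates, so no point borrows data across videos. Whether the original
protocol used nearest, mean or interpolated values is not documented;
nearest assignment was chosen because it is reproducible, monotone, and
preserves the median's robustness. The analysis grid carries
`time_index = 3 (video − 1) + position`.

The vitals generator draws, per participant and signal,
`value = baseline + b0 + (beta_time + b1 + beta_age_time * (age − mean age)) * k + noise`
with `(b0, b1)` bivariate normal (SDs and correlation configurable). A
negative intercept–slope correlation encodes "participants with higher
baselines relax faster". SpO2 has a zero time slope by default — it is a
safety measure expected to stay constant — and is clipped to [0, 100]. The
within-participant noise SDs (HF 2, MAP 3, RF 1.5, SpO2 0.5) are plain
configuration values chosen to look like two-minute-median vital signs;
nothing in the protocol pins them down, so they are stated here and in
`vital_truth_params()` rather than presented as estimates.

## Mixed models

All models are linear mixed-effects models fitted by maximum likelihood
(lme4, bobyqa optimizer), so nested models are comparable by likelihood
ratio. For each vital sign the package fits a three-rung ladder with time
and video type as fixed effects:

1. random participant intercept;
2. plus an uncorrelated random time slope;
3. intercepts and slopes correlated.

Each extension is kept only if its likelihood-ratio test against the
previous rung is significant at alpha = 0.05; the correlation rung is only
tested when the slope rung survives. These tests put a variance component on
the boundary of its parameter space, where the naive chi-squared reference
is conservative; the package uses the naive reference and documents the
caveat rather than mixing chi-squared distributions. Fixed-effect tests are
conditional t-tests with residual degrees of freedom (`n_obs − rank(X)`);
the df method is recorded in the fit metadata (`df_method = "residual"`)
because reported t(df) values depend on it and other choices (e.g.
Satterthwaite) are common. Questionnaire scales are added to the chosen
model one at a time — eight scales against 37 participants would be heavily
collinear if entered jointly — and their p-values are Holm-adjusted across
scales.

For the windowed oculomotor features, where the sample size is enormous and
p-values inflate, effect sizes replace significance: eight models per
feature (zero; full = time + target + video type; three single-predictor;
three leave-one-out), each with Nakagawa marginal and conditional R².
The marginal R² is `var(fixed predictions) / (var(fixed) + sum of random
variances + residual variance)`; the conditional R² credits the random
effects too. Random-slope terms contribute their mean observation-level
variance `mean_i(z_i' Sigma z_i)`. The increase in explained variance
credited to a predictor is `R²m(full) − R²m(full without it)`. A zero model
has exactly zero marginal R²; `0 ≤ R²m ≤ R²c ≤ 1` is asserted on every fit.
The windowed features are strongly autocorrelated (adjacent windows share
59/60 of their data); the models ignore this serial dependence, which is
another reason to read the R² values, not the p-values — a limitation, not
a modelling claim.

## Questionnaire

The 17 items map onto eight scales (usability 7–9; sickness 10–12, 15;
oculomotor problems 13–14; disorientation 16; immersion 1; presence 2;
realism 5; involvement 3–4, 6; item 17, favourite video, belongs to no
scale). A scale score is the unweighted mean of its items. Each scale is
tested one-sided against the rating-scale midpoint,
`t = (mean − 2.5) / (sd / sqrt(n))` with n − 1 df, on the side the scale is
expected on (usability, immersion, presence, realism, involvement above;
sickness, oculomotor problems, disorientation below). `t` is antisymmetric
under reflection of the scores about 2.5 and invariant under rescaling of
the deviations, both asserted as properties. One published reference row for
the sickness scale (M = 1.16, SD = 0.4, n = 37) prints a t of −18.10 that is
inconsistent with its own summary statistics under this formula, which gives
−20.38; the package reports the recomputed value and flags the discrepancy
rather than reconciling it by guessing.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at reduced but
structurally faithful sizes, chosen as the smallest scales at which every
property is comfortably testable: 100 random traces of up to 2,000 samples
for the I-DT/oracle comparison; 200 synthetic eye frames (120 x 110 px,
radii 15–40 px, noise SD 0–10) for pupil recovery; 50 replicates of 50
participants for slope recovery and model selection; 3 participants x 3
five-minute videos at a 0.5 s feature step (~5,400 windows) for the
effect-size ordering; 200 groups x 30 observations for the constructed
variance partition. Floating-point comparisons in the I-DT window logic use
a 1e-9 slack so that a span of exactly 100 ms (6 frames at 60 Hz) counts as
inclusive; nearest-record ties in the vitals grid break toward the earlier
record; singular mixed-model fits (a variance component at zero) are
flagged but returned.

## Known limitations

- The closure criterion (no accepted Hough circle) and its 0.3 score
  threshold are this package's concrete rule for a step that protocols
  rarely specify; both are configurable.
- The naive chi-squared reference for boundary likelihood-ratio tests is
  conservative; model 2/3 selection rates should be read with that in mind.
- Serial dependence of the windowed features is not modelled.
- The synthetic generators emulate the statistical structure of the streams,
  not their physiology; passing recovery tests bounds algorithmic error, not
  measurement error.
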