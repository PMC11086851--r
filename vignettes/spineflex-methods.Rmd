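---
title: "Classifying low back pain phenotypes from spine flexion kinematics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying low back pain phenotypes from spine flexion kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineflex)
```

## The problem

Non-specific low back pain with a movement component is clinically split
into two phenotypes that call for different exercise strategies:
*movement impairment* (MI), where spinal movement is restricted by pain,
and *motor control impairment* (MCI), where movement is unrestricted but
painful. Expert classification is reliable but takes extensive training,
which limits access to tailored management. This package implements a
pipeline that predicts the MI/MCI label from the kinematics of repeated
forward spine flexion as seen by a single video camera — concretely, from
the per-frame 2-D positions of three pose-estimation keypoints (ankle,
hip, neck) — optionally combined with seven routine patient-reported
outcome measures (PROMs).

## The spine flexion angle

For each frame the angle at the hip between the hip–neck and hip–ankle
segments is obtained by the law of cosines from the three pairwise
Euclidean distances (hip–neck $hn$, ankle–hip $ah$, ankle–neck $an$):

$$\theta = \arccos\!\left(\frac{hn^2 + ah^2 - an^2}{2\,hn\,ah}\right),$$

converted to degrees. Standing is $\approx 180^\circ$; flexion decreases
$\theta$. Because only distance ratios enter, $\theta$ is invariant to
uniform scaling, rotation, translation and reflection of the keypoints —
pixel units and y-down image coordinates need no calibration, and the same
formula applies unchanged to 3-D motion-capture coordinates. The arccos
argument is clamped to $[-1, 1]$; for nearly collinear standing postures
the argument can drift a hair above 1 in floating point, and clamping maps
these to exactly $180^\circ$. Coincident hip/neck or ankle/hip points are
rejected as degenerate geometry rather than silently producing NaN.

## Smoothing

The raw waveform is smoothed with a centred moving average of
`window_frames = 30` frames (1 s at 30 fps). Two choices here are open and
worth stating:

* **Edge handling.** Where the full window does not fit, the window
  shrinks symmetrically around the output frame. A trailing window would
  have been simpler but introduces a phase lag of half a window, which
  would bias every detected minimum by ~0.5 s; the symmetric shrink keeps
  minima in place at the cost of less smoothing in the first and last
  half second (which the pipeline discards as partial repetitions
  anyway).
* **Even windows.** A 30-frame centred window cannot be perfectly
  symmetric; the interior window is $[i-15, i+14]$, which shifts a linear
  trend by half a frame's slope. This is negligible at 30 fps and zero
  for odd windows.

One consequence of 1 s smoothing deserves emphasis: a moving average
attenuates the flexion oscillation by roughly
$\mathrm{sinc}(W/T_\mathrm{move})$, where $W$ is the window and
$T_\mathrm{move}$ the moving part of the repetition period. For fast
repetitions (2–2.5 s) the smoothed trough sits 10–15° *above* the true
deepest angle. Smoothed-waveform features therefore measure properties of
the smoothed signal, and any ground-truth comparison (as in the package's
own parameter-recovery tests) must smooth the reference profile the same
way before comparing.

## Repetition segmentation

Full-flexion minima are found by negating the smoothed waveform and
applying continuous-wavelet-transform ridge-line peak detection (ricker
wavelet, per-scale relative maxima linked into ridge lines, filtered by
ridge length and signal-to-noise ratio — the Du et al. 2006 algorithm).
The implementation is a direct R port of the reference algorithm in
`find_peaks_cwt`.

* **Wavelet widths** default to 0.25–1.5 s (7–45 frames at 30 fps),
  spanning the expected width of the flexion *trough*, which is roughly
  half a repetition period. This is the parameter that matters most:
  widths much longer than the repetition period make the coarse scales
  see groups of repetitions rather than individual troughs, ridge lines
  then anchor on those merged maxima, and detection collapses to every
  second or third repetition. Validation against the simulator's ground
  truth shows the default range detects every repetition exactly for
  cadences from 1.6 s to beyond 5.5 s per repetition, while a 0.5–3 s
  range misses most minima below ~2.2 s cadence.
* Detected positions are refined to the local minimum of the smoothed
  waveform within ±0.5 s, minima in the first/last 0.5 s are discarded as
  partial repetitions, and minima closer than 1 s are merged keeping the
  deeper one.
* Fewer than two surviving minima raises a typed
  `spineflex_insufficient_repetitions` error: repetition features are
  undefined in that case, and downstream code can catch the condition.

## Features

Nine kinematic features are computed in a fixed canonical order (subset
masks index into it): waveform variance, standard deviation, minimum
(full spine flexion angle), range, maximum (spine standing angle);
repetition-time mean and variance (frames between consecutive minima);
depth variance (variance of the angle at the minima); and movement
stability (second-half range minus first-half range, positive when the
excursion grew across the trial; the halves split at
$\lfloor n/2 \rfloor$). All variances are sample variances
(denominator $n-1$), applied uniformly. Repetition times stay in frames;
only reports convert to seconds.

The seven PROMs (VAS 0–100, ODI 0–100, TSK 17–68, PCS 0–52, PSEQ 0–60,
CSQ 0–70, SBT 0–9) are typed, range-validated inputs — no imputation, no
scoring of raw questionnaire items. The CSQ total range 0–70 assumes 14
items scored 0–5; the bound is configurable since totalling conventions
vary. SBT enters the model as its 0–9 total (its low/medium/high band is
derived for reporting only).

## The classifier

Each feature family is a *stream*: batch normalisation → a square linear
layer (as many outputs as inputs) → ReLU. Streams are concatenated and a
final linear layer with sigmoid yields $P(\mathrm{MI})$; the label is MI
iff the probability reaches the decision threshold (default 0.5, required
by training with binary cross-entropy). A stream whose mask has no active
features is dropped entirely, which is how angle-only and PROMs-only
models arise.

Defaults, with reasons:

* **Full-batch gradient descent** (`batch_size = 0`), learning rate 0.05,
  500 epochs. At cohort sizes near 100 a full batch makes every gradient
  exact and training bit-reproducible under the seed; mini-batches are
  available but buy nothing here.
* **Initialisation** uniform in $\pm 1/\sqrt{d}$ per layer, seeded.
* **Batch normalisation**: batch statistics during training; running
  statistics (momentum 0.1, unbiased variance, $\varepsilon = 10^{-5}$)
  at inference.
* **No bias on the stream linear layer.** Batch normalisation's learnable
  shift $\beta$ already provides exactly this degree of freedom, so a
  linear-layer bias after BN is redundant parametrisation. It is also
  actively harmful at the tiny widths used here: with one active feature,
  the redundant bias is the main route by which gradient descent drives
  *all* pre-activations negative — the absorbing "dying ReLU" state, from
  which no learning rate or epoch budget recovers (about 40% of random
  inits die on perfectly separable one-feature data with the bias; about
  2% without it). The final layer keeps its bias (it feeds a sigmoid, not
  a ReLU, and carries the class base rate).
* **Seeded restarts** (`max_restarts = 3`): if the final epoch's loss is
  no better than the base-rate entropy — the signature of a dead stream —
  training restarts from a deterministically derived seed. This is the
  same pattern as multiple starts in k-means; identical seeds still give
  identical models.

Because batch normalisation standardises each feature from the data,
model output is invariant to affine rescaling of any input feature (up to
the $\varepsilon$ stabiliser, which is far below decision resolution).

## Evaluation protocol

* **Pooled stratified 5-fold cross-validation.** Folds are assigned by a
  single continuous round-robin over per-class shuffled samples, so class
  proportions per fold differ by at most one and overall fold sizes are
  as equal as possible (17/17/17/16/16 at $n = 83$). Held-out predictions
  from all folds are pooled into one confusion matrix and metrics are
  computed from the pooled counts — pooling has lower variance than
  averaging per-fold metrics at this sample size and produces honest
  denominators when $n$ is not divisible by $k$. Every record is tested
  exactly once.
* **Metrics.** Accuracy $(TP+TN)/n$, sensitivity $TP/(TP+FN)$ (MI
  detection), specificity $TN/(TN+FP)$ (MCI detection), F1
  $= 2PR/(P+R)$. Metrics with zero denominators are `NA` and flagged, not
  silently zeroed. Values stay unrounded internally; reports round
  percentages to 2 decimals and F1 to 3.
* **Exhaustive subset search** evaluates all $2^9 = 512$ angle and
  $2^7 = 128$ PROM subsets by cross-validation with a per-subset seed
  derived from the mask (results are independent of evaluation order).
  The empty subset is enumerated — so the counts are the full powersets —
  but recorded as an untrained majority-class predictor and never ranked
  optimal. Ranking is by F1, ties broken by accuracy, then by fewer
  features (smallest adequate model).
* **Ablation** re-runs CV once per active feature with that feature
  removed and reports the accuracy drop in percentage points.
* **Reconstruction of printed metric tables.**
  `solve_confusion_matrix()` enumerates all integer confusion matrices at
  a given $n$ whose metrics round to stated 2-decimal percentages —
  useful for auditing published tables. It flags non-uniqueness, and
  genuine inconsistency (some printed metric triples admit no integer
  matrix at all at the stated $n$).

## Chance-level significance

With $n$ evaluated samples and $c$ equiprobable classes, the number of
correct predictions of a guessing classifier is binomial. The minimum
significant accuracy is $St(\alpha) = \mathrm{binoinv}(1-\alpha, n, 1/c)
\cdot 100/n$ — the $1-\alpha$ binomial quantile as a percentage — and the
package also reports the exact exceedance probability $P(z)$ of reaching
the quantile count by chance. Two subtleties:

* $St$ depends strongly on which $n$ is used: at $\alpha = 0.001$ it is
  87.5% for a per-fold test set of 16 but only ~66% for the pooled 83.
  Reports therefore state both.
* By the quantile's definition $P(z)$ can slightly exceed $\alpha$
  (e.g. $P(14\,|\,n{=}16) = 137/65536 \approx 0.0021$); the accuracy one
  count higher is below $\alpha$. The package exposes the exact value
  rather than rounding the claim.
* When validating the threshold against a Monte-Carlo null, note that for
  some $n$ the exact CDF at the quantile lies within $\sim 3\times10^{-5}$
  of $1-\alpha$; resolving the quantile empirically then needs on the
  order of $10^7$ replicates, which is what the package's tests use.

## Motion-capture criterion validation

The same angle is computed from a 3-D marker set: neck → C7; hip → the
centroid of the four pelvic markers (the symmetric reading of "midpoint
of the pelvic markers", which names ASIS and PSIS without laterality);
ankle → a *virtual ankle*, the L4 marker with its vertical coordinate set
to zero (only the vertical coordinate — the horizontal/depth coordinates
are kept). Distances are 3-D Euclidean; no sagittal projection is applied
(none is needed: with planar motion the two agree exactly, and projection
would add a camera-axis convention). The 120 Hz mocap waveform is
linearly interpolated onto the 30 fps grid — at an exact 4:1 rate ratio
the retained samples coincide with mocap samples, so interpolation and
decimation are identical here — and compared by mean squared error.
The MSE is reported in degrees²; where a criterion value is quoted "in
degrees" its unit is ambiguous between degrees and degrees², and this
package always states degrees².

## The synthetic cohort

The simulator defines the study conditions under which the pipeline is
tested: 41 MI and 42 MCI participants, each performing 8–10 flexion
repetitions at 30 fps from a standing angle of ~172° (SD 3°). Class
structure: MI flexes less deeply (full-flexion angle mean 120°, SD 8°)
and more slowly (period 3.5 s, SD 0.5 s); MCI flexes deeper (85°, SD 8°)
and faster (2.5 s, SD 0.4 s). Each repetition is a raised-cosine
excursion from standing to a per-repetition depth (within-trial jitter SD
2°) with a configurable standing dwell (15% of the period) — chosen over
a pure sinusoid so that dwell between repetitions is representable.
Keypoints come from a planar two-segment model (ankle at the origin, hip
vertically above it, trunk of fixed length at the flexion angle) plus
isotropic pixel noise (SD 1 px). PROMs are class-conditional truncated
normals rounded to integers, heavily overlapping for all measures except
SBT (MI mean 3, MCI mean 6, SD 1.5), reflecting a chronic cohort with
acute/severe cases excluded. The mocap twin realises the same latent
angle profile at 120 Hz with C7 on the trunk, four pelvic markers
centred on the hip, and L4 on the vertical ankle–hip axis at positive
height so the virtual-ankle construction is genuinely exercised.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: pose-estimator noise is neither isotropic nor
independent across frames (real errors are structured and
occlusion-driven); the trunk is a single rigid segment, so lumbar versus
hip contributions to flexion are not distinguishable; the standing
segment is exactly vertical; PROMs are drawn independently, ignoring
their real correlations; and class differences are injected only through
depth, cadence and SBT, so feature-selection results on synthetic
cohorts describe the simulator's structure, not clinical reality.

## Problem sizes and numerical choices

The test suite runs the full pipeline on the default 83-participant
cohort, parameter recovery on 10 noise-free trials, the exhaustive
512-subset angle search at 100 training epochs (the subset ranking is
about enumeration and relative ordering; the reduced budget leaves the
ordering of informative versus uninformative subsets intact), the
128-subset PROM search at 40 epochs, and 3 label-shuffled null
replicates. Oracle tolerances: $10^{-9}$° for closed-form angle
identities, $10^{-6}$° for generator round-trips, 0.5° / 5 frames for
post-smoothing parameter recovery, and the binomial $2\sigma$ band for
null accuracies.

## Known limitations

* Single sagittal angle, single task: multi-segment spine angles,
  extension/side-flexion tasks and multi-directional phenotypes are out
  of scope.
* The classifier is intentionally tiny; no calibration of the output
  probabilities is attempted, and the decision threshold is fixed at
  0.5 by default.
* The subset search applies no multiple-comparison correction across the
  640 evaluated subsets; its ranking is exploratory.
* COCO-format ingestion derives the three landmarks from shoulder, hip
  and ankle midpoints with a per-side confidence fallback; it does not
  run or validate any pose estimator.
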