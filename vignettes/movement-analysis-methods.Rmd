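---
title: "Methods: depth-video movement analysis for iRBD screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depth-video movement analysis for iRBD screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbdvideo)
```

## The problem

Isolated REM sleep behavior disorder (iRBD) is an early-stage
alpha-synucleinopathy in which the physiological muscle atonia of REM
sleep fails, so patients move — often in brief jerks — while dreaming.
Confirming the diagnosis requires video-polysomnography and laborious
manual review. A ceiling-mounted time-of-flight depth camera offers an
appealing alternative signal: each frame is a per-pixel distance map of
the bed surface, so body movement appears as frame-to-frame depth
change, robustly and without illumination.

`rbdvideo` implements the full analysis chain for this setting:

1. **Motion detection** (`detect_motion()`): per-region binary motion
   traces from a depth sequence.
2. **Event features** (`movement_features()`): duration-binned movement
   events during REM sleep, summarised per subject as a movement *rate*
   and movement *ratio*.
3. **Classification** (`run_cv()`): ridge-regularized logistic
   regression over region/bin feature sets under repeated stratified
   cross-validation, with subgroup analyses.
4. **Statistics** (`mann_whitney_u()`, `wilcoxon_signed_rank()`,
   `benjamini_hochberg()`, `spearman_corr()`, `demographic_table()`,
   `compare_classifiers()`).
5. A **synthetic scene and cohort generator** so that every stage is
   testable end to end without any clinical recording.

## Movement detection

Frames are differenced pairwise; a pixel counts as *changed* when its
depth moved by more than `pixel_delta_mm` (default 10 mm) between
consecutive frames. Changed pixels are counted inside four regions of
interest:

* **lower body** and **upper body** — static, manually drawn polygons;
* **head** and **hands** — dynamic per-frame bounding boxes from an
  external detector, consumed as a track file.

The precedence rule resolves the overlap: when head/hand boxes are
validly detected in a frame, their pixels belong to the head/hands
regions and are removed from the upper-body mask; when the tracker
drops out, those movements fall back to the upper body. Every changed
pixel therefore contributes to exactly one region.

A region's frame is flagged as *movement* when its (filtered)
changed-pixel count reaches `min_area_px` (defaults: 50 px for
upper/lower body, 20 px for head/hands at full 512 × 424 resolution;
all thresholds are configurable because the upstream clinical pipeline
never published its values, and they should be rescaled when working
at reduced resolution).

### Respiration suppression

Breathing moves the chest quasi-periodically (0.15–0.5 Hz) and can
masquerade as upper-body movement. `respiration_suppress()` removes
*narrowband periodic* content from the per-region changed-area signal
while preserving broadband transients: the dominant frequency inside
the band is located by fine-grid periodogram maximisation and a
least-squares harmonic fit (fundamental plus harmonics up to Nyquist)
is subtracted. The harmonic stack matters because thresholded
respiration produces a rectified, clipped waveform whose power sits
well above the fundamental. A moving-average band-stop was considered
and rejected: any filter that attenuates the whole band also removes a
large part of a 1-s movement pulse's spectrum (roughly half its peak),
whereas the harmonic model only removes what is actually periodic. The
implemented contract is: an in-band stationary sinusoid is attenuated
by at least 20 dB, a 1-s rectangular pulse keeps at least 70 % of its
peak (in practice ≥ 95 %), and white noise loses no more than the
band's spectral share of its RMS.

After suppression a 3-point running median removes isolated
single-frame area spikes (`median_window = 3`, configurable). These
arise from depth quantisation jitter at threshold crossings and from
sensor glitches; a genuine movement at the 0.1-s minimum duration spans
three frames at 30 fps and is untouched.

## Events and features

Flagged-frame runs become events; consecutive events of one region are
merged when the inter-movement interval is **at most 1 s** (movements
are separate only when the gap exceeds 1 s). Merged events are
restricted to REM sleep and binned by duration:

| bin | duration |
|---|---|
| short | [0.1, 2) s |
| medium | [2, 15) s |
| long | [15, 300] s |

Durations below 0.1 s or above 300 s are dropped. The printed bin
bounds overlap at 2 and 15 s; assignment here is half-open at those
boundaries (and closed at 300 s) so it is deterministic.

Two conventions were genuinely open and are fixed as follows:

* **REM membership is decided by event onset**, and kept events retain
  their full duration. The onset rule is order-independent and never
  counts an event twice at a REM boundary; clipping rules would
  introduce a dependence on interval bookkeeping that the source
  material does not specify.
* **Merging precedes REM restriction**, so an event fragmented around a
  REM boundary is reassembled before membership is decided.

Per subject, region and bin, two features summarise the events:

* **rate** — events per hour of REM sleep;
* **ratio** — seconds of movement per hour of REM sleep (equivalently
  the REM-time fraction spent moving scaled by 3600, so full occupancy
  equals exactly 3600).

## Classification

Seven predictor configurations are trained per duration bin: each
single region (head, hands, upper body, lower body; 2 predictors —
rate and ratio), head+hands+upper body and head+hands+lower body (6
predictors), and all four regions (8 predictors). Features are
normalized to the training set's 5th and 95th percentiles (mapped to 0
and 1, not clipped outside), and a logistic regression with ridge
penalty is fitted by Newton iterations on

$$\frac{1}{n}\sum_i \ell(y_i, \beta_0 + x_i^\top w) +
\frac{\lambda}{2}\lVert w\rVert^2,$$

with the intercept unpenalized and convergence declared at gradient
max-norm below 1e-8. Evaluation uses 10 runs of stratified 10-fold
cross-validation (run seeds `seed_base + 0:9`); the normalizer and
model are fitted on training folds only, and per-run metrics (accuracy,
F1, sensitivity, specificity, PPV, NPV; positive class iRBD) are
computed on the pooled out-of-fold predictions, then aggregated as
mean ± SD across the 10 runs. Fold-level metrics are retained for
paired comparisons. Undefined ratios (zero denominators) are recorded
as `NA` and excluded from aggregation rather than imputed as 0.

Open choices, fixed here and reported in `cv_result$settings`:

* **`ridge_lambda = 0.01`.** The penalty strength was never published.
  On the *mean* log-likelihood scale used above, a unit penalty is
  equivalent to `n` units on the summed-likelihood scale and collapses
  the model to its intercept for cohorts of this size; 0.01 is
  comparable to the common unit penalty on the summed scale at
  n ≈ 100–200 and leaves percentile-normalized predictors room to act.
* **Stratified folds** — with 53 positives among 181 subjects,
  unstratified folds occasionally lose a class entirely.
* **Decision threshold 0.5** on the predicted probability.

Subgroup performance (`subgroup_metrics()`) restricts the pooled
out-of-fold predictions to iRBD plus one differential-diagnosis
subgroup (e.g. sleep-related breathing disorder, RLS/PLMS, or
insomnia/no-relevant-disorder) without retraining.

## Statistics

Group feature comparisons use Mann–Whitney U (exact when there are no
ties and `n_a n_b ≤ 400`, otherwise a tie-corrected normal
approximation). Paired comparisons of classifier metrics use the
Wilcoxon signed-rank test with an exact null distribution computed by
convolution over tie-averaged ranks for `n ≤ 25` — fold-level metric
values tie frequently, and the usual exact algorithms refuse ties —
with Benjamini–Hochberg control at q = 0.05 within each metric family
(accuracy; F1). Pairing is at the fold level (100 values) by default;
run-level pairing is available. Spearman correlation (average ranks,
t approximation) relates predicted iRBD probability to an external
REM-atonia index where one is available. Demographic tables choose
t tests versus Mann–Whitney by a Shapiro–Wilk gate at α = 0.05 and
compare categorical variables by chi-squared.

## The synthetic generator

Real recordings of this kind are not publicly distributable, so the
package ships a generator with two entry levels.

**Scene level.** `generate_hypnogram()` builds a 30-s-epoch night with
a requested REM fraction in a requested number of contiguous REM
periods. `plant_events()` draws, per region and bin, a homogeneous
Poisson number of events over REM time, placed uniformly inside REM
intervals with a minimum same-region gap above the merge threshold so
ground truth cannot fuse. `render_depth_video()` draws the mattress
plane at `bed_depth`, the body polygons `body_depth_offset` closer to
the camera, a sinusoidal chest oscillation (default 4 mm at 0.25 Hz),
per-pixel Gaussian sensor noise (default σ = 5 mm), and each planted
event as a patch displaced by `event_displacement` (default 50 mm) —
magnitudes plausible for a Kinect-v2-class sensor; none are
calibratable against published movement-amplitude statistics, which do
not exist. During an event the displaced patch alternates between full
and half displacement on consecutive frames: a moving limb changes the
depth map continuously, whereas a statically held offset would be
invisible to frame differencing except at its edges. Head/hand boxes
are emitted per frame with Bernoulli dropouts (`track_dropout_prob`),
emulating the external detector's limited coverage.

**Cohort level.** `sample_cohort_features()` draws per-subject feature
tables directly from per-cell (group × region × bin × feature)
calibration given as median and quartiles: a value is exactly zero with
probability `zero_inflation`, otherwise log-normal with location
`ln(median)` and scale `ln(q75/q25) / (2 × 0.67449)` (quantile
matching). The default calibration `cohort_reference()` encodes the
published group-level medians/IQRs of a 181-subject clinical cohort
(53 iRBD, 128 no-RBD). Degenerate cells need conventions: cells with
`q25 = 0` but positive median use zero inflation 0.3 and match the
upper quartile ratio instead; cells printed as `0 [0, 0]` use zero
inflation 0.9 with a small-magnitude log-normal tail. Cells are drawn
independently by default (no joint distribution was published); an
optional shared per-subject log-normal severity factor can induce
positive cross-cell correlation.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: posture changes and blanket
occlusion, PAP-tube artifacts, non-stationary respiration, correlated
feature structure within subjects, detector box jitter, and any
relationship between the rendered scene statistics and the cohort-level
feature distributions. The classifier results on synthetic cohorts show
that the pipeline recovers the separation implied by the calibration
table, not that the accuracy on a clinical population would match.

## Numerical choices and problem sizes

* Frame `i` covers `[i/fps, (i+1)/fps)`; intervals are half-open
  seconds throughout; hypnogram and video clocks align via
  `start_time`.
* Depth frames are integers in [0, 8000] mm, stored on disk as
  lossless 16-bit grayscale TIFFs plus a `meta.json` sidecar (fps,
  dimensions, start time); round trips are bit-exact.
* The detector reports events one frame longer than the planted truth
  (frame differencing flags both the onset and the offset transition);
  recovery tests allow ±1 frame.
* Ridge fitting uses Newton steps with step-halving; the permutation
  and CV machinery is deterministic given seeds, with the caller's RNG
  state always restored.
* Test and example scenes run at reduced scale — 40–64 px frames,
  10 fps, clips of 2–30 min — chosen so the full suite exercises
  night-scale logic (tens of thousands of frames) at desk-scale cost;
  all conclusions checked there are resolution-independent contracts
  (masks, counts, rates), not image-quality claims.

## Known limitations

* Thresholds are configurable defaults, not values validated against
  manually annotated movements.
* Hands coverage in real recordings is poor (≈ 42 % in the reference
  cohort); the pipeline models dropouts but not systematic biases in
  *which* frames are missed (e.g. during movement).
* The respiration filter assumes approximately stationary breathing
  within an analysis window.
* Whether the upstream pipeline clips event durations at REM
  boundaries, and whether merging crosses the REM/NREM boundary, is
  unknown; the conventions above are this package's own.
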