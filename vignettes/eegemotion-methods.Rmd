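---
title: "Methods: temporal features and boosted classification for EEG emotion recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal features and boosted classification for EEG emotion recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Dimensional models of emotion describe affective states along a pleasantness
axis (valence) and an intensity axis (arousal), each self-reported on a
continuous 1–9 scale, or — for film-clip paradigms — as discrete
positive/negative trial labels. `eegemotion` implements a complete pipeline
for classifying these binarized states from multichannel scalp EEG: signal
conditioning, temporal segmentation, extraction of two time-domain
complexity features, and evaluation of four classifier families under
within-subject and cross-subject protocols.

The package is organized around the benchmark geometries common in this
literature: a within-subject corpus of 32 subjects x 40 one-minute trials
recorded at 128 Hz with 32 EEG channels first in a 40-channel array (8064
samples per trial including a 3-s pre-trial baseline), and a cross-subject
corpus of 10 subjects x 30 labelled trials of roughly four minutes. Because
both real corpora are gated behind registration, the package ships a
synthetic generator that emulates the shapes and the class-conditional
statistics the features respond to; readers for the per-subject file
dialects are provided so the same pipeline runs on real exports.

## Signal conditioning

Conditioning follows the conventional chain for these recordings, every
stage acting independently per trial and channel:

* **Down-sampling** by integer decimation, preceded by an 8th-order
  Butterworth anti-aliasing low-pass at 0.8 x the target Nyquist. 512 Hz
  recordings decimate to 128 Hz (63-s trials: 32256 -> 8064 samples).
* **Band-pass**: 4th-order Butterworth, 4–45 Hz by default. A 0.5–45 Hz
  variant is sometimes quoted for this task; the band is fully
  configurable (`band_low_hz`, `band_high_hz`), and 4–45 Hz is the default
  because theta-through-gamma is where the features discriminate.
* **Notch** at 50 Hz for powerline interference. The quality factor is not
  standardized in this literature; the default Q = 30 (about 1.7 Hz of
  −3 dB width at 50 Hz) rejects the line tone without touching the 45 Hz
  band edge. The design places zeros on the unit circle at the center
  frequency with the pole radius set from the tan-prewarped bandwidth, so
  it stays accurate close to Nyquist.
* **Zero-phase application**: all filters run forward–backward by default
  (`zero_phase = FALSE` gives a single causal pass). Zero-phase filtering
  leaves no group delay, so segment boundaries cut the same physical time
  in every band. Edges are handled by odd-reflection padding of three
  coefficient-lengths with initial conditions matched to the padded
  signal's steady state; the first and last few dozen samples of a trial
  remain implementation-defined, which is one reason the pre-trial trim
  runs after filtering.
* **Trimming and channel selection**: the first 3 s of each trial
  (baseline) are dropped — 8064 -> 7680 samples — and the leading 32
  channels (the scalp EEG) are kept. Selection commutes with the
  per-channel filters, so the implementation selects first to avoid
  filtering channels it will discard.

Whether filtering happens before or after trimming is not standardized;
this implementation filters first (the stages are LTI, so results differ
only at trial edges, and trimming then removes the leading edge).

## Segmentation and labelling

Trials are cut into non-overlapping windows, the unit of feature
extraction and classification. Two modes exist:

* **Fixed duration** (`segment_trials`, default 3 s): 60-s trials at
  128 Hz yield 20 windows of 384 samples; 32 subjects x 40 trials give
  25,600 segments. Remainder samples are dropped, never padded — padding
  would fabricate signal, and the benchmark geometry divides exactly.
* **Fixed count** (`segment_trials_by_count`, default 20): used for
  variable-length labelled trials; each trial is split into 20 equal
  windows of `floor(samples/20)` samples, so the window length is
  per-trial and the feature extractors (which are length-agnostic) see
  comparable inputs. Fixed-count is the default for the cross-subject
  path because it reproduces the 600-segments-per-subject bookkeeping;
  fixed-duration remains available.

Ratings binarize at 4.5: a rating of 4.5 or lower is class 0 (low), above
4.5 is class 1 (high) — the tie goes to class 0, following the common
"4.5 or lower" convention verbatim. Segments inherit their parent trial's
label through the provenance triple (subject, trial, segment); there is no
per-segment re-rating. All provenance indices are zero-based.

## Features

**Differential entropy (DE).** The entropy of a continuous random
variable, estimated per segment and channel from a normalized histogram:

$$h(X) = -\sum_{i=1}^{M} p(x_i)\,\ln p(x_i)\,\Delta x_i,$$

where $p$ is the piecewise-constant density (the histogram normalized to
integrate to 1) and $\Delta x_i$ the bin widths. Empty bins contribute
zero (the limit $p \ln p \to 0$), so the sum is finite; the value can be
negative. The automatic bin rule takes the larger of the Sturges and
Freedman–Diaconis counts on equal-width bins over $[\min x, \max x]$,
which adapts to both sample size and dispersion; a fixed bin count is
available for reproducibility studies. Natural logarithms throughout, so
for Gaussian data the estimator targets the closed form
$h = \tfrac12 \ln(2\pi e \sigma^2)$ — the anchor the test suite checks at
$\sigma^2 \in \{0.25, 1, 4\}$ within 0.05 nats at n = 50,000. Tree
ensembles are invariant to the log base; distance-based classifiers are
not, which is why the base is fixed rather than configurable.

**Higuchi's fractal dimension (HFD).** A complexity measure estimated
from the scaling of curve length with sampling interval. For start offset
$i$ and interval $j$, the normalized curve length of the subsampled
series $X(i), X(i+j), X(i+2j), \dots$ is

$$L_i(j) = \Bigl[\sum_{m=1}^{\lfloor (N-i)/j \rfloor}
  |X(i+mj) - X(i+(m-1)j)|\Bigr]\,
  \frac{N-1}{\lfloor (N-i)/j \rfloor\, j},$$

and the mean curve length per interval applies the curvilinear-time
correction at the averaging stage,
$L(j) = \frac{1}{j}\,\overline{L_i(j)}$, the canonical formulation: with
the correction inside the average a smooth curve scales as $L(j) \propto
j^{-1}$ and uncorrelated noise as $L(j) \propto j^{-2}$. The dimension is
the least-squares slope of $\ln L(j)$ against $\ln(1/j)$ over
$j = 1..k_{max}$, reported as computed (no clamping). Printed forms of
these equations in the applied literature sometimes drop the correction
or the log–log regression; the package implements the canonical
estimator, which is what reproduces the anchors the suite checks: a ramp
at $1.0 \pm 0.05$, white noise at $2.0 \pm 0.15$, and exact agreement
(1e-10) with a naive triple-loop reference.

$k_{max}$ is not standardized; the default 10 satisfies
$k_{max} < N/2$ with a wide margin for 384-sample windows and sits on the
flat part of the slope-vs-$k_{max}$ curve for signals in this class. DE
is computed on the filtered broadband signal — no band decomposition —
and both features are computed per channel, giving column layouts like
`DE_ch00 ... HFD_ch31`.

`feature_structure_report` summarizes the extracted matrix the way the
applied literature inspects it: a channels x channels Pearson correlation
per feature (zero-variance columns flagged undefined rather than
zero-filled) and per-column location/spread/skewness with a
kernel-density peak.

## Classifiers and evaluation

Four families sit behind one estimator contract (`estimator_spec`,
`fit_predict`): k-nearest neighbours (Euclidean, uniform votes, k = 5),
an RBF-kernel SVM (C = 1, gamma = "scale"), extreme gradient boosting
(binary logistic objective, log-loss metric), and classic gradient
boosting (shrinkage 0.1, depth-3 trees, 100 rounds, no stochastic
subsampling). The classic-gradient-boosting family runs on the same
boosted-tree backend as the XGBoost family, configured to the classical
algorithm's defaults. Distance-based families receive features
standardized with training-fold statistics; tree ensembles see raw
features. Whether the original protocols standardized before KNN/SVM is
unstated in this literature; standardization is the package default
because DE and HFD columns live on incommensurate scales, and it can be
read off the code rather than asserted as anyone's historical choice.

Two protocols:

* **Stratified k-fold** (default k = 5, i.e. 80/20): shuffled,
  stratified, segment-level splits with a fixed default seed (42). A
  per-fold and a pooled report (over concatenated test predictions) are
  returned. Segment-level splitting is the protocol that reproduces the
  published support bookkeeping, but it leaks trial identity — segments
  of one trial land in different folds — so trial- and subject-grouped
  splitters are provided (`split = "trial"`, `"subject"`), and the README
  states the leakage explicitly.
* **Leave-one-subject-out**: one fold per subject, metrics averaged over
  folds; subjects with a single class are flagged, excluded from
  averages, and warned about.

Reports implement the standard confusion-matrix metrics — accuracy,
per-class precision/recall/F1 with each class treated in turn as positive,
supports — plus an ROC sweep over unique scores (ties grouped) with
trapezoidal AUC, which equals the rank-sum statistic exactly. Undefined
ratios (zero denominators) are reported as `NA`, never zero-filled.
Scores for the ROC are class-1 probabilities where the family provides
them and min–max-mapped decision values for the SVM. `grid_search` does
exhaustive evaluation of a candidate grid by mean CV accuracy with
deterministic tie-breaking (first in grid order).

`paired_accuracy_ttest` compares two per-fold accuracy vectors with a
two-sided paired Student's t. Five folds give at most df = 4, which
bounds how small a p-value the design can resolve; published tables in
this literature sometimes print far smaller p-values per feature than a
5-pair test can produce, and the derivation is typically not recoverable.
The package therefore also supports pooling per-fold accuracies across
repeated seeded CV runs before testing, and reports degenerate cases
(zero-variance differences) explicitly instead of fabricating a finite
p-value.

## The synthetic generator

`synthetic_spec` defines a class-conditional signal model chosen to be
the minimal one with an independent knob per feature:

$$x_t = \varphi\, x_{t-1} + \varepsilon_t + A \sin(2\pi f t + \phi_0),
  \qquad \varepsilon_t \sim N(0, \sigma^2),$$

an AR(1) bed (stationary initialization) plus a sinusoid with random
phase. The innovation scale $\sigma$ controls signal variance and hence
differential entropy; the AR coefficient $\varphi$ controls smoothness
and hence fractal dimension. Defaults: class 0 has $\varphi = 0.8,
\sigma = 1$; class 1 has $\varphi = 0.4, \sigma = 3$ (innovation-scale
ratio 3); both share a 10 Hz unit-amplitude sinusoid. These values make
the classes separable by either feature alone — the entropy gap is
$\ln(\sigma_1^{stat}/\sigma_0^{stat}) \approx 0.67$ nats per channel —
which is what the end-to-end recovery check relies on, and single-feature
ablations can zero out either knob.

The within-subject geometry fills the first 32 channels from the class
model and the remaining channels with unrelated unit noise, mimicking
peripheral channels: a pipeline that forgets to drop them is
distinguishable by test. Ratings are drawn on the correct side of the
4.5 threshold (truncated normal, class means 3 and 6.5, SD 0.8) with
probability `label_fidelity` (default 1, so binarization recovers the
latent class exactly). The cross-subject geometry adds a per-subject
additive offset (SD 2) and log-normal gain (SD 0.1) to model
inter-subject variability; trials are balanced 15/15 by construction.
Everything is deterministic given the spec seed — subject $i$ uses stream
`seed + i` — so generated file sets carry reproducible MD5 manifests.

What the generator does **not** emulate: 1/f spectra, ERP morphology,
topographic correlation across channels, artifacts. Passing tests on
synthetic data therefore demonstrate that the pipeline's arithmetic,
estimators and protocols are correct and that constructed class signal is
recovered — not that any particular accuracy carries over to real
recordings.

## Numerical choices and degenerate inputs

* Histogram entropy of a constant segment is $-\infty$ (point mass);
  constant inputs raise a degenerate-distribution error rather than
  returning a sentinel.
* Higuchi on a constant series has zero curve length (log undefined):
  degenerate error; identical curve lengths across intervals raise a fit
  degeneracy error.
* The zero-phase filter requires trials longer than three
  coefficient-lengths ("trial too short" otherwise); decimation requires
  an integer rate ratio.
* Stratified folds deal shuffled within-class indices cyclically with the
  dealing position carried across classes, so fold sizes differ by at
  most one row and per-fold class counts by at most two.
* Ties in the grid search resolve to the first combination in
  deterministic grid order; ties in the ROC sweep collapse into one step,
  which is what makes the AUC equal the rank-sum statistic under ties.
* Randomness is confined to declared seeds: fold shuffling (`seed`),
  estimator internals (`random_state`, default 42), generator streams
  (`spec$seed + subject`).

## Problem sizes used by the checks

The test suite and the acceptance script run the full default geometries:
25,600 segments x 32 channels for the within-subject corpus (one subject's
raw tensor in memory at a time — subjects stream through conditioning and
feature extraction, so the 3 GB corpus never materializes), and 6,000
segments for the cross-subject corpus. Oracle checks use 50,000-sample
draws for the entropy closed form and 100 x 384-sample windows for the
fractal-dimension noise anchor. Unit tests run on deliberately tiny
geometries (a few trials of a few seconds) since every structural
property is size-independent.

## Known limitations

* No artifact-removal algorithm beyond the stated filters (no ICA/EOG
  regression); preprocessed-release inputs are assumed artifact-corrected.
* No band-wise DE (theta/alpha/beta/gamma), PSD, wavelet or statistical
  features; no overlapping windows; no multi-class labelling.
* Segment-level CV reproduces the published protocol but optimistically
  biases accuracy through trial leakage — use the grouped splitters for
  deployment-relevant estimates.
* The SVM's ROC scores are min–max-mapped decision values, comparable
  within a fold but not calibrated probabilities.
* Real-corpus readers cover the preprocessed-release dialects only; raw
  multi-format exports (EDF/BDF) are out of scope.
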