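---
title: "Emotion charting from multimodal physiological signals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emotion charting from multimodal physiological signals: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(emochart)
```

## The problem

Affective state is commonly summarized by two self-reported dimensions,
valence (pleasantness) and arousal (activation). Crossing their high/low
halves yields four classes — HVHA, HVLA, LVHA, LVLA — and the task this
package addresses is predicting that quadrant from short windows of
multimodal physiological recording: 14-channel EEG, 2-lead ECG and
single-channel skin conductance (GSR). These signals are attractive because
they are generated autonomically and are hard to mask, but they are noisy
(powerline pickup, baseline drift, cross-talk) and nonstationary, so the
pipeline couples aggressive preprocessing with learned features rather than
hand-crafted ones.

The pipeline is: overlapping segmentation, per-modality bandpass filtering,
independent component analysis of the EEG, discrete-wavelet scalograms per
channel, unsupervised feature learning with a contractive stacked
convolutional autoencoder, and a majority-vote ensemble of a linear
one-vs-rest SVM, a random forest and an LSTM over the bottleneck features.
Evaluation is k-fold cross-validation with one-vs-all sensitivity and
specificity per class.

## Segmentation and filtering

Trials are cut into 30 s windows every 15 s (50% overlap), giving
`floor((T - 30)/15) + 1` windows per trial; partial trailing windows are
dropped, and a sub-window trial yields an empty set with a warning. Windows
inherit the trial's quadrant label, obtained by splitting each rating at the
scale midpoint `(min + max)/2` with ties mapping low; the split point is a
parameter because neutral points differ between rating instruments.

Filtering runs over the *whole trial before segmentation*. The alternative
(segment first) is configurable, but filtering first is the default because
the GSR band's 0.04 Hz lower edge has a settling time comparable to a whole
30 s window, and windowed filtering would spend most of each window inside
the filter transient. Pass-bands are 0.5–45 Hz for EEG and ECG (rejecting
drift below 0.5 Hz and powerline at 50/60 Hz) and 0.04–0.25 Hz for GSR, the
conventional sympathetic-response band.

The filter is a 4th-order Butterworth bandpass applied forward–backward
(zero phase), so waveform morphology is neither delayed nor skewed. Two
numerical choices matter here:

* the design is carried out in zero–pole–gain form and realized as a
  cascade of biquad sections. At 128 Hz the GSR band corresponds to
  normalized frequencies of order 1e-3, where the expanded
  transfer-function polynomial of an 8-pole bandpass is numerically
  meaningless (measured gains of 1e232); biquads are exact at any band;
* the input is padded by odd reflection, sized to ~9 time constants of the
  slowest pole, before the forward–backward pass, so startup transients
  die inside the padding rather than in the data.

## Independent component analysis

EEG (only) is unmixed into statistically independent sources under the
standard noiseless linear model: observed channels are an unknown square
mixing of independent sources, and we estimate an unmixing matrix whose
output maximizes non-Gaussianity. The implementation is the fixed-point
iteration with PCA whitening, a `tanh` contrast and symmetric
decorrelation, initialized from a seeded random orthonormal matrix, so fits
are reproducible. ICA is fitted per trial; per-subject or per-window
fitting are reasonable alternatives, but per-trial matches how the
stationarity assumption is usually defended and keeps fits independent
across trials.

The estimated *sources* — not back-projected channels — feed the wavelet
stage. No components are discarded by default: without an artifact
annotation step any rejection rule is arbitrary, so all 14 sources are
forwarded; a kurtosis-threshold rejection is available but off. Two
diagnostics are built in: rank-deficient inputs fail naming the deficient
dimension, and inputs whose whitened components all have near-zero excess
kurtosis (within three sampling-noise SDs of Gaussian) raise a warning,
because independent components are only weakly identifiable from Gaussian
data and the iteration may then fail to converge — non-convergence is an
error carrying the iteration count and final step size.

## Wavelet scalograms

Each channel of each window is decomposed with an orthonormal Daubechies
discrete wavelet transform: recursive low/high-pass filtering and dyadic
decimation, with the high-pass filter derived from the scaling filter by
the quadrature-mirror alternating-flip relation. Defaults are `db4` and
L = 5 levels: at 128 Hz the detail bands then straddle the classical EEG
rhythms (d1 32–64 Hz, d2 16–32, d3 8–16, d4 4–8, d5 2–4, approximation
< 2 Hz). Boundary handling is periodic, which keeps the transform exactly
orthonormal — reconstruction is exact to rounding and coefficient energy
equals signal energy, both of which are tested, and the pyramid output is
cross-checked against a brute-force convolution-and-decimate oracle.

The scalogram assembly is this package's own design (the upstream idea is
only "DWT, then images"): the 1 + L sub-bands are stacked top-to-bottom
from approximation to finest detail, the level-j band replicated
`2^(L-j)`-fold so the image has `2^L` conceptual rows; cells hold
`log(1 + |coefficient|)`; each band is spread along the time axis; the
image is min–max normalized to [0, 1] (an all-zero decomposition maps to an
all-zero image rather than dividing by zero) and resampled to the
configured size (64×64 by default, 32×32 in the desk-scale configuration)
by block averaging. Tones placed at sub-band centers localize to the
correct row block, which is tested against the analytic band edges
`rate/2^(j+1)`–`rate/2^j`.

## The contractive stacked autoencoder

All 17 channel scalograms of a window are stacked as input planes of a
single autoencoder — one network sees all modalities, performing early
fusion; per-modality encoders would be a different architecture, out of
scope here. The encoder is three convolutional blocks with 15×15, 9×9 and
3×3 kernels (16/32/64 filters by default), each block being convolution →
batch normalization → ReLU → 2×2 max pooling (argmax positions recorded) →
dropout, followed by a flatten and an affine projection to a 128-d
bottleneck (the feature vector; a vector rather than a feature map because
the downstream classifiers consume vectors). The decoder mirrors this:
affine expansion, then per block max *unpooling* to the recorded positions,
transposed convolution, batch normalization, ReLU and dropout, with a
linear final reconstruction layer.

Training minimizes mean squared reconstruction error plus a contractive
penalty `lambda * ||d b / d m||_F^2` — the squared Frobenius norm of the
bottleneck–input Jacobian — which shrinks the sensitivity of the learned
code to input perturbations. With `lambda = 0` the loss is exactly the
MSE. Two implementations of the penalty coexist deliberately:

* an exact one (`encoder_jacobian`, one reverse-mode sweep per bottleneck
  unit), quadratic in network size, used for loss reporting and testing;
* a stochastic one used inside training: a single Gaussian probe `v` with
  `E||Jv||^2 = ||J||_F^2`, the directional derivative taken by finite
  difference through a second encoder pass. The two agree on small
  networks, which is tested, and the finite-difference Jacobian oracle
  validates the reverse-mode one to 1e-4.

Optimization is Adam (default 50 epochs, batch 32, learning rate 1e-3,
`lambda` 1e-4, dropout 0.1 — all configurable); every stochastic element
(initialization, shuffling, dropout, probes) derives from the config seed,
so the loss history reproduces run-to-run. Training is unsupervised: labels
never enter. Within cross-validation the autoencoder is fitted on training
folds only; the upstream description is silent on this, but fitting on test
segments would leak, so the leakage-free protocol is the default and is
enforced by a recorded lineage manifest.

The convolutions (forward, input gradient and weight gradient) are computed
in the Fourier domain: linear convolution as circular convolution on a
zero-padded grid, with the per-frequency channel contractions in small
compiled kernels. At scalogram sizes this does an order of magnitude less
memory traffic than patch-matrix (im2col) convolution, which is what makes
a from-scratch R implementation fast enough; the im2col route is retained
internally and the two are cross-checked against each other, and the whole
backward pass is checked against finite differences across all layer
types.

## Classifiers and the ensemble

Three classifiers are trained on identical bottleneck features:

* **SVM**: linear kernel, one-vs-rest (four binary machines, argmax of
  oriented decision values), cost C = 1;
* **Random forest**: 100 trees, seeded bootstrap;
* **LSTM**: a single cell with 32 hidden units. The features are static,
  so each 128-d vector is unrolled into 8 timesteps of 16 values (step
  count configurable); the final hidden state feeds a softmax over the four
  quadrants. The cell follows the textbook gate arithmetic exactly —
  forget `y_t = sigma(a_t A_f + h_{t-1} H_f)`, input
  `I_t = sigma(a_t A_i + h_{t-1} H_i)`, candidate
  `n_t = tanh(a_t U_c + h_{t-1} H_c)`, state `c_t = y_t c_{t-1} + I_t n_t`,
  output `o_t = sigma(a_t A_o + h_{t-1} H_o)`, `h_t = o_t tanh(c_t)` — and
  `lstm_cell_step` is the bias-free reference implementation against which
  the batched training cell is conformance-tested; trained models use a
  standard positive forget-gate bias initialization.

Determinism contracts: the LSTM trains full-batch, so it is exactly
reproducible under its seed; the SVM and forest canonicalise the order of
training rows (sort by label, then lexicographically by features) before
fitting, making them invariant to the order the data arrived in, not just
to the seed.

The ensemble returns any label that wins at least two of the three votes.
On a three-way disagreement it falls back to the LSTM's label (flagged
`tie_broken`), because the LSTM is the strongest standalone member in the
upstream ablation; the fallback member is configurable. The voting table is
tested exhaustively over all 4³ triples against a brute-force count.

## Evaluation

k-fold cross-validation, k = 10 by default. The default split is
segment-stratified — class proportions preserved, segments of one subject
allowed on both sides — which mirrors the upstream evaluation protocol
("each subject has multiple samples"); because that protocol lets the
models exploit subject identity, a grouped-by-subject mode that never
splits a subject is provided as a first-class alternative and its accuracy
should be expected to be lower on real data. Overall accuracy is
trace/total of the pooled 4×4 confusion matrix; per class, the matrix is
binarized one-vs-all and sensitivity `TP/(TP+FN)` and specificity
`TN/(TN+FP)` are reported, with empty denominators reported as undefined
(`NA`), never as zero. Metrics are verified against a brute-force counting
oracle.

The ablation harness (`run_ablation`) re-evaluates the same recordings
under named variants of the ladder {no-preprocess, bandpass, bandpass+ica}
× {scalogram, autoencoder, stacked-autoencoder} × {cnn, rf, svm, lstm,
ensemble} with shared folds and seed, so differences between rows are
attributable to the varied stage. The `cnn` entry is a small baseline head
(one 3×3 convolutional block and a softmax when reading scalograms; a
one-hidden-layer softmax head when reading extracted features); the
upstream work names such a baseline without specifying it, so its
architecture is declared here in config rather than inferred.

## The synthetic data generator

No benchmark recordings ship with the package, so the generator produces
datasets with the statistical structure the pipeline assumes, and every
stage is tested against it:

* **EEG**: each channel is a sum of band-limited noise in the five
  classical bands (delta 1–4, theta 4–8, alpha 8–13, beta 13–30, gamma
  30–45 Hz), weighted by a per-quadrant band-power profile — beta-dominant
  for HVHA, alpha-dominant for HVLA, gamma-tilted for LVHA, slow-wave
  dominant for LVLA, the standard arousal/valence spectral caricature. Band
  components wax and wane under a slow burst envelope, as cortical rhythms
  do; this also makes the channels super-Gaussian, without which
  independent components would be unidentifiable and ICA would rightly
  fail. Powerline (50 Hz), slow drift and broadband noise are added so the
  preprocessing stage has real work to do, and the generator and filter are
  mutually consistent (the injected tone is attenuated ≥ 20 dB — tested).
* **ECG**: a stylized beat train (narrow R-like and broad T-like bumps) at
  a per-quadrant heart rate (95/88 bpm aroused, 62/55 calm) with
  per-quadrant beat-interval variability — *not* a biophysical model;
  sufficient for pipeline mechanics, tested via the autocorrelation peak.
* **GSR**: slow tonic level plus exponentially decaying phasic events at a
  per-quadrant rate (8/6 per minute aroused, 2/1 calm); spectral mass sits
  below 0.5 Hz, matching the analysis band.
* **Ratings** are drawn on the correct side of the scale midpoint, so
  quadrant labels are recoverable from the ratings by construction.

Difficulty is a dial: the `easy` preset uses the well-separated profiles
above with noise SD 0.4 (a linear classifier on raw band powers reaches ≥
90% — tested, which pins the difficulty level the end-to-end acceptance run
is performed at); the `moderate` preset shrinks the spectral contrast
halfway toward a common profile and doubles the noise. What passing tests
on this data shows is that the *pipeline machinery* — filtering, unmixing,
time-frequency imaging, feature learning, ensembling, scoring — is correct
and leak-free; it does not show that the learned features transfer to real
recordings, where class signatures are weaker, subject-specific and
confounded. Published accuracies on real benchmark datasets are therefore
not reproduced here and the package makes no claim about them.

## Problem sizes and numerical choices

The desk-scale configuration (`desk_scale_config()`) — 8 subjects × 4
trials × 60 s, 32×32 scalograms, 8/16/32 filters, 64-d bottleneck, 10
epochs per fold, batch 16, 10-fold CV, LSTM unrolled to 4 steps of 16
features (keeping 16 dimensions per step, as the full-scale 128-d → 8×16
reshape does) and trained for 80 full-batch epochs — is the package's
chosen demo and acceptance scale: a complete run takes a few minutes of
single-core CPU and under 2 GB of memory. Other defaults of note: wavelet `db4`, L = 5;
ICA tolerance 1e-6 with at most 500 iterations; Adam (0.9, 0.999, 1e-8);
finite-difference step 1e-3 for the training-time penalty probe and 1e-6
for Jacobian validation; EDF quantization is 16-bit over each channel's
physical range, so round-trips are exact to half a quantization step.

## Known limitations

* The generator's quadrant signatures are caricatures; real affective EEG
  differences are far subtler and non-stationary across subjects.
* The stratified default leaks subject identity across folds by design
  (to mirror the upstream protocol); use grouped mode for
  subject-independent claims.
* The MATLAB container reader implements one documented layout
  (uncompressed v5, `joined_data`/`labels_selfassessment` cells) and
  refuses compressed files rather than guessing.
* Three-way ensemble ties are resolved asymmetrically (LSTM fallback);
  the asymmetry is documented and configurable.
* The LSTM consumes an arbitrary unrolling of a static vector; it is a
  faithful port of the upstream design, not an argument that recurrence
  helps on static features.
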