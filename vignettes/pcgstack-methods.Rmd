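---
title: "Heart-sound stacking ensembles: models, defaults, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound stacking ensembles: models, defaults, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgstack)
```

## The problem

Heart failure with preserved ejection fraction (HFpEF) is a diastolic
phenotype of chronic heart failure: the ventricle ejects normally but fills
poorly. Impaired relaxation and elevated filling pressures change the
mechanical — and therefore acoustic — behaviour of the heart, which makes
the phonocardiogram (PCG), a cheap single-channel recording of heart
sounds, an attractive screening signal. `pcgstack` implements a complete
PCG classification pipeline for the two-class problem *non-heart-failure
vs HFpEF-like*, organised as five stages that can each be used on their
own.

## Signal conditioning

Raw auscultation audio carries baseline wander, mains hum and broadband
artifact. The conditioning chain (`preprocess_signal()`) is:

1. **Butterworth bandpass 10–1000 Hz** (order 4, applied forward–backward).
   Heart sounds live well inside this band. The zero-phase application
   doubles the effective attenuation and, more importantly, does not shift
   S1/S2 timing — a causal IIR filter would.
2. **FIR mains notch at 50 Hz**, a fixed linear-phase band-stop of ~12 Hz
   design width, applied with its group delay removed. A fixed design is
   used because a notch this narrow is already safe for the surrounding
   band: tones 10 Hz away pass within 1 dB.
3. **Optional SVD + wavelet denoising** (`denoise_svd_wavelet()`): a Hankel
   (trajectory-matrix) embedding whose leading singular subspace — 99.5% of
   squared singular-value energy — captures the quasi-periodic component,
   followed by a 5-level Daubechies-4 decomposition with soft thresholding
   at the universal threshold, the noise scale estimated from the finest
   detail level's median absolute deviation. The retained-energy default is
   set so that a noiseless structured signal passes through essentially
   unchanged (correlation ≥ 0.99) while still stripping broadband noise.
4. **Resample to 2205 Hz and z-score.** All downstream stages assume this
   working rate and unit scale.

The denoiser is off in the default pipeline profile: the Hankel SVD is by
far the most expensive stage, and the synthetic training conditions have a
mild noise floor. It is one flag away
(`preprocess_config(denoise_enabled = TRUE)`) and is tested directly.

## Gammatonegrams

The time–frequency image is built from a gammatone filterbank rather than
an STFT. The channel impulse response is the product of a gamma envelope
and a tone,

$$g(t; f_c) = a\, t^{\,n-1} e^{-2\pi b t} \cos(2\pi f_c t + \varphi),
\qquad t \ge 0,$$

with order $n = 4$, $b = 1.019\,\mathrm{ERB}(f_c)$ (Glasberg–Moore), and
center frequencies equally spaced on the ERB-rate scale — so low
frequencies get narrow filters and high frequencies broad ones, matching
auditory frequency resolution. Defaults (all configurable, none dictated
by theory): 64 channels spanning 20–1000 Hz, 25 ms frames with a 10 ms
hop, per-channel framed RMS energy. Impulse responses are truncated where
the envelope falls below $10^{-5}$ of its peak and gain-normalized to unit
response at $f_c$; equivalence with the analytic response — causality,
zero at the origin, spectral peak at $f_c$ — is what the tests pin down,
not a particular realization.

`gammatonegram_image()` converts the matrix to a gray image:
log-compression to dB, clipping to a 60 dB dynamic range below the peak,
min–max scaling and bilinear resizing (224×224 for the deep-feature path,
the standard CNN input size; 128×128 for the texture path, where the
gray-level statistics saturate well below CNN resolution and the smaller
raster keeps the zone/run scans cheap). An all-zero spectrogram maps to an
all-zero image by convention.

## Texture features

The image is quantized to $N_g = 32$ equal-width gray levels over its own
range (the scale is already normalized, so fixed-count binning is the
natural choice), and four classical gray-level matrices are computed with
the coordinate convention *x = column, y = row, origin top-left*:

* **GLCM** — joint occurrences of level pairs at offset $(\Delta x, \Delta y)$,
  distance 1, four directions, symmetric, normalized to sum to 1;
* **GLRLM** — maximal same-level runs per direction;
* **GLSZM** — sizes of maximal 8-connected same-level zones;
* **GLDM** — per-pixel counts of Chebyshev-1 neighbours within gray-level
  tolerance $\delta = 0$.

From these come the standard radiomics panel of **70 scalar features**
(24 GLCM + 16 GLRLM + 16 GLSZM + 14 GLDM), GLCM/GLRLM averaged over the
four directions. Degenerate inputs follow fixed conventions so every
feature is finite: correlation-type features are 0 when a marginal
variance vanishes, the informational correlations fall back to 0 when the
normalizing entropy is 0, and GLDM feature weights use dependence + 1 so
the zero-dependence column is well defined. Each builder is verified
against an independent brute-force enumeration written straight from the
defining counts, exhaustively on all 512 binary 3×3 images and on random
larger images.

## Deep features and the backbone interface

The deep path is an interface: `backbone_spec()` accepts `resnet50`,
`densenet121`, `inception_resnet_v2` (with Adam fine-tuning settings —
batch 16, 120 epochs, learning rate $10^{-4}$, early stopping — carried as
configuration), but those need externally supplied pretrained weights and
requesting them without weights raises an explicit error, never a silent
fallback. The tested default, `desk_default`, is a deterministic seeded
random-projection convolutional featurizer: downsample to 32×32, cut into
8×8 patches, project each patch through a fixed Gaussian filter bank with
a ReLU, and mean/max-pool over patches (64 dimensions). Random
convolutional features are a standard cheap surrogate for learned
representations; what the ensemble machinery needs from this stage — a
deterministic image-to-vector map that separates band-energy differences —
is exactly what it provides, and the three "architectures" of the default
profile are three different filter-bank seeds. PCA (retaining 95% of
variance by default) reduces the features before classification.

## Base learners, calibration, stacking

Four first-order models: one **RFE-SVM** on the 70 texture features
(features z-scored with training statistics; recursive elimination ranked
by squared linear-SVM weights, dropping 10% of the remainder per round to
20 survivors; final RBF SVM) and three **PCA + random forest** models
(500 trees) on the three deep feature sets. Raw scores — SVM decision
values, forest vote fractions — are mapped to posteriors by **Platt
sigmoid calibration** (chosen over isotonic because the training sets are
small); the map is monotone, so calibration never changes a learner's AUC,
and the positive- and negative-class posteriors sum to one by
construction.

Stacking uses **out-of-fold predictions**: the training set is cut into
K = 5 folds grouped by subject and stratified by label, each learner
predicts every training sample from a model that never saw any segment of
that sample's subject, and the pooled out-of-fold posteriors both (a)
train the meta-learner and (b) give each learner's validation AUC
$\hbar_\mu$. Using the pooled out-of-fold AUC as the "validation AUC" is a
design choice — it is unbiased and uses the whole training set, where a
single held-out slice would be noisier. Weights are AUC-proportional,

$$\omega_\mu = \hbar_\mu \Big/ \sum_\nu \hbar_\nu,$$

and the meta-learner input is the columnwise weighted posterior
$\zeta_{i\mu} = \omega_\mu P_{i\mu}$ (only the positive-class posterior:
its complement is redundant). The meta-learner is an **MLP with hidden
layers 256/128/64** (ReLU, sigmoid output, full-batch Adam on binary
cross-entropy, early stopping on a 10% internal stratified split, at most
500 epochs, deterministic given its seed). Two baselines reuse the same
fitted base learners: *soft voting* (unweighted posterior mean) and
*plain stacking* (weights forced to 1) — with equal validation AUCs,
weighted stacking's meta-inputs are exactly plain stacking's scaled by
$1/\mu$.

Weights are recomputed per split (not fixed globally): they are estimates
from the training data at hand, and each repeat has its own training set.

## Evaluation protocol

Subjects — never segments — are split 7:3 per class (so a subject's
segments are all train or all test), the ensemble is fitted with
out-of-fold stacking on the training segments, and the metric panel (AUC
with DeLong 95% CI, accuracy, sensitivity, specificity, precision, F1) is
computed on test segments at a fixed 0.5 threshold (a Youden-optimal
threshold estimated on training out-of-fold posteriors is available behind
`youden = TRUE`). The protocol repeats with fresh splits (10 by default)
and averages. Metrics are segment-level; subject-level aggregation is a
deliberate non-default since the segment is the unit the model scores.
AUC differences between correlated ROC curves use the fast DeLong
placement-value estimator, checked in the tests against both `pROC` and a
paired-bootstrap oracle, with degenerate conventions `p = 1` for
identical scores and an explicit error for zero variance with unequal
AUCs.

## Bayesian optimization

Hyperparameters are tuned by a Gaussian-process model of the loss
(default loss: 1 − validation AUC) with a squared-exponential kernel
(lengthscale picked by marginal likelihood over a small grid, jitter
$10^{-8}$), and the closed-form expected improvement for minimization,
$EI = (l^* - \mu)\Phi(z) + \sigma\phi(z)$. Proposals maximize EI over a
seeded 512-point random candidate set plus local perturbations of the
incumbent; the initial design is a Latin hypercube (n = 5). Integers are
relaxed and rounded, categoricals one-hot encoded. Per-fold independent
tuning is supported but global tuning is the default at desk scale —
per-fold tuning multiplies the cost by the fold count for little benefit
on synthetic data. Failed objective evaluations are recorded as the worst
observed loss and flagged rather than aborting the search.

## The synthetic-data generator

`simulate_pcg_dataset()` provides the study conditions every test runs
under. Each recording is a quasi-periodic train of Gaussian-windowed tone
bursts: S1 (~45 Hz, σ = 22 ms) at each cycle onset and a weaker S2
(~70 Hz, σ = 15 ms) a third of a cycle later, at a population heart rate
of 75 bpm. Subjects carry random effects — log-normal amplitude, heart
rate offset (SD 4 bpm), cycle timing jitter — so subject-grouped splitting
is meaningfully exercised. The positive class receives an S3-like
early-diastolic low-frequency burst (~28 Hz) and an upward shift of the
S2 band, both scaled by `effect_size`; `effect_size = 0` makes the two
class-conditional distributions identical (verified by a Monte-Carlo
band-power test). White noise with `noise_sd` (default 0.1) is added, and
the native rate of 4410 Hz forces the resampling step to do real work.
Defaults mirror a modest clinical cohort: 40 subjects per class, 5
segments per subject, 10-second recordings.

What the generator does **not** emulate: murmurs and valvular pathology,
respiratory modulation, sensor and contact artifact, rhythm disturbances,
and the true acoustic physiology of diastolic dysfunction — the "HFpEF"
class is a planted spectral effect, not a hemodynamic model. Passing
tests therefore demonstrate that the pipeline recovers a class difference
expressed as band-energy/texture structure under subject grouping and
stays at chance when none exists; they say nothing about clinical
performance on real auscultation data.

## Problem sizes and numerical choices

The verification runs use desk-scale sizes chosen once: end-to-end checks
use the 40 × 2-subject, 5-segment, 10-second default cohort (400
recordings) with `effect_size = 2, noise_sd = 0.05` for the separable
condition and `effect_size = 0` (3 repeats, averaged) for the null;
the strategy comparison uses 20 subjects per class × 3 segments of 4 s.
Matrix-builder equivalence is exhaustive at 3×3 and sampled at 16×16;
DeLong is checked against a 10,000-rep bootstrap at n = 50 and a 500-run
null calibration. Seeds derive from a single integer through a fixed
linear-congruential mix kept below $2^{31}$, and every stochastic
component (simulator, folds, forests, filter banks, MLP, optimizer) draws
from R's RNG under that derivation, which is what makes reruns
bit-identical.

## Known limitations

* The texture feature panel follows the de-facto standard radiomics
  definitions of the four matrix families; other software's variants
  (different aggregation across directions, different $N_g$) will produce
  numerically different — though strongly correlated — features.
* Platt calibration assumes a sigmoidal score-to-probability link; badly
  specified scores would need the isotonic alternative.
* The desk backbone is not a learned representation; with real data and
  pretrained weights the deep path should be swapped to a CNN backbone
  through the same interface.
* The DeLong normal approximation for CIs is anti-conservative for AUCs
  very near 1 with few subjects.
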