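---
title: "Discriminating herbal varieties from NIR hyperspectral images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminating herbal varieties from NIR hyperspectral images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbspec)
```

## The problem

Medicinal bulb flakes (here: twelve commercial varieties of a *Fritillaria*
herb) look alike but differ in chemical composition, and those differences
leave small signatures in near-infrared reflectance. herbspec implements the
full chemometrics chain for discriminating such varieties from line-scan NIR
hyperspectral images: reflectance calibration, sample segmentation, spectral
extraction and denoising, exploratory PCA, and three discriminant models —
PLS-DA, an RBF-kernel SVM, and a one-dimensional VGG-style convolutional
network — compared with confusion-matrix metrics.

Because instrument data of this kind are rarely public, the package ships a
first-class synthetic generator that emulates the statistical structure the
analysis assumes. Every stage is tested against it.

## Reflectance calibration

Raw counts depend on illumination and dark current. With a white reference
(near-100 % reflectance tile) and a dark reference (capped lens), relative
reflectance is

$$I_C = \frac{I_{raw} - I_{dark}}{I_{white} - I_{dark}}.$$

`calibrate()` applies this band-wise, accepts per-band, per-column
(line-scan) or full-frame references, and clips the result to $[0, 1.5]$
rather than erroring: specular pixels legitimately exceed 1, but values far
above that indicate a broken reference, and the clip keeps downstream
statistics finite. Any non-positive $I_{white}-I_{dark}$ denominator is a
hard error naming the offending bands.

Cubes travel in the ENVI convention: an ASCII `.hdr` with
`samples/lines/bands/interleave/data type/byte order/wavelength` keys and a
little-endian flat binary in BIL, BIP or BSQ order (`read_envi()`,
`write_envi()`; unsigned 16-bit and 32-bit float payloads).

## Segmentation and spectral extraction

Samples are segmented at a single high-contrast band (default 1019 nm,
where sample/background contrast is strong for this instrument class).
The threshold is Otsu's criterion — it maximises between-class variance,
which is exactly the "maximum contrast" idea — and connected components
below `min_region_px` (default 20 px) are discarded as speckle. The binary
mask then cuts the same ROI out of every band; `extract_pixel_spectra()`
returns one row per ROI pixel in raster order with `(row, col)` provenance.

Two cleanups follow:

* **Wavelength cropping.** Line-scan NIR systems are unstable at the ends of
  the spectral axis. The default window keeps 875–1546 nm (a config value,
  never hard-coded); the synthetic generator triples the noise outside this
  window so that the crop is actually load-bearing in tests.
* **Wavelet denoising.** Each spectrum is decomposed to scale 3 with a
  Daubechies filter (default `db6`, 12 taps; the order is configurable),
  detail coefficients are soft-thresholded at the universal threshold
  $\sigma\sqrt{2\ln n}$ with $\sigma$ estimated from the median absolute
  deviation of the finest details, and the signal is reconstructed. The
  transform uses periodized boundaries, which keep the decomposition
  orthogonal and make reconstruction exact to machine precision at any
  length (odd lengths are pad-and-truncated). No wavelet package exists in
  the package's dependency stack, so the pyramid algorithm is implemented
  directly and property-tested (orthonormal quadrature-mirror filters,
  exact reconstruction, noise-reduction and near-idempotence on noisy
  profiles).

Denoising is defined pixel-wise (`denoise_spectra()` maps over rows);
whether models then consume pixel spectra or per-sample means is the
caller's choice. The pipeline default is one mean spectrum per sample —
with 12 × 30 samples that gives the 360-row design matrix the split
arithmetic below assumes — and the pixel-wise route stays available through
the same functions.

## PCA

`spectra_pca()` performs centred (not scaled) PCA by SVD — scaling is
deliberately omitted because reflectance bands share units and comparable
variance, and component shares are reported as percentages of total
variance (`cumulative_variance()` sums the leading ones). Loading signs
follow a fixed convention (largest-magnitude element positive) so repeated
fits are bit-identical. PCA here is exploratory; it feeds no information
into the classifiers.

## The three discriminant models

All three sit behind one contract: `fit_*()` returns a classed object whose
`predict()` yields 0-based integer labels; each stores the per-band
standardizer (mean/sd learned from training rows only) it applied.

**PLS-DA** (`fit_plsda()`): SIMPLS regression of a one-hot class-indicator
matrix on the spectra; predicted class is the argmax of the predicted
indicators (equivalently, the class indicator at minimal absolute
difference from the prediction). `ncomp = "auto"` selects the number of
latent variables by leave-one-out cross-validation over `1..max_ncomp`,
smallest on ties; one SIMPLS fit yields nested predictions for every
component count, which keeps the n-fold loop affordable. The SIMPLS core is
cross-checked in the test suite against an independent PLS-DA
implementation (mixOmics) on a separable fixture.

**RBF-SVM** (`fit_svm_rbf()`): exhaustive grid search over penalty `c` and
kernel width `g`, scored by stratified 5-fold cross-validation on the
training rows (the fold count is a package choice; any inner CV scheme
would do), ties broken toward smallest `c` then smallest `g`, best pair
refit on all training rows. The machine itself is e1071's libsvm binding —
a solved problem the package does not re-solve — but the search, fold
construction and tie policy are owned and tested here. The full
`(c, g) → accuracy` surface is kept for inspection.

**1-D CNN** (`fit_cnn()`): five blocks of two length-3 convolutions
(stride 1, padding 1) with batch normalization and ELU
($f(x) = x$ for $x>0$, $\alpha(e^x-1)$ otherwise, $\alpha = 1$), filter
ladder 16–32–64–128–128, max-pool of 2 after each block, then a 256-wide
dense layer, dropout 0.5, and a K-way softmax head trained with Adam on the
cross-entropy loss under the hyperbolic decay
$\eta_t = \eta_0/(1+kt)$ with $\eta_0 = 5\times10^{-4}$, $k = 0.045$,
batch size 256, and a default budget of 800 epochs. Forward and backward
passes are written directly on BLAS matrix kernels (im2col convolutions),
with analytic gradients verified against finite differences in the tests.
Design points worth recording:

* *Block order* is conv→conv→pool, the VGG convention.
* *Pooling* is max-pooling of size 2 (also the VGG convention); sequence
  lengths floor-halve five times, so inputs need at least $2^5$ bands.
* *Initialization* is the He scheme for all hidden layers; the output
  layer starts at zero, so the untrained network predicts exactly the
  uniform distribution and the initial loss is $\ln K$ — a useful training
  diagnostic and a stable starting point.
* *Standardization* is the usual $(x-\mu)/\sigma$ with training-set
  statistics.
* *Best-epoch restore*: the returned parameters are those of the epoch
  with the lowest training loss; the full loss history is kept.
* Training is bit-deterministic given the spec seed (initialization,
  shuffling and dropout share one seeded stream; nothing touches the
  global RNG).

## Evaluation

`confusion()` builds the K×K count matrix (rows true, columns predicted);
`metrics()` derives per-class precision $TP/(TP+FP)$, recall $TP/(TP+FN)$,
their harmonic-mean F-score, and **macro** averages (unweighted class
means), plus overall accuracy. Macro averaging is the scheme under which a
single precision/recall pair per model is meaningful on balanced classes
while still allowing precision ≠ recall; micro-averaged values — which
provably equal accuracy — are carried alongside as an internal consistency
check. A class never predicted gets precision 0 and is flagged rather than
propagating NaN. `model_report()` tabulates train/test metrics for several
models side by side.

## The synthetic generator

`synthetic_config()` fixes the generative recipe; everything downstream is
a pure function of it.

* **Baseline**: a gentle logistic rise flattening in $[0.25, 0.55]$
  reflectance — the general level and shape of bulb-flake NIR curves,
  without claiming chemical fidelity.
* **Shared features**: Gaussian bumps placing peaks at 1100 and 1300 nm and
  valleys at 1200 and 1460 nm, the C–H overtone / water-band structure all
  varieties share; peak and valley positions are common to every class.
* **Class deltas**: each class adds two small position-staggered Gaussian
  perturbations. The default amplitude (0.035) makes classes overlap
  heavily, as real varieties do; the `"well_separated"` preset (0.2) exists
  so that accuracy-style checks have a deterministic-by-margin target.
  Intra-class variability and SNR of the real samples are not published
  anywhere, so the noise levels are free parameters chosen once: pixel
  noise sd 0.01 (≈1 % reflectance), tripled outside the clean window —
  realistic orders of magnitude for line-scan NIR, not estimates.
* **Cubes**: `simulate_cube()` re-encodes reflectance to counts by
  inverting the calibration identity against smooth synthetic white/dark
  frames, so calibrate ∘ encode is exactly the identity — the round-trip is
  a tested invariant, not an approximation. The sample is a centred disc;
  the ground-truth mask ships with the cube so segmentation accuracy is
  measurable.

What passing tests on this generator shows: the chain is internally
consistent, calibration and extraction are exact, and the models can
recover class structure of the assumed form at realistic noise. What it
does not show: performance on real instrument data, whose intra-class
variance, scattering artefacts, and baseline drifts the generator does not
attempt to model. The published headline accuracies of the motivating
study were measured on its private samples and are not reproduction
targets here.

## Numerical choices and degenerate inputs

* Band selection at a target wavelength takes the nearest band, ties
  toward the lower wavelength.
* Cropping keeps the closed interval and is idempotent.
* Otsu on a constant image is a degenerate-input error, as is an empty
  post-filter mask.
* Softmax subtracts the row maximum before exponentiating; the
  cross-entropy log is clamped at $10^{-12}$.
* A non-finite training loss aborts with the epoch number rather than
  returning a corrupt model.
* Constant bands standardize to 0 (sd replaced by 1, flagged).
* All randomness flows through per-call seeded streams; the caller's
  `.Random.seed` is never disturbed.

## Problem sizes used in the shipped checks

The test-and-demonstration runs use the study design (12 × 30 samples, 256
bands cropped to 199) with short CNN budgets (25–30 epochs), which the
well-separated preset comfortably saturates; small 3-class fixtures cover
unit behaviour. The 800-epoch default remains available for full-scale
runs.

## Limitations

* The CNN runs on CPU BLAS; it is adequate for hundreds of spectra, not
  for pixel-wise training on whole cubes.
* The ENVI reader covers the dialect written by `write_envi()` (BIL/BIP/
  BSQ, uint16/float32, little-endian) — not bad-band lists, chunked
  streams or geo keys.
* Segmentation assumes one bright sample region per scene; instance
  splitting of touching samples is out of scope.
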