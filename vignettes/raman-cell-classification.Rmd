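---
title: "Classifying single-cell Raman spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying single-cell Raman spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramancell)
```

## The problem

Raman micro-spectroscopy records, for a single fixed cell, the inelastic
scattering spectrum of a focused laser spot — a "molecular fingerprint" in
which bands at characteristic Raman shifts report on nucleic acids, proteins,
lipids and carbohydrates. Primary tumor cells (here: hepatocellular
carcinoma) carry more nuclear DNA than their non-tumor counterparts, which
shows up as slightly elevated nucleic-acid bands (782–785, 1094, 1335, 1370,
1578 cm⁻¹) and slightly depressed Amide III (~1240 cm⁻¹) and CH₂/CH₃
deformation (~1438 cm⁻¹) bands. The differences are a few percent of peak
height, smaller than the fluorescence background and comparable to
cell-to-cell heterogeneity, so classification requires a careful
preprocessing chain and supervised models.

`ramancell` implements the full chain: spectrum simulation, preprocessing,
outlier screening, linear discriminant models, a windowed CNN-LSTM with a
reject option, and blind prediction of the tumor fraction of cell mixtures.

## The synthetic-data generator

Every downstream stage must be testable without patient data, so the
generator emulates the statistical structure the analysis assumes:

* **Bands.** One pseudo-Voigt line (50/50 Gaussian/Lorentzian, unit peak
  height scaling) per entry of `default_band_table()` — the characteristic
  bands of fixed single liver cells. Tumor spectra multiply the five
  nucleic-acid bands by 1.25 and the 1240/1438 cm⁻¹ bands by 0.8. These
  magnitudes put the class-mean difference at a few percent of peak height,
  the regime reported for primary liver cells; they are parameters, not
  constants.
* **Study shape.** Defaults are the study conditions: 40 cells per class,
  5 spectra per cell, a 600–1800 cm⁻¹ grid at 1 cm⁻¹.
* **Cell heterogeneity.** One log-normal factor per cell (sd
  `cell_effect_sd`, default 0.1) multiplies the class-informative band
  amplitudes, so spectra cluster by cell.
* **Background and noise.** A random cubic fluorescence baseline (coefficient
  ranges giving a background comparable to or larger than the peaks — cubic
  by design, so the order-3 correction is exact in expectation) plus
  i.i.d. Gaussian noise (`noise_sd` default 0.02 against order-1 peak
  heights, i.e. SNR ≈ 50, plausible for 60 s × 2 accumulations). The study
  never reports its noise level or background magnitude; these defaults are
  calibrated only to reproduce the qualitative difference spectrum, and were
  fixed once.
* **Corruption.** `outlier_fraction` of spectra (exactly
  `round(fraction × N)`) are corrupted by one of two modes: a narrow
  cosmic-ray-like spike (10–30× the largest band) or a broad fluorescence
  surge (8–12× the largest band, FWHM ~200 cm⁻¹). A corrupted "10× cubic
  baseline" mode would be removed *exactly* by the order-3 baseline
  correction and thus be undetectable by construction; the surge is the
  closest corruption that survives preprocessing, which is the property an
  outlier screen can be validated against.

What the generator does **not** emulate: CCD etalon fringes, wavelength-
dependent instrument response, cosmic-ray statistics, within-cell spatial
gradients, patient-to-patient variation, or band-shape changes (only
amplitudes differ between classes). Consequently, passing tests demonstrate
that the pipeline recovers the structure it assumes — not that it reaches
any particular accuracy on real patient spectra. On the default synthetic
task the linear models are near-perfect; the real-data regime (77–93%
accuracy) is harder than this simulation, and the acceptance checks are
therefore phrased as floors (e.g. accuracy ≥ 0.85), not as reproductions of
the patient-data percentages.

## Preprocessing

The stage order is fixed: axis calibration → substrate background
subtraction → crop to [600, 1800] cm⁻¹ (closed interval) → baseline
correction → vector normalization. Choices worth recording:

* **Calibration** is a rigid translation anchored on the 520.7 cm⁻¹
  crystalline-silicon line; offsets beyond ±10 cm⁻¹ abort (instrument
  fault, not data). No dispersion correction — one reference line cannot
  estimate one.
* **Background** grids may differ from sample grids; the background is
  linearly interpolated, and must cover the sample grid (no extrapolation).
* **Baseline**: iterative polynomial clipping ("modified polyfit"): fit an
  order-3 polynomial, clip the working signal to the fit, repeat. Exact on
  peak-free polynomial inputs of degree ≤ 3. The iteration converges
  geometrically but slowly on noisy spectra (relative change ~10⁻⁴ after
  100 iterations, still ~10⁻⁵ after 400), so the convergence tolerance is
  10⁻⁴ with `max_iter` 250 — tight enough that the residual baseline error
  is far below the noise floor, loose enough that realistic spectra
  converge without warnings. Non-convergence warns and returns the current
  fit rather than failing.
* **Vector normalization** = unit Euclidean norm (the standard chemometric
  meaning); idempotent; an all-zero spectrum is an error. Every spectrum
  leaving the pipeline has unit norm — this is asserted, not assumed.
* Outliers are screened **after** preprocessing; the screening statistics
  are meaningless on spectra that still carry their fluorescence baseline.

## Outlier screening

A PLS1-DA model (response 0/1 = Non-Tumor/Tumor, NIPALS, default 5 latent
variables) yields two complementary statistics per spectrum: the Q-residual
(squared distance from the latent subspace) and Hotelling's T² (Mahalanobis
distance inside it). Limits at 95%: Jackson–Mudholkar approximation for Q
(from the residual covariance eigenvalues) and `A(N−1)/(N−A) · F₀.₉₅(A, N−A)`
for T². The default flagging rule is the union ("either") — the conservative
screening choice; "both" is available.

Five components is a deliberate middle ground: small against N (≈400), large
enough to capture the class-relevant variance. **Masking** deserves a note:
a *single* gross spike fitted into the model can dominate the covariance
with the response, be absorbed as a latent variable, and then appear as an
extreme T² score rather than an extreme Q-residual. The union rule flags it
either way, and with realistic corruption (many outliers in distinct
directions) Q behaves as expected; the test suite pins down both regimes.

## Linear models

* **LDA** is implemented with a pooled within-class covariance and optional
  shrinkage toward a scaled identity, `S* = (1−γ)S + γ(tr S/p)I`. Full
  spectra have p ≈ 1200 ≫ n ≈ 300, so the unshrunk problem is singular;
  `"auto"` uses the Ledoit–Wolf intensity, `"none"` falls back to an
  eigenvalue-thresholded pseudo-inverse. Priors: empirical or uniform.
* **Grid-search tuning** evaluates shrinkage ∈ {none, auto, 0.1…0.9} ×
  priors ∈ {empirical, uniform} by k-fold (default 5) CV accuracy; ties are
  broken by first-in-grid order, so builds are deterministic.
* **PCA-LDA** fits PCA once (covariance of mean-centered intensities, no
  scaling), then selects the number of leading components by leave-one-out
  CV of an LDA on the scores, over candidate counts 5, 10, …, 60 (a step-5
  grid keeps the LOOCV affordable; the candidate vector is an argument).
  Smallest count wins ties. The cumulative explained variance of the chosen
  components is reported alongside.
* **Splits** default to spectrum-level stratified randomization with a fixed
  seed. Because the 5 spectra of a cell are correlated, spectrum-level
  splitting leaks cell identity across folds; `split_mode = "cell"` assigns
  whole cells to folds and is provided for the honest-generalization
  variant. The default mirrors the study design; the leakage caveat is why
  both modes exist.
* **Metrics**: sensitivity = TP/(TP+FN) and precision are computed with
  Tumor as the positive class; percentages print at 2 decimals.

## The CNN-LSTM

Each preprocessed spectrum is cut into `k_s = 3` equal, non-overlapping
slices (trailing remainder points are dropped — at 1 cm⁻¹ resolution that is
at most 2 of 1201 points). A shared convolutional stack — "time-distributed":
identical weights applied to each slice — extracts per-slice features; the
flattened features form a 3-step sequence for a 100-unit LSTM; a softmax
head classifies. Two depth variants exist:

| variant | convolution stack (filters/stride) | head |
|---|---|---|
| 25 layers | 64/4, 128/4, 256/4 | LSTM → dropout → dense(2) |
| 56 layers | 64/2, 64/2, 128/2, 128/2, 256/2, 256/1, 256/1 | LSTM → dropout → dense(64) → dense(2) |

Design notes:

* **Kernels are 1-D of length 4.** A 6×4 2-D kernel is an image-network
  formulation; applying it to a 1-D spectrum requires reshaping each slice
  into an arbitrary 2-D patch and padding to stack further layers. The 1-D
  stack with strided downsampling has the same receptive-field structure
  without the arbitrary reshape; the kernel length is configurable.
* **Layer counting.** The advertised counts (25/56) follow a documented
  manifest convention: every named layer is counted, with time-distributed
  layers counted once per slice, and the 56-layer variant counting its
  selective branch. `summary()` prints the manifest; behavior, not the
  count, is the tested contract.
* **Two dropout sites**: the tuned rate (0.1–0.25) on the flattened slice
  features, and a fixed 0.5 after the LSTM — the tuned interval and the
  fixed head rate describe different sites, not a contradiction.
* **Selective branch** (reject option): two dense layers (100→32→1,
  sigmoid) on the LSTM state emit a confidence g. The loss is the
  confidence-weighted selective risk `Σgᵢrᵢ/Σgᵢ` plus a coverage penalty
  `λ·max(0, c − ḡ)²` (λ = 32, target coverage c = 0.9) plus 0.5× the plain
  cross-entropy as auxiliary head. At prediction time a spectrum is
  rejected iff g < threshold; thresholds 0.2 and 0.8 are the two reference
  operating points.
* **Augmentation**, training folds only, re-drawn every epoch: *value*
  multiplies each window by one uniform factor in ±10%; *frequency*
  translates each window's axis by up to ±10% of its length (linear
  resampling, edge padding). Validation and test windows are never
  augmented; the fold table carries an explicit `val_augmented` flag so
  this is checkable.
* **Optimization**: Adam, batch 32, early stopping on validation loss
  (patience 10). All weight initialization and shuffling is seeded; training
  is bitwise reproducible on a fixed BLAS.
* **Engine.** No deep-learning backend is involved: convolutions are im2col
  matrix products against the linked BLAS, and gradients are derived
  manually. At the default sizes a 5-fold cross-validation of the 25-layer
  variant on ~360 spectra × 1201 points runs in a few minutes on one CPU.
* **Hyper-parameter search** uses a tree-structured Parzen estimator over
  depth ∈ {25, 56}, log-uniform learning rate in [10⁻⁴, 0.05], dropout in
  [0.1, 0.25], reject threshold ∈ {0.2, 0.8} and augmentation mode; after a
  random warm-up, candidates maximize the good/bad Parzen density ratio at
  the 25% quantile split. `ablation_grid()` reproduces the 16-cell
  (2 depths × 2 thresholds × 4 augmentation modes) comparison table, each
  depth at its reference learning rate and dropout (0.001/0.15 and
  0.01/0.2).

## Blind mixture prediction

`blind_predict()` votes per spectrum and estimates the tumor fraction as
`100 × n_predicted_tumor / n_non_rejected`; rejected spectra are excluded
from the denominator and reported. The estimate converges to
`p·sens + (1−p)(1−spec)` for true fraction p, which is the stated
interpretation of a vote-based percentage (misclassified non-tumor spectra
*do* inflate it); the test suite checks this closed form on simulation.
Votes are conserved: tumor + non-tumor + rejected = n. A per-cell
majority-vote aggregation is deliberately out of scope of the default path
(the fraction is defined at the spectrum level). Sets must be preprocessed
with the configuration used in training; a mismatch is an error, not a
warning.

## Problem sizes and determinism

The packaged tests and the acceptance script run the full study at its
native size — 400 spectra × 1201 points, 10% corruption, 5-fold CV, a
30-epoch budget for the 25-layer network — and smaller, coarser-grid
variants (301-point axis) for unit-level checks. Every stochastic step
(generation, splits, initialization, augmentation, TPE) takes an explicit
seed; degenerate inputs (empty sets, all-zero spectra, single-class labels,
all-rejected mixtures) raise errors or well-defined `NA`s rather than
propagating nonsense.

## Known limitations

* The simulator's class difference lives entirely in band amplitudes on a
  shared peak set; real tumor/non-tumor differences include band shifts and
  shape changes it cannot represent.
* Spectrum-level splits leak cell identity (see above); cell-level splits
  are provided but are not the default.
* The Q-limit's Jackson–Mudholkar approximation assumes approximately
  normal residuals; gross corruption violates this, which is harmless for
  screening (limits are then conservative in the right direction) but the
  limit should not be read as an exact false-positive rate.
* Training the 56-layer variant at full resolution is an order of magnitude
  slower than the 25-layer one; the ablation table at realistic epoch
  budgets is a batch job, not an interactive call.
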