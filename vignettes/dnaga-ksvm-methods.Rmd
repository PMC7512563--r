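---
title: "Methods: DNA-GA tuned Tsallis-entropy wavelet features with an RBF-kernel SVM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNA-GA tuned Tsallis-entropy wavelet features with an RBF-kernel SVM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnagaksvm)
```

## The classification problem

`dnagaksvm` classifies 2-D grayscale brain MRI slices as benign or
malignant. The method has three stages:

1. **Multiresolution decomposition.** Each image is normalized to [0, 1],
   resized to 128 x 128 by bilinear interpolation, and decomposed with a
   decimated 3-level 2-D Haar wavelet transform. The orthonormal filter
   pair is low-pass $(1/\sqrt2, 1/\sqrt2)$ and high-pass
   $(1/\sqrt2, -1/\sqrt2)$, applied separably to rows then columns with
   symmetric (half-point) boundary extension and even-phase downsampling.
   A 3-level decomposition of a 128 x 128 image leaves a 16 x 16 = 256
   coefficient approximation plus nine detail sub-bands.

2. **Non-extensive entropy features.** Every sub-band is reduced to its
   Tsallis entropy
   $S_q = \left(1 - \sum_i p_i^q\right) / (q - 1)$,
   where the $p_i$ are a 256-bin gray-level histogram of the sub-band's
   coefficients (min-max scaled per sub-band) and $q > 0$ is the
   non-extensive parameter; $S_q \to -\sum_i p_i \ln p_i$ as $q \to 1$.
   The feature vector is the 10 per-sub-band entropies, ordered
   $[\mathrm{LL}_3, \mathrm{HL}_1, \mathrm{LH}_1, \mathrm{HH}_1, \dots]$.

3. **Soft-margin RBF-kernel SVM.** Features are standardized (statistics
   from the training folds only) and classified by a C-SVM under the
   Gaussian kernel $K(x, y) = e^{-\sigma\|x - y\|^2}$ — note $\sigma$
   multiplies the squared distance (a gamma-style width).

The three hyperparameters $(q, C, \sigma)$ are tuned jointly by a DNA
genetic algorithm whose fitness is the stratified five-fold
cross-validation classification rate (the mean of the five held-out
accuracies). After the search, a final SVM is refit on all data at the
best parameters; this refit-on-all policy maximizes the training data for
the deployed model.

## The DNA genetic algorithm

Individuals are strings over the quaternary alphabet {0, 1, 2, 3}, read
as the nucleotide bases with the fixed map C=0, T=1, A=2, G=3 (the unique
assignment consistent with the three substitution tables below). Each
parameter occupies one gene of $l = 8$ digits; a gene decodes big-endian
to an integer $v \in [0, 4^l - 1]$ mapped affinely onto the parameter's
interval, giving a resolution of (upper - lower)/65535 — finer than any
precision at which the tuned parameters are meaningfully distinct. The
default search intervals are $q \in (0, 1)$, $C \in (50, 200)$,
$\sigma \in [0.5, 2]$, with a selectable alternative $q \in (0, 2)$
(`default_param_specs("sbd")`). Because $q = 0$ is outside the entropy's
domain, the lower bound of $q$ is $10^{-3}$ rather than 0.

Each generation applies:

* **Selection** — binary tournaments with replacement; the best parent is
  always copied into slot 1 (elitism) and that copy is exempt from
  variation, so the best-so-far fitness trajectory is non-decreasing.
* **Crossover** (probability $p_c$ per individual, one operator chosen
  uniformly): *transformation* (two of five contiguous near-equal
  segments exchange positions), *permutation* (a segment is replaced by
  the corresponding segment of a random other individual) and
  *translocation* (a segment is moved to a new position). The five-segment
  partition assigns remainder digits to the leftmost segments.
* **Mutation** (probability $p_m$ per digit, one operator chosen
  uniformly among four): the digit maps *reversal* (0↔2, 1↔3),
  *transition* (0↔1, 2↔3), *exchange* (0↔3, 1↔2) — each a fixed-point-free
  involution, with reversal∘transition = exchange — and *point mutation*
  (replacement by a uniformly chosen different digit).

Defaults are $T = 20$ individuals, $G_{\max} = 30$ generations,
$p_c = 0.8$, $p_m = 0.02$, chosen as ordinary GA practice for a
three-parameter search. Evolution stops at $G_{\max}$ or when the best
fitness changes by less than $\delta = 10^{-4}$ for 3 consecutive
generations; a single-step $\delta$ rule was found to halt too eagerly
when the fitness surface has plateaus, so the 3-generation window is the
default. Whether point mutation is an alternative to or additional to the
digit-map mutations was an open choice; a uniform choice among the four
is used. All randomness flows through explicit stream objects derived
from one master seed (independent streams for data generation, fold
assignment and the GA), so every result is bit-reproducible.

## The SVM layer

The soft-margin dual (box constraints $0 \le \alpha_i \le C$, equality
$\sum_i \alpha_i y_i = 0$) is solved by libsvm via `e1071`; the model is
re-expressed as explicit support vectors, dual coefficients and bias, and
all predictions are computed by this package's own kernel expansion
$g(x) = \sum_i \alpha_i y_i K(s_i, x) + b$. `ksvm_kkt()` verifies the
optimality conditions (margin conditions per dual-coefficient regime) on
the training set; the solver contract is KKT residuals $\le 10^{-3}$.
Feature standardization is applied because the kernel's Euclidean
distances are scale-sensitive and the 10 entropy features have unequal
spreads. Malignant is the positive class, so sensitivity is the malignant
detection rate.

Two conventions worth noting: the Shannon entropy display convention is
$\log_2$ (bits), but the $q \to 1$ limit of the Tsallis form is the
natural-log Shannon entropy, so Tsallis entropies (and hence all pipeline
features) are in nats; and although the non-extensivity argument suggests
$q < 1$ for strongly correlated systems, the implementation permits
$q \in (0, 2)$ — in practice the tuned optimum on noisy data often lies
above 1.

## What the phantom generator emulates

Real reference datasets (simulated T1/T2 brain volumes; hospital
T2-weighted slices) are not redistributable here, so the package ships a
phantom generator that reproduces their statistical task structure:

* **Anatomy.** A concentric-ellipse head: background, an outer CSF band,
  a GM band, and a WM core (band fractions 0.88 and 0.70 of the
  normalized elliptical radius). Each draw jitters the semi-axes
  (about ±1%), the band fractions (±0.005) and the orientation (±10°;
  axial slices are approximately orientation-normalized in practice, and
  orientation strongly redistributes edge energy between the HL and LH
  sub-bands, so an unbounded rotation would model a nuisance real
  datasets do not have).
* **Contrast.** Dataset generation uses a T2-weighted intensity map —
  CSF 0.9, GM 0.6, WM 0.35 — the modality chosen in clinical practice
  precisely because focal lesions are strongly hyperintense against
  white matter. (`phantom_spec()` itself defaults to a T1-like map
  0/0.3/0.6/0.9; under T1 contrast a lesion at intensity 1.0 differs from
  WM by only 0.1, which is ~2 standard deviations of the 20 dB noise —
  too small for any histogram feature to detect reliably.)
* **Malignancy.** Hyperintense discs (default two, radius 6-11 px on the
  128 grid, intensity 1.0) placed fully inside the WM core so the
  lesion-tissue contrast is consistent. Real pathology diversity
  (infiltration, edema, mass effect) is *not* modeled: passing tests show
  that the pipeline recovers a detectable focal-hyperintensity signal
  under Rician noise, not that it would classify real tumors.
* **Noise.** Rician magnitude noise
  $\sqrt{(I + n_1)^2 + n_2^2}$ with $n_1, n_2 \sim N(0, \sigma_n)$ and
  $\sigma_n = \mathrm{rms}(I)/10^{\mathrm{SNR_{dB}}/20}$ — the SNR is
  defined on the rms signal because no formula accompanies the printed dB
  levels. The magnitude is left unclipped (clipping at 1.0 would erase
  the lesion-vs-WM top-of-range structure); PNG export rescales by the
  image maximum.

Two dataset presets mirror the two experimental regimes: `"aanlib"` is a
90-slice collection of 18 subtypes x 5 replicates (5 benign + 85
malignant, subtypes differing in lesion count, size and contrast), used
for composition and stratification checks; `"sbd"` is the noise-sweep
regime — 45 benign + 45 malignant replicates of the same anatomy,
generated at each SNR in {5, 10, 15, 20} dB. The sweep uses a balanced
composition because the corresponding experiment quantifies slices
against ground truth rather than reusing the 5 x (1 + 17) collection;
with 5 benign images out of 90, a five-fold CV would hold out a single
benign case per fold and the sweep would measure the majority-class rate,
not noise robustness.

## Numerical choices and degenerate inputs

* Histogram binning: min-max scaling onto 256 bins (mirroring 8-bit gray
  levels); a constant sub-band puts all mass in bin 0 and contributes
  zero entropy. The printed summation limit in the entropy's source
  formula is a typo; the sum runs over all gray levels.
* Tsallis entropy dispatches to the natural-log Shannon entropy within
  $10^{-9}$ of $q = 1$ to avoid cancellation.
* Odd-length signals are extended by repeating the boundary sample
  (half-point symmetric extension), giving ceiling-halving shapes at
  every level; for dyadic sizes the transform is exactly orthonormal
  (round-trip and energy errors at machine precision).
* Ties in the SVM decision (exactly zero) are broken towards malignant —
  the conservative direction for a screening tool.
* An all-zero image yields an all-zero feature vector and a defined
  prediction (no error).
* Five-fold CV with hyperparameters tuned on the same folds reproduces
  the source protocol; it is *not* a nested CV, so the reported CV
  fitness is an optimistically biased estimate of generalization. This is
  deliberate and documented rather than corrected.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
90-image datasets of 128 x 128 phantoms with $T = 20$, $G_{\max} = 10$,
five replicate seeds per SNR level — sizes chosen so the whole experiment
reruns from scratch in about a minute on one core while leaving the
fitness landscape non-trivial (about 200 CV evaluations per run, each
refitting five SVMs). Sub-band histograms are cached per image, so
changing $q$ during the search never re-runs a wavelet transform
(`prepare_images()` exposes an instrumentation counter that the tests
assert on). Unit tests use 64 x 64 phantoms where the full resolution is
not the point.

## Known limitations

* The phantom family is deliberately simple; benign/malignant differ only
  by focal hyperintensities in white matter.
* Only the Haar wavelet and the RBF kernel are implemented; the search
  intervals for $(q, C, \sigma)$ are fixed to the published ranges.
* The confusion-matrix cell values of the published comparison table are
  typographically garbled in the source and are not used as fixtures;
  only the derived accuracies (440/450, 388/450, 411/450) are checked.
* Per-pixel lesion segmentation overlays are out of scope; the unit of
  classification is the whole slice.
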