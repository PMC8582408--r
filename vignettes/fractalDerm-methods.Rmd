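---
title: "Surface fractal dimension and color-cluster features for skin lesions: methods and design"
author: "fractalDerm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fractalDerm methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalDerm)
```

# Overview

`fractalDerm` implements a feature-extraction and classification workflow for
pigmented skin-lesion images (dermoscopy or clinical photographs). The
pipeline is:

1. **Preprocessing** — hair removal and lesion segmentation, producing the
   binary mask that defines "within the lesion".
2. **Color features** — the percentage of lesion pixels falling in each of a
   set of axis-aligned RGB color-cluster boxes (23 in the canonical set).
3. **Texture feature** — the two-dimensional Higuchi surface fractal
   dimension (HFD) of each RGB channel of the whole image, averaged into a
   single descriptor.
4. **Selection** — a per-feature Welch two-sample t-test, keeping features
   with p < 0.05.
5. **Classification** — k-nearest neighbours or a radial basis function
   neural network (RBFNN), both evaluated by stratified 5-fold
   cross-validation, with sensitivity, accuracy, precision, AUC, Dice and MSE
   reporting. Melanoma is always the positive class.

Every stage is testable without real images: the package ships generators for
fractional Brownian surfaces of known roughness, lesions of exactly known
color composition, and two-class Gaussian feature tables with controllable
effect sizes.

# The 2D Higuchi surface fractal dimension

A channel is an intensity surface $\gamma_{ij}$, $i = 1,\dots,M$,
$j = 1,\dots,N$. For a scale $k = 1,\dots,k_{max}$ (default $k_{max} = 8$)
and offset $m = 1,\dots,k$, the subsampled matrix $X_k^m$ keeps every $k$-th
row and column starting at $(m, m)$; $k = 1$ keeps every pixel. Over each
$k \times k$ grid cell of $X_k^m$ the estimator multiplies the four absolute
intensity differences along the cell's edges, sums over all
$\lfloor (M-m)/k \rfloor \cdot \lfloor (N-m)/k \rfloor$ cells and normalizes
by

$$\xi = \frac{1}{2k^4}\,
       \frac{N-1}{\lfloor (N-m)/k \rfloor}\,
       \frac{M-1}{\lfloor (M-m)/k \rfloor},$$

giving the surface-area proxy $A_m(k)$. $A(k)$ is the mean of $A_m(k)$ over
the $k$ offsets. The channel dimension is $HFD_c = S_c + 1$ where $S_c$ is
the least-squares slope of $\ln A(k)$ against $\ln(1/k^2)$, and the image
descriptor is the mean of the three channel values. $k_{max} = 8$ keeps all
scales informative on images of 16 px and larger while remaining cheap; every
channel must satisfy $\min(M, N) \ge k_{max} + 1$.

Two ambiguities in the published formulation of this estimator had to be
resolved, and both resolutions are exposed as options:

* **`formulaMode`.** As typeset in the source literature, the second
  difference factor compares against a fixed column index $m + k$, which
  breaks the symmetry of the four cell edges. We treat this as a typographic
  slip for the cell's right-edge difference: `corrected` (the default) uses
  the four cell edges; `as_printed` reproduces the typeset formula for
  auditability. The $k^4$ in $\xi$ matches a product of four $k$-spaced
  differences, which supports the corrected reading.
* **`fitScale`.** The published abscissa of the log-log fit is garbled
  (self-referential). The default regresses $\ln A(k)$ on $\ln(1/k^2)$, the
  sign convention under which rougher surfaces obtain larger HFD;
  `k_squared` exposes the opposite convention.

## Calibration behavior, and the [2, 3] band

The theoretical fractal dimension of a surface lies in $[2, 3]$, and $3 - H$
for a fractional Brownian surface with Hurst exponent $H$. The package's test
suite measures what this estimator actually does on 8-bit fBm surfaces
(128×128, 20 seeds per Hurst value):

* white noise is estimated near 3 and a smooth ramp near 1;
* the estimate decreases strictly as $H$ grows (rougher ⇒ larger HFD), the
  property the classifier relies on;
* because the measure multiplies *four* $k$-lag differences, each scaling as
  $k^H$, $A(k) \propto k^{4H-4}$ and the fitted value behaves like $3 - 2H$
  rather than $3 - H$: smooth surfaces ($H > 0.5$) are estimated *below* 2.

The estimator is therefore a roughness index whose raw range on fBm spans
roughly $[1.4, 2.4]$ rather than the theoretical $[2, 3]$ band, and the
acceptance suite records the lower bound honestly as failing that band. Since
downstream classification only needs a monotone roughness descriptor, the
**raw** value is the feature used; a copy clamped to $[2, 3]$ is reported
alongside (`meanHFDClamped`) with a flag when clamping altered it, for users
who want the conventional range. HFD is computed on the full rectangular
image, not within the mask: subsampling a masked irregular domain is not
well-defined for this estimator.

Flat channels (some $A(k) = 0$) carry no fractal information and raise an
error naming the offending scale rather than propagating `NaN` through the
log fit. All arithmetic is done in doubles: a product of four 8-bit
differences can exceed the 32-bit integer range.

# Synthetic data: what it emulates, what it does not

* **`fbmSurface` / `fbmImage`** — Fourier spectral synthesis with power
  spectral density $\propto f^{-(2H+2)}$ and uniform random phases,
  rescaled to $[0, 255]$ and rounded. The rounding deliberately mimics 8-bit
  dermoscopy channels; quantization noise is part of the test conditions.
  Spectral synthesis was chosen over midpoint displacement because it is
  isotropic and trivially deterministic under a seed.
* **`syntheticLesion`** — an elliptical mask (semi-axes 0.38 and 0.30 of the
  image side, optionally perturbed by random radial harmonics) whose pixels
  are drawn uniformly from named, pairwise-disjoint cluster boxes. Counts
  are apportioned by largest remainder, so realized per-cluster counts match
  the requested composition within one pixel — the exact ground truth the
  color-feature tests rely on. `maskArea` trims the mask to an exact pixel
  count so percentages have a known denominator. The background "skin" color
  (default RGB 242, 230, 221) is verified at generation time to fall outside
  every box of the active set.
* **`twoClassTable`** — unit-variance Gaussian features; informative columns
  shift the melanoma class mean by `effect` standard deviations.

None of this is photorealistic: there is no illumination gradient, no vignette,
no color constancy problem, no smooth pigment texture, and "hairs" used in
preprocessing tests are straight dark strokes. Passing tests demonstrate
algorithmic correctness against known ground truth, not clinical performance
on real dermoscopy collections.

# Preprocessing stand-ins

Published descriptions of this workflow rarely specify the hair-removal or
segmentation algorithms, so the package uses standard, replaceable building
blocks and lets a manifest supply externally produced masks so segmentation
quality never blocks the feature stages.

* **Hair removal** (`removeHair`): grayscale bottom-hat (closing − image)
  maximized over line structuring elements of length 11 px at 0°-150° in 30°
  steps, thresholded at `lineStrength` (default 20 intensity units — above
  the in-lesion texture of typical images, below hair/skin contrast).
  Detections shorter than the structuring-element length in every direction
  are discarded: a hair is by definition elongated, while high-curvature
  lesion-boundary slivers are not. Remaining pixels are inpainted by
  iterated mean-of-known-neighbors fill. Luminance is the unweighted channel
  mean throughout the package, avoiding a commitment to any colorimetric
  standard. The morphology is computed by a small shift-based min/max filter
  so that 0-255 intensities are handled exactly.
* **Segmentation** (`segmentLesion`): Otsu threshold on the luminance, the
  darker side taken as lesion, largest connected component kept, holes
  filled. The result always has exactly one component and no holes; a
  constant or foreground-free image raises a segmentation failure rather
  than returning an empty mask.

# Color clusters

The classical 23-cluster RGB palette for melanocytic lesions is defined only
graphically in the literature, so the box bounds live in a user-editable CSV
(`id,rmin,rmax,gmin,gmax,bmin,bmax`, inclusive bounds) and the package ships
its own default: black, a ten-step brown ramp, four blue-grays, four reds,
two pinks and two whites, constructed pairwise disjoint. All correctness is
defined with respect to whatever set is loaded. A pixel belongs to the
*first* listed box containing it (deterministic under overlap; with disjoint
boxes the order is irrelevant), and pixels matching no box are tracked in an
explicit `unassigned` percentage so the output always sums to 100.

# Selection and classifiers

* **t-test selection**: Welch's unequal-variance statistic (lesion datasets
  are strongly imbalanced, e.g. 68 vs 297), strict p < 0.05, no multiplicity
  correction by default for fidelity to the plain rule, with `adjust`
  available. Zero-variance features are flagged and never selected.
* **kNN** (`knnPredict`): Euclidean distance; the neighbor count is not
  fixed by the source methodology, so the default is k = 5, required odd to
  avoid two-class vote ties; distance ties at the neighborhood boundary go
  to the smaller training index. The score is the positive-neighbor
  fraction.
* **Cross-validation** (`runCV`, `makeFolds`): stratified folds dealt
  cyclically after a within-class shuffle, so fold sizes differ by at most
  one overall and per class. Stratification is a deliberate strengthening:
  with 5 folds and severe imbalance, unstratified folds risk single-class
  test sets. By default the pipeline refits feature selection inside every
  training fold (leakage guard); `paperFaithful = TRUE` restores the
  select-once-then-cross-validate order with a logged warning.
* **RBFNN** (`trainRBFNN`): Gaussian units
  $\exp(-\lVert x - c\rVert^2 / 2\sigma^2)$ centered on training samples,
  two linear output nodes fit by least squares against one-hot targets.
  Training is greedy incremental: each step adds the candidate center that
  most reduces training MSE, computed through an orthogonalized update that
  is algebraically identical to a full least-squares refit per candidate
  (orthogonal least squares), so the recorded MSE trajectory — which starts
  at the bias-only, 0-neuron solution — is exactly non-increasing. Training
  halts at MSE ≤ 0.01 or 50 neurons (the defaults used throughout), or when
  no candidate adds information. The spread default is the median pairwise
  training distance, a standard heuristic for a parameter the source
  methodology leaves unspecified; inputs are z-scored by default and the
  transform travels with the model. A rank-deficient final design falls back
  to a ridge solve (regularizer 1e-8) with a warning. Output ties predict
  the nevus class and are logged.

# Evaluation conventions

Sensitivity, accuracy, precision and Dice come from the pooled out-of-fold
confusion counts (melanoma positive); pooled metrics are primary and per-fold
rows are reported alongside. AUC is the Mann–Whitney rank statistic over
continuous scores (kNN: neighbor fractions; RBFNN: the positive-class output,
min-max squashed — rank-preserving). MSE follows the network convention,
mean squared difference between one-hot targets and raw outputs; for kNN an
MSE against scores is reported but flagged as not comparable. Zero-denominator
ratios are `NA` with a warning, never 0. Reports print percentages to two
decimals and AUC/Dice to four.

# Problem sizes used by the test and acceptance suites

The suites run at the study conditions they document: the Hurst sweep uses
9 values × 20 seeds of 128×128 RGB surfaces; oracle-equivalence checks use 50
random 32×32 surfaces in both formula modes at tolerance 1e-9; composition
recovery uses 10,000-pixel masks (±0.01 percentage points); selection
calibration uses 1,000 null features against the 99% binomial band around
α = 0.05; classifier checks use 100 samples per class, 5 features, effect 3,
over 10 seeds; and the bookkeeping checks extract 365- and 120-image
manifests with 15- and 9-cluster sets (5,475 and 1,080 cluster-feature
values).

# Known limitations

* The HFD estimator's raw values undershoot the theoretical surface band on
  smooth inputs (see above); treat it as a relative roughness index.
* Hair removal targets thin, dark, roughly straight structures; bright or
  very curly hair and ruler markings are out of scope.
* Segmentation assumes a lesion darker than the surrounding skin with a
  roughly unimodal background; masks can and should be supplied for images
  that violate this.
* No color constancy, contrast normalization or artifact (gel, vignette)
  handling is attempted.
* Reported performance on synthetic data says nothing quantitative about
  real dermoscopy collections.
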