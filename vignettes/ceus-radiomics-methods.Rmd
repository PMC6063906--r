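---
title: "CEUS radiomics: models, parameters and design choices"
author: "ceusRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CEUS radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science behind the package: the models and
assumptions of every stage, the tunable parameters with their defaults
and units, what the synthetic phantom emulates (and what it does not),
and the design choices made where more than one reasonable option
existed.

## The imaging model

Destruction–replenishment CEUS records a plane of a tumour in B-mode
while intravascular microbubbles flow through it. After a
high-mechanical-index pulse destroys the bubbles in the plane, re-inflow
follows the mono-exponential model

$$ I(t) \;=\; I_0 + A\,\bigl(1 - e^{-\beta t}\bigr), $$

where $A$ (intensity units) is the plateau amplitude, $\beta$ (1/s) the
replenishment rate, and $t$ seconds since destruction. $\beta$ scales
with mean blood flow velocity; the package converts it through an
explicit calibration constant `beamWidth` (length units, default 1)
because the elevational beam geometry of a given transducer is a
property of the instrument, not of the algorithm.

## The synthetic phantom

Real CEUS study data cannot be redistributed, so the package generates
ground-truthed phantoms that reproduce the *design* of a two-dataset,
three-observer xenograft study:

* **Three phenotype classes** (`P1`, `P2`, `P3`) encoded as parameter
  triplets (vessel density 0.08/0.13/0.20, $\beta$ 0.5/1.0/1.8 s⁻¹,
  background echogenicity 18/22/27). These stand in for three tumour
  models with hypovascular/slow through hypervascular/fast perfusion
  phenotypes; the spacing gives *moderate* class separation — the
  downstream classifier is accurate but not trivially perfect.
* **Study design.** 5 + 5 + 4 animals, two imaged positions per animal
  (two independent phantom realizations sharing the animal's class
  parameters), each position rendered twice (test / retest) with
  identical geometry and fresh noise — 28 scans per dataset — and three
  observer delineations per scan (the true ellipse, plus jittered
  ±2 px dilated/eroded variants). Animal-level biological variability
  is a log-normal jitter (SD 0.10) on density and $\beta$.
* **Vessel networks** grow from seeded random walks with branching
  (per-step probability 0.08), dilated to ~3 px for main branches with
  1-px terminal twigs, iterated until the vessel fraction of the ROI is
  within 10% (relative) of the class target. The generator fails
  loudly if the target is unreachable within its iteration budget.
* **Speckle.** Multiplicative-style speckle is emulated as a smoothed
  exponential random field (correlation length 2 px) standardized and
  scaled to `speckleScale` (default 6 intensity units) around the
  phenotype's background level. Crucially the field is split into a
  *static* interference texture and a *fluctuating* part
  (`speckleTemporalFrac = 0.4`): tissue speckle is deterministic given
  the scatterer configuration, so frame-to-frame decorrelation is
  partial. A fully i.i.d.-per-frame noise model would be unphysical
  — and would make breathing shifts undetectable in principle, since a
  shifted i.i.d. field is distributionally identical to an unshifted
  one.
* **Kinetics and artifacts.** Bolus inflow is a linear ramp to the
  plateau (cosmetic — only post-destruction kinetics are analysed),
  destruction drops the vessel signal to zero at frame 16 of 48
  (10 frames/s), and every 10th frame is globally shifted by 3 px to
  emulate breathing, with the schedule recorded in the ground truth.

What the phantom does **not** emulate: acoustic wave propagation and
RF-domain statistics, depth-dependent attenuation and focusing,
non-rigid breathing motion, bubble-size-dependent echogenicity, 3-D
effects (scans are 2-D planes), and irregular (non-elliptical) tumour
outlines. Passing tests therefore demonstrate the correctness and
internal consistency of the algorithms under a controlled data model —
not clinical performance on real scans.

## Denoising

Frames are log-transformed (`log(I + 1)`; the offset guards zero
pixels) so multiplicative speckle becomes approximately additive, then
decomposed to level 3 with the biorthogonal 3.7 wavelet. The noise
scale is the standard robust estimate from the first-level diagonal
detail, $\hat\sigma_n = \mathrm{median}(|HH_1|)/0.6745$, and each
third-level detail subband is soft-thresholded with the BayesShrink
rule $T = \hat\sigma_n^2/\hat\sigma_x$,
$\hat\sigma_x = \sqrt{\max(\hat\sigma_y^2 - \hat\sigma_n^2, 0)}$
(all-noise subbands are zeroed entirely). Only the deepest level is
thresholded; shallower details and the approximation pass through.
Thresholding all levels is the more common BayesShrink variant, but the
deepest-level-only scheme is retained deliberately as the package's
filtering definition; `thresholdScale` exposes the shrinkage strength
(0 disables it, which is also the oracle used to test the transform's
perfect-reconstruction property, exact to 1e−10).

No wavelet package exists in the supported dependency stack, so the
decimated 2-D transform (periodized, with symmetric padding to a
multiple of $2^{level}$) and the level-1 stationary transform are
implemented in the package itself with published filter coefficients.

## Vessel segmentation

The chain follows the order: Wiener-type 3×3 adaptive smoothing →
artifact detection → frame differencing → maximum intensity projection
→ adaptive thresholding → speckle removal.

* **Adaptive smoothing** uses the local-statistics estimator
  `m + max(v − v_n, 0)/max(v, ε) · (x − m)` with the noise variance
  $v_n$ estimated as the mean of the local variances.
* **Artifact frames.** Each frame is scored by its mean absolute
  difference to the previous frame; outliers above
  `median + 3·MAD` are candidate artifacts. A breathing displacement is
  *transient and reversible*: both flanking transitions are high while
  the skip difference $|f_{t+1} - f_{t-1}|$ stays below half the
  smaller flanking transition. This distinguishes one-frame shifts
  from persistent changes (bolus ramp, destruction), which a pure
  outlier rule mis-flags for fast-replenishing tumours. Flagged frames
  are excluded, not registered.
* **Projection and thresholding.** The per-pixel maximum of
  |consecutive frame differences| accumulates moving-bubble signal and
  cancels static echoes. It is binarized by a local-mean threshold
  (window 15 px) plus an offset of `0.5 · sd(MIP inside the ROI)`. A
  zero offset — thresholding at exactly the local mean — would keep
  roughly half of the background pixels of any noisy projection, since
  fluctuations are symmetric about the local mean; scaling the margin
  by the projection's own dispersion adapts it to the residual noise
  level and vanishes for noiseless input. Pixels outside the ROI are
  filled with the ROI median before the local mean is computed so the
  boundary does not bias the threshold. Connected components smaller
  than 5 px (8-connectivity) are removed.

On the default phantom this recovers the vessel mask with Dice ≈ 1.0
noiseless and ≥ 0.95 at default speckle; segmented rBV is within a few
percent of ground truth and fitted $\beta$ within 15%.

## Feature definitions

All intensity/texture/wavelet features are computed on a single
reference image: the per-pixel temporal mean of the denoised
pre-destruction frames. A temporal mean is reproducible, uses the
frames in which bubbles are at plateau, and suppresses residual
temporal noise; any single-frame choice would be noisier and arbitrary.

* **Quantization.** Texture matrices use 32 grey levels, equal-width
  bins over the ROI min–max range, applied per image and per wavelet
  subband.
* **First order (14).** energy, histogram entropy and uniformity (on
  the quantized histogram, log₂), kurtosis and skewness
  (population-normalized moments; both defined as 0 for constant
  input), max/mean/median/min/range, mean absolute deviation, RMS,
  SD, variance.
* **GLCM (19).** Symmetric, normalized co-occurrence matrices at
  distance 1 for the four 2-D directions, pairs restricted to the ROI,
  averaged over directions: autocorrelation, cluster prominence/shade,
  contrast, correlation (1 for a constant ROI), difference entropy,
  dissimilarity, energy, entropy, homogeneity (inverse difference
  moment), IMC1/IMC2, IDMN, maximum probability, sum
  average/entropy/variance, variance, inverse variance.
* **GLRLM (11).** Maximal constant-level runs along the four
  directions (runs break at the ROI boundary), matrices padded and
  averaged over directions: SRE, LRE, GLN, RLN, run percentage,
  LGLRE, HGLRE, SRLGLE, SRHGLE, LRLGLE, LRHGLE.
* **Vascular (15).** Number of vessels (8-connected components), mean
  / median / maximum component size, total vascular area, skeleton
  network length (Zhang–Suen thinning) and branch points (skeleton
  pixels with ≥ 3 skeleton neighbours), mean/SD/max of the Euclidean
  distance from non-vessel ROI pixels to the nearest vessel, rBV,
  rBV periphery and core and their ratio, and flow velocity. The core
  is the innermost 50% of the ROI area obtained by iterative 3×3
  erosion until the area first drops to ≤ 50%. Ten of these are
  classical CEUS morphometry; the other five (total area, max size,
  branch points, the two rBV components) are natural companions that
  complete the class at fifteen, and are documented as such.
  Degenerate inputs are defined, not exceptional: an empty vessel mask
  reports zero counts and the ROI's internal maximum feasible
  distance; a zero core rBV reports the periphery/core ratio as the
  sentinel 0 rather than infinity.
* **Wavelet (176).** One level of the stationary (undecimated)
  coiflet-1 transform gives four same-size subbands A/H/V/D; the 44
  first-order + texture features are computed per subband. 4 × 44
  = 176. The run length nonuniformity of the run-length matrix on the
  diagonal-detail subband (`waveletD_glrlm_RLN`) is the wavelet-class
  analogue of the classical "diagonal RLN" signature feature.

The class partition 14 + 30 + 15 + 176 = 235 is enforced structurally
at extraction time.

## Feature selection

Four rankings are computed per feature, each oriented so rank 1 is
best:

1. **Stability**: concordance correlation coefficient between dataset 1
   and dataset 2, computed per user and averaged over the three users.
2. **Dynamic range**: $DR = \frac1n \sum_i (1 - |t_i - r_i|/R)$ with
   $R$ the pooled range — biological spread relative to repeat
   variability, in [0, 1]; $R = 0$ defines $DR = 0$. Averaged over
   users like the CCC.
3. **User independence**: Quade test across the three delineations
   (scans × datasets as 56 blocks); higher p ranks better. All-constant
   blocks define p = 1.
4. **Discriminative power**: Kruskal–Wallis p across the three models
   on dataset 1 (configurable to dataset 2); lower p ranks better.

The final score is the unweighted mean of the four ranks — the
aggregation is deliberately simple and argument-free — with ties broken
by the stability rank and then the feature name, so the final ranking
is a deterministic permutation. The best-ranked feature per biomarker
class forms the candidate signature; while any pair correlates with
|r| > 0.75 (Pearson, on user-1/dataset-1 values), the worse-ranked
member of the most-correlated offending pair is replaced by the next
candidate of its class. The loop provably terminates or fails loudly
when a class is exhausted. Constant features have undefined r; this is
treated as 0 (no evidence of redundancy) and documented.

## Classification and clustering

The signature columns are z-scored (constant columns map to 0; the
transform is idempotent) and fed to a linear soft-margin SVM (C = 1,
one-vs-one) under seeded stratified 4-fold cross-validation; held-out
predictions are pooled into one confusion matrix, and the accuracy
carries a 95% Wilson score interval. Pooling (rather than averaging
per fold) is what makes a single integer confusion matrix and an exact
binomial n for the interval. With fewer samples per class than folds
the fold assignment falls back to plain random folds.

Unsupervised structure uses Euclidean average-linkage (UPGMA)
clustering of all 235 z-scored features, cut at k = 3. Cluster
composition is tested per cluster with an exact multinomial test
against the overall phenotype frequencies (summing the probabilities of
all compositions at most as probable as the observed one), followed by
per-(cluster, model) exact binomial post-hoc tests with Bonferroni
correction over all post-hoc tests.

## Numerical choices and problem sizes

* Phantom images are 96 × 96 px with 48 frames — large enough for a
  level-3 decomposition and rich vascular morphometry, small enough
  that the full 168-extraction study builds in about a minute; the
  test suite and the acceptance script use this size throughout.
* The replenishment fit starts from `I0 = I(0)`,
  `A = I(end) − I(0)`, `β = 2/t_max` and runs Levenberg–Marquardt with
  non-negativity bounds; a flat curve (SD < 1e−10) short-circuits to
  the degenerate fit A = β = 0 instead of a spurious convergence
  failure.
* All RNG flows through explicit seeds (`withr::with_seed`); the study
  bundle, the feature table, the ranking and the classifier are pure
  functions of the configuration.

## Known limitations

* The phantom's observers differ by morphological perturbations of a
  shared ellipse; real inter-observer variability is richer.
* Velocity is reported in units of `beamWidth` per second; absolute
  velocities require instrument calibration.
* The deepest-level-only BayesShrink variant removes less noise than
  all-level thresholding; it is kept as the package's definition of
  the filter.
* The exact multinomial test enumerates compositions and is intended
  for cluster sizes up to a few dozen samples, not thousands.
* Classification accuracy on phantoms reflects the configured class
  separation; it validates the pipeline, not any claim about real
  tumour models.
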