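---
title: "Multimodal fusion and bag-of-features classification of neuroimaging volumes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal fusion and bag-of-features classification of neuroimaging volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofuse)
```

## The problem

Structural MRI (gray-matter density maps) and FDG-PET (glucose metabolism)
carry complementary information about neurodegeneration. `neurofuse`
implements a discriminative pipeline that classifies subjects into clinical
groups — Alzheimer's disease (AD), mild-cognitive-impairment converters and
non-converters (MCI-C / MCI-NC), and normal controls (NC) — from such paired,
already-preprocessed volumes. The pipeline is:

1. **Dense local descriptors.** Gradient-orientation histograms are computed
   on a regular grid of patches over 2D slices of each volume and pooled per
   volume (a dense-SIFT-style scheme).
2. **Multilayer pyramid.** Descriptors are binned into cells of a two-layer
   spatial hierarchy: layer 1 is the undivided slice, layer 2 a 2×2
   subdivision; the `stacked` mode concatenates both.
3. **Visual vocabulary and encoding.** K-means centroids over pooled training
   descriptors form the vocabulary; each subject becomes a per-cell BoVW
   occurrence histogram and/or a VLAD residual vector
   \(v_k = \sum_{m:\,NN(x_m)=\mu_k}(x_m - \mu_k)\).
4. **Normalization.** Power (signed-root) normalization
   \(x \leftarrow \mathrm{sign}(x)|x|^{\rho}\) with \(\rho = 0.5\), then the
   inter/intra-subject two-step scheme **L2AL2W**: each feature dimension is
   divided by its l2 norm over training subjects (across), then each subject
   vector is scaled to unit norm (within).
5. **CCA fusion.** Regularized canonical correlation analysis finds bases
   \(B^{(1)}, B^{(2)}\) maximizing
   \(\mathrm{corr}(B^{(1)\top}X^{(1)}, B^{(2)\top}X^{(2)})\); the augmented
   representation \(F = [X^{(1)}; X^{(2)}; Z^{(1)}; Z^{(2)}]\) carries both
   modality-individual and shared features.
6. **Kernel maps.** Explicit finite-dimensional maps let a linear SVM emulate
   the Hellinger, chi-square and Jensen–Shannon kernels.
7. **Classification and hybrid fusion.** Linear SVMs are trained per
   representation; BoVW and VLAD decision scores are combined as
   \(S = \alpha S_{BoVW} + (1-\alpha) S_{VLAD}\) with \(\alpha\) chosen on an
   inner split. Evaluation is repeated stratified 10-fold CV reporting
   ACC/SEN/SPEC/BAC/PPV/NPV/AUC as mean ± SD over all folds.

## The synthetic cohort

Real paired MRI/PET cohorts are access-restricted, so the package ships a
generator whose draws stand in for preprocessed volumes. Each subject has a
shared latent vector \(t\) that drives **both** modalities:

* the first latent coordinate carries a disease-severity code
  (NC = 0, MCI-NC = 1/3, MCI-C = 2/3, AD = 1) scaled by `shared_effect`, so
  adjacent clinical stages are closer than the AD/NC extremes and
  conversion prediction is the hardest task, as in real cohorts;
* subject-level shared variability is isotropic with SD
  `0.15 * shared_effect` per latent dimension — scaling it with the effect
  makes `shared_effect = 0` a true null in which the two modalities share
  nothing;
* volumes are an ellipsoidal envelope plus six anisotropic Gaussian blobs per
  modality over a fixed band-limited texture; blob amplitudes and positions
  are linear in \(t\) (the first blob's amplitude loading is exactly the
  severity axis, so the AD-vs-NC amplitude difference at its center equals
  `shared_effect`), with smooth additive noise of SD `modality_noise` and
  clipping at zero;
* feature-space draws (`generate_paired_vectors()`) use orthonormal random
  mixings of the same latent, for unit tests that do not need images.

What the generator does **not** emulate: scanner physics, registration
error, partial-volume effects, non-Gaussian intensity distributions, or
realistic anatomical variability. Passing tests therefore demonstrate that
the pipeline recovers a shared class-informative signal embedded in textured
volumes — not clinical performance on real data.

All randomness derives from one seed through per-subject counter streams, so
cohorts are reproducible and independent of generation order; the `draw`
argument resamples subjects while holding the population (mixings, blob
model) fixed, which is how held-out sets are produced.

## Parameters that matter

| parameter | default | why |
|---|---|---|
| patch / stride / bins | 16 px, 8 px, 4×4×8 (D = 128) | standard dense-SIFT geometry; slices every 2 along axis 3 |
| descriptor clamp | 0.2 then re-l2 | suppresses dominant gradients; after the final rescaling components may exceed 0.2 but never 1 |
| pyramid | 1×1 + 2×2 stacked | keeps per-cell descriptor counts adequate at desk scale |
| K (BoVW / VLAD) | 256 / 64 | exposed in config; the test suite and acceptance script use 64 / 16, matched to cohorts of 40 subjects × 144 descriptors per volume |
| power exponent ρ | 0.5 | the signed square root |
| CCA ε | 1e-3 × mean diagonal of the pooled covariance | the generalized eigenproblem is undefined for singular covariances, inevitable when features outnumber subjects |
| CCA components c | min(d, n−1) truncated at ρ_i ≥ 0.01 | drops numerically dead directions |
| kernel-map order n / period L | 3 / 0.65·n^{−1/2} | the period balances spectrum truncation against periodization so error decreases with order; ~1.5% worst-case relative error at n = 3 |
| SVM C, fusion α | grids {0.01, 0.1, 1, 10} and {0, 0.1, …, 1} | chosen per training fold on one stratified 5-fold inner split |

## Numerical and design choices

* **CCA solver.** For d ≤ n the generalized eigenproblem is solved directly;
  for d > n it is solved in the span of the centered data via thin SVD
  (cost O(n³)), which the encoded representations (up to ~40k features)
  require. Bases are normalized to \(B^\top(\Sigma + \varepsilon I)B = I\);
  per-component signs are fixed so correlations are nonnegative. The test
  suite checks both routes against an independent whitening+SVD oracle at
  1e-8.
* **Second-view projection.** The canonical projection of view 2 applies
  \(B^{(2)}\) to \(X^{(2)}\); pairing it with \(X^{(1)}\) would make the
  second projection redundant with the first and is treated as a notational
  slip in the source material.
* **CCA stage.** By default CCA runs on the encoded, normalized per-modality
  vectors (`cca_stage = "encoded"`), which is fully determined by the
  equations above. The alternative `"input"` stage fits CCA on flattened
  voxel intensities of the training fold and renders each subject's volumes
  reconstructed through the canonical subspace
  (\(\hat X = (\Sigma + \varepsilon I) B Z + \mu\)); these canonical
  pseudo-modalities re-enter descriptor extraction and are concatenated with
  the originals. Both are provided because the flowchart-level and
  equation-level descriptions of the method differ; `encoded` is the default
  as the unambiguous one.
* **Stage order.** encode → power → L2AL2W → CCA/augment → kernel map →
  SVM. Power-then-l2 is the established convention for super-vector
  encodings. The nonlinear chi2/JS maps require nonnegative input, so they
  are valid only for BoVW-encoded representations without CCA blocks; the
  config validator enforces this rather than silently shifting negative
  values.
* **L2A divisors** come from training subjects only and are reused on test
  subjects — the scheme is defined cohort-wide, but computing divisors on
  test data would leak fold information.
* **Hard assignment** to the nearest visual word (ties to the lowest index);
  flat patches yield the zero descriptor and fall in whichever cluster owns
  the origin. The k-d forest (4 randomized trees, best-bin-first search with
  a bounded examination budget) accelerates queries for large vocabularies;
  the default budget `max(64, K)` keeps agreement with the exact scan at
  ~100% on correlated descriptor data, and the exact linear scan is the
  encoder default at desk scale.
* **Gram-domain SVM.** Inside CV all linear SVMs are solved through the
  subjects' Gram matrix (identical dual solution, verified against the
  explicit solver), so fit cost is O(n³) regardless of feature count.
  Decision values are oriented positive toward the disease class; zero
  decision values predict the positive class.
* **Inner selection.** C and α are selected on one stratified 5-fold split
  of each training fold, reusing the fold-level transforms (codebooks,
  normalization, CCA) fitted on the whole training fold. This trades a
  small optimistic bias in the *inner* selection signal for an order of
  magnitude less refitting; the outer test fold never influences any fitted
  component, which the leakage tests assert bit-wise.
* **Stratified folds** (the source material says only "randomly
  partitioned"): with imbalanced classes and desk-scale cohorts,
  unstratified folds frequently lose a class entirely.
* **SD aggregation**: reported SDs are across all k × repeats fold metrics,
  and are labeled as such in the report.

## Problem sizes used by the tests

The acceptance checks run the full pipeline on cohorts of 20 subjects per
class with 32³ volumes (40 subjects per binary task, 144 descriptors per
volume, K = 64/16), 10-fold CV over 3 generator seeds, with the strong
cohort at a shared effect 5× the modality noise SD. Feature-level checks
(CCA oracle, augmentation tendency) use d ≤ 10, n ≤ 500. These sizes were
chosen so the whole suite runs in minutes on one core while keeping at
least ~40 held-out predictions behind every reported accuracy.

## Known limitations

* 2D slice-wise descriptors, not 3D; no keypoint detection, no soft
  assignment, no Fisher vectors.
* Binary tasks only; no multi-class decision rule.
* The synthetic cohort is a stand-in: parameters of real GM/PET intensity
  distributions are unknown here, and no claim about ADNI-scale accuracy
  follows from these tests.
* PPV/NPV are reported as missing (not zero) when a fold has no positive or
  negative predictions; with 4-subject test folds this occurs occasionally.
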