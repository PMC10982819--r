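---
title: "Weakly supervised lymph-node staging: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weakly supervised lymph-node staging: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Preoperative N staging of rectal cancer asks, for each patient, whether any
pelvic lymph node harbours metastasis (binary staging) and roughly how many
do (ternary N0 / N1 / N2 staging, with N1 = one to three and N2 = four or
more metastatic nodes). Node-by-node pathological ground truth is
essentially unobtainable in retrospective series: nodes resected at surgery
cannot be matched one-to-one with nodes seen at MRI. What the pathology
report does provide, per patient, is the number of resected nodes and the
number of metastatic nodes among them.

`milstage` trains *node-level* metastasis classifiers from exactly that
patient-level information. A patient is a *bag* of MRI-visible nodes
(instances); the model scores every node with a metastatic probability
$p_i \in [0,1]$ and couples the bag of scores to the two patient-level
targets through two pooled heads:

* **MIL head (max pooling).** The node with the highest probability,
  $p^{\max} = \max_i p_i$, is matched to the binary patient label $y$: if
  the patient has any confirmed metastasis, the most suspicious node should
  be positive; if not, even the most suspicious node should be negative.
* **LLP head (average pooling).** The mean probability
  $p^{\mathrm{avg}} = \frac{1}{n}\sum_i p_i$ is matched to the metastatic
  proportion $\rho = k / m$ among the $m$ resected nodes with $k$
  metastatic. This "learning from label proportions" term calibrates the
  *count* of positive nodes, which the MIL term alone leaves free.

The loss for one bag is

$$L \;=\; \lambda_{\mathrm{mil}}\,\mathrm{BCE}(p^{\max}, y)
      \;+\; \lambda_{\mathrm{llp}}\,\mathrm{BCE}(p^{\mathrm{avg}}, \rho),$$

with soft-target binary cross-entropy
$\mathrm{BCE}(p,t) = -[t\log p + (1-t)\log(1-p)]$ and probabilities clamped
at $10^{-7}$. Both heads default to weight 1. BCE was chosen for both heads
because both targets live in $[0,1]$ and it subsumes the usual binary case;
a squared-error proportion loss would be a one-line change in
`weakSupervisionLoss()` but was not needed. Gradients flow to the arg-max
node through the MIL head and to every node through the LLP head.

## Model variants

* `M_I` — the intensity model: a small residual convolutional network maps
  each (robustly normalized) T2-weighted node patch to a logit. The
  architecture is a stem 3×3 convolution, a max-pooled residual stage, a
  widening 3×3 convolution, a second max-pooled residual stage, global
  average pooling and a linear read-out (defaults 8 and 16 channels). The
  second convolution of each residual block is zero-initialized so every
  block starts as the identity. Max pooling was chosen for the spatial
  downsampling because the discriminative texture is focal (a few pixels)
  and average pooling dilutes it.
* `M_IS` — the integrated intensity + size model: a one-hidden-layer
  perceptron (8 ReLU units) over the standardized features
  $[\mathrm{logit}(p_I), \text{long diameter}, \text{short diameter},
  \text{short/long ratio}]$, trained under the identical bag loss with the
  intensity network frozen. The intensity probability enters on the logit
  scale so that an exact pass-through of the intensity model is inside the
  hypothesis class.
* `M_ISA` — adds the mean apparent diffusion coefficient (ADC, in
  $10^{-3}\,\mathrm{mm^2/s}$) as a fifth feature.

Feature standardization statistics are frozen on the training bags
(leakage guard). The decision threshold $\tau$ maximizes Youden's J of
$p^{\max}$ against $y$ on training bags only, and is then reused to count
positive nodes at prediction time: $\hat k = \#\{i : p_i \ge \tau\}$,
$\widehat{\text{stage}} = \mathrm{N0/N1/N2}(\hat k)$, patient ROC score
$= p^{\max}$. The predicted count $\hat k$ is also the default ordinal
score for the ternary concordance index (the discrete predicted stage is
an accepted alternative and gives the same concordance up to ties).

## Optimization

Mini-batches are whole bags; the optimizer is Adam
($\beta_1 = 0.9, \beta_2 = 0.999$, learning rate $5\times10^{-3}$) with
global gradient-norm clipping at 5 and a 0.3× learning-rate decay after
75% of the epochs. The weakly supervised loss surface has a conspicuous
constant-probability plateau (predict the base rates for every node);
whether a run escapes it depends on the initialization. Training therefore
probes `nStarts = 3` random initializations for `warmupEpochs = 6` epochs
each and trains the one with the best validation bag loss to completion,
keeping the best-validation weights (early stopping patience 12 epochs,
20% of bags held out). The fusion perceptron gets the same multi-start
treatment, with two extra safeguards: one candidate is warm-started at the
exact identity mapping of the intensity probability, and the untrained
identity itself competes in the final validation-loss selection — so a
fused model can only match or improve on its intensity backbone under the
selection criterion. All randomness (initialization, splits, shuffling)
derives from the single `seed` in `modelConfig()`; training is exactly
reproducible.

The convolutional network and its backpropagation are implemented in
C++ (RcppArmadillo), evaluating each 3×3 convolution as nine shifted
GEMMs over a zero-padded buffer. A finite-difference check in the test
suite verifies the analytic gradients to ~1e-8 relative error.

## The synthetic cohort generator

The generator (`simulateCohort()`) reproduces the population structure the
weak supervision relies on, with defaults matching the cohort the package
targets:

* visible nodes per patient: rounded normal, mean 14, SD 5, truncated to
  5–50;
* patient-level metastasis rate 0.39;
* metastatic count for positive patients: zero-truncated negative binomial
  with positive-patient mean 4.1 and dispersion 1.4, capped at 35 — chosen
  because a Poisson cannot produce an SD near 3.2 at an overall mean near
  1.6, which these defaults reproduce ($0.39 \times 4.1 \approx 1.6$);
* per-node geometry: log-normal short axis (benign median ≈ 4.2 mm, log-SD
  0.35, metastatic axes multiplied by `sizeEffect`, default 1.6), a
  Beta-distributed short/long ratio in (0.35, 0.95);
* ADC: Gaussian, benign mean 1.0, SD 0.15, metastatic shift `adcEffect`
  (default +0.25, i.e. model-suspicious nodes have *higher* ADC, matching
  the direction reported for model-defined metastatic nodes; the sign is a
  parameter);
* image patches: each node is rendered the way the extraction stage
  produces patches — a crop of twice its bounding box resampled to a fixed
  `patchPx` grid — so the node always spans about half the patch and
  absolute size lives in the millimetre features, not in the image. The
  patch is background noise (0.40 ± 0.12) plus nodal signal (+0.25);
  metastatic nodes additionally receive one Gaussian blob of amplitude
  $0.3 \times$ `textureEffect`, intranodal with probability 0.6 and
  perinodal otherwise, emulating focal heterogeneous intensity. At
  `textureEffect = 0` metastatic and benign patches are drawn from
  identical distributions.
* `hiddenNodeRate` adds resected-but-invisible nodes (Poisson), which may
  be metastatic: the LLP denominator then genuinely mismatches the visible
  bag, as it does in real data. The default is 0 so that recovery
  experiments have exact node-level truth.

One master seed drives hierarchical per-patient and per-node substreams,
so cohorts are reproducible and independent of generation order.

What the generator deliberately does **not** emulate: 3-D anatomy and
volumetric partial-volume effects, scanner- and protocol-specific noise,
mucinous nodes, inter-reader segmentation variability, and any correlation
between nodal texture and size beyond what the latent label induces.
Passing the recovery tests therefore shows that the weak supervision
mechanism works when its assumptions hold — not that any particular
real-cohort performance number would be reproduced.

## Morphometry conventions

Diameters are measured on the convex hull of the foreground *pixel
corners* (so a 40 × 10 px axis-aligned rectangle at 0.5 mm/px measures
exactly 20 × 5 mm), with pixel indices converted to millimetres before any
geometry, handling anisotropic spacing exactly. The default axis
convention is the rotated bounding rectangle oriented along the *minimum
caliper width*. The more familiar minimum-*area* rectangle is numerically
treacherous on rasterized masks: for mid-eccentricity ellipses the
smallest-area box can sit diagonally (a 15.3 × 8.6 px ellipse admits a
12 × 12 px box), misstating the long axis by several pixels, whereas the
minimum-width orientation coincides with it on rectangles and elongated
shapes and is stable under rasterization (worst observed round-trip error
about 1.25 px, typically under 1 px; half a pixel of that is the corner
convention itself). A pure caliper convention (maximum Feret diameter +
minimum width) is available via `method = "caliper"` and is what the
brute-force oracle in the test suite reproduces exactly. Degenerate masks
follow documented conventions: a single pixel measures one pixel's extent
in both axes; an empty mask is an error.

## Interpretability

Grad-CAM maps are computed from the intensity network only (the fusion
perceptron has no spatial structure): the last convolutional feature maps
are weighted by the spatial mean of the logit gradient, rectified,
bilinearly upsampled to the patch grid and min–max normalized, with an
all-zero map passed through unchanged. Hotspots are classified by
thresholding at half the map maximum ("highlighted" is not otherwise
defined, so the 0.5 level is a fixed documented choice) and asking where
the supra-threshold pixels fall: inside the mask (intranodal), in a
morphological dilation ring of 3 mm (converted at the pixel spacing;
`ringPx = ceiling(3 / spacing)`), or outside, with ties broken
intranodal > perinodal > outside. The rule is invariant to monotone
rescaling of the map.

## Evaluation suite

All statistics are implemented with brute-force-verifiable definitions:
midrank AUC (equal to the half-credit pair count), DeLong's
placement-value test for correlated ROC curves (two-sided normal p value;
identical score vectors return p = 1 with a degeneracy flag), count MAE,
the ternary concordance index with half credit for prediction ties,
Cohen's kappa with marginal-product expected agreement, per-class and
macro F1 with the zero convention for empty classes, equal-width-bin
calibration tables (empty bins emitted with count 0), and decision curves
with net benefit $TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and
treat-none references. Confidence intervals are 2000-replicate percentile
bootstraps, stratified by class for the AUC, under a fixed seed; the CI
method is a package choice. Sensitivity and specificity are reported at
the training-derived threshold and never re-optimized on test data.

## Problem sizes and stochastic checks

The test suite validates instance-label recovery on a 300-bag training /
100-bag held-out cohort with strong texture signal (`textureEffect = 3`,
five training seeds, node-level AUC against the latent truth), chance
behaviour on a matched null cohort (no texture, size or ADC signal),
variant ordering (M_I ≤ M_IS ≤ M_ISA in mean patient AUC) on 150/80-bag
cohorts constructed so size and ADC carry signal independent of the image
(`textureEffect = 1.2`, `sizeEffect = 1.8`, `adcEffect = 0.35`), and the
LLP ablation (count MAE with the proportion head on vs off) on a
150/80-bag moderate-texture cohort. These sizes give stable averages over
five seeds while keeping a full run of the suite on a single CPU
comfortably under half an hour; larger cohorts sharpen the estimates but
do not change the qualitative outcomes.

## Known limitations

* The simulator is 2-D and stylized; its effect sizes are parameters, not
  facts about any real cohort, and real-data performance claims cannot be
  derived from it.
* With `hiddenNodeRate > 0` the LLP target is systematically mismatched
  to the visible bag; the model tolerates moderate rates but node-level
  truth is then only partially observable.
* The residual network is sized for 32 × 32 patches on a CPU; it is not a
  drop-in for full-resolution 3-D volumes.
* Near-circular nodes have intrinsically ill-defined long-axis
  orientation; both axis conventions return diameter-like values, but
  their attribution to "long" vs "short" is unstable exactly when the two
  are nearly equal.
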