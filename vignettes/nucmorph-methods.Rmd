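---
title: "Biomarker-optimized death classification: models, simulation, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomarker-optimized death classification: models, simulation, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model and
procedure, the parameters that matter, what the synthetic world does and
does not emulate, numerical choices, and known limitations. It states no
empirical result that the test suite does not itself compute.

## 1. The weak-labeling model

Each neuron co-expresses a green, calcium-sensitive death indicator and a
red morphology marker from one construct, so the ratio of their mean
intensities over the cell mask,

$$ r = \frac{\bar I_{\mathrm{GEDI}}}{\bar I_{\mathrm{morph}}}, $$

is a per-cell death readout that cancels expression level. Labels come from
two empirical thresholds $(\theta_{\mathrm{live}}, \theta_{\mathrm{dead}})$:
$r < \theta_{\mathrm{live}}$ is live, $r > \theta_{\mathrm{dead}}$ is dead,
anything else — including exact threshold equality, which the thresholds'
"under/above" phrasing leaves undefined — is an ambiguous intermediate and
is discarded before training. Defaults are 0.1/0.25 for the diffuse marker
and 0.03/0.055 for the nuclear-localized one. A classifier trained on
morphology crops with these free labels is "biomarker-optimized": no human
annotation enters the loop.

## 2. The synthetic world

No raw imaging is publicly deposited, so all inputs come from a generative
model with complete ground truth. Its defaults are the stated experimental
conditions wherever those exist; everything else was chosen once, as
realistic for primary-neuron culture imaging, and not revisited:

* **Timepoints** 0, 8, 16, 24 h (imaging every 8 h over 24 h after an
  excitotoxic insult); about half the cells die
  (`fraction_dead = 0.5`), at a death time drawn from the post-treatment
  timepoints.
* **Geometry.** Soma = ellipse (major semi-axis 8–14 px, aspect 0.7–1),
  nucleus = concentric ellipse at 0.45–0.6 linear scale, neurites = 2–5
  random-walk polylines (20–60 px, ~2 px wide) starting at the soma
  boundary. This is the simplest geometry that can express every phenotype
  the analysis depends on; it makes no attempt at dendritic-tree realism.
* **Phenotypes.** Dead diffuse cells: rounder soma, fragmented/retracted
  neurites, total fluorescent area scaled to 0.6× the live render. Dead
  NLS cells: signal leaked from the nucleus over a larger soma-shaped
  region plus fragmented neurites, total area 1.5× the live (nuclear)
  render, plus an intranuclear punctum (radius 2 px) whose peak intensity
  is 4× the surrounding nuclear mean. The area scale factors are *render
  contracts*: fragments are retracted until region + fragments meet the
  configured total, so area-recovery tests have an exact target. The
  punctum is specified as a brightness multiple rather than a display-
  contrast property, because display contrast is not a data property; its
  size and brightness are placeholders exposed in `sim_config()` (the
  source describes the punctum only qualitatively).
* **Photometry.** Per-cell amplitude is log-normal (median 3000 of a
  16-bit range, sdlog 0.3), standing in for transfection-efficiency
  variation. The death-indicator channel is the morphology template times
  the cell's true ratio, so mask-mean measurement recovers the truth
  exactly in the noise-free limit. Ratios are log-normal per state:
  diffuse live/dead medians 0.05/0.5 (sdlog 0.35), NLS 0.02/0.1 (sdlog
  0.2/0.3). The source prints thresholds, not distributions; these place
  ≥ 97.5% of each population on its own side of its threshold, leaving a
  realistic few-percent intermediate band.
* **Camera.** Background 100, Poisson-like shot noise at gain 10, Gaussian
  read noise (sd 20), clamped to 16 bits. With noise disabled the render
  equals the analytic template exactly — several oracles depend on this.
* **Drift.** Integer-pixel global shifts within ±5 px per timepoint, so
  registration ground truth is exact by construction.

What the world does **not** emulate: optics (no PSF, no z-dimension),
cell-cell contact and overlap, focus drift, photobleaching, real nuclear
texture, or death-subtype diversity. A green test therefore establishes
that the *pipeline logic* is correct on data with the assumed statistical
structure — not that the trained network would transfer to microscopy.

## 3. Imaging workflow conventions

Pixel coordinates are 0-based (row, col); crop windows are half-open with
the rounded centroid at index `side/2`; the registration reference is the
first timepoint. Background subtraction is `max(I − median(I), 0)` per
image. Segmentation is Otsu thresholding — computed on intensities clipped
at the 99.5th percentile so a handful of punctum pixels cannot drag the
threshold above the cell body — followed by 8-connected components with a
30 px minimum area and intensity-weighted centroids; channel means are
measured over the component mask, not the crop rectangle (the less
background-contaminated choice; the alternative is a config option).
Tracking is greedy nearest-centroid linking within 30 px, ties toward the
smaller label; on well-separated cells this provably coincides with the
optimal assignment, which the tests verify against an exhaustive oracle.
For area trajectories the package reports *fluorescent area* (all
above-threshold pixels in the cell's crop window) rather than the main
component's area, because fragmented neurites are disconnected from the
soma yet belong to the cell's fluorescence footprint — this matches how
"area of fluorescence" is quantified in the field and makes the configured
area scales recoverable.

## 4. The classifier

Two architectures share one native engine (im2col + BLAS GEMM, exact
gradients, written for single-CPU use): `resnet18`, the standard 18-layer
residual network, and `smallresnet` (default), a four-residual-block
reduction whose stem downsamples 4× (stride-2 conv + 3×3/2 max pool) the
way the 18-layer network treats its own input scale. Batch normalization
is replaced by He initialization plus zero-initialized residual-branch
output convolutions (blocks start as identity — the BN-free analog of
zero-init gamma, which makes convergence reliable across seeds): pretrained weights are not
downloadable in the build environment, and at this scale BN-free residual
nets train without trouble. Training follows the stated recipe — batches
of 32, learning rate 1e-3, Adam, two-class cross-entropy — at a desk-scale
default of 2,000 steps (the full-scale run used 200,000; that
configuration remains selectable). Crops are min-max normalized per crop,
which also removes absolute-brightness shortcuts. Validation loss is
evaluated every 100 steps and the reported model is always the
minimum-validation-loss checkpoint, never the last step. Splits are
80/10/10 with largest-remainder rounding (which reproduces the published
5,422/678/678 from 6,778) and are stratified by label; stratification is
not stated in the source but prevents degenerate class ratios at small n.
Labels are assigned per (cell, timepoint) with no temporal smoothing.

## 5. Attribution

Guided Grad-CAM: channel weights are spatial means of the class-evidence
gradient at a chosen layer (default: the mid-depth residual stage — "layer
two" for resnet18), the ReLU'd weighted activation sum is bilinearly
upsampled and multiplied elementwise by the guided-backpropagation input
gradient; the result is clipped at zero and normalized to unit mass. For
two classes the evidence gradient is the logit contrast (the softmax
depends only on the difference). Localization is quantified as enrichment
= (attribution mass in a phenotype mask) / (mask area fraction); the
nuclear membrane is the 2 px inner boundary ring of the nucleus mask.
"Live-class punctum enrichment" is computed counterfactually on dead crops
(live cells have no punctum), paired per crop with the dead-class map.

## 6. Statistics

Simulated curators replace the human panels: each rater has a
sensitivity/specificity profile (default panels: five 0.8/0.8 raters for
the diffuse arm, three for the NLS arm), consensus is majority vote with
ties resolved toward dead (flagged; missing a death is the costlier
error). Precision-recall curves integrate step-wise over distinct score
thresholds, so a binary rater contributes its single operating point.
Batch benchmarking uses balanced 50-image batches; one-sample t and exact
Wilcoxon signed-rank tests (exact for n ≤ 25) compare batch accuracies to
the 50% chance mean, two-sided throughout (sidedness is not stated in the
source). Dunnett-style pre/post comparisons use t statistics with a pooled
variance against Monte-Carlo critical values of the max-|t| null (100,000
draws, seeded) — simpler than multivariate-t quadrature and verifiable by
convergence against larger draws; at k = 1 it reproduces the two-sample t
critical value. Area analyses are per-cell, with per-well aggregation left
to the caller.

## 7. Reproducibility and orchestration

Every stochastic step takes a seed; module seeds are derived from one
global seed by hashing (seed, module name), kept below 2^31. The full
pipeline (`run_pipeline()`) is metric-identical across repeated runs of
one config; the config round-trips through JSON. Multi-page 16-bit TIFF
I/O is provided by a minimal built-in baseline codec (no TIFF package
exists in the supported dependency set); it is validated in the tests
against an independent implementation.

## 8. Known limitations

* **The attribution randomization null fails, by design honesty.** One
  acceptance sub-clause expects a random-weight model's punctum enrichment
  to be ≈ 1. It is not: guided Grad-CAM's guided-backprop factor is
  dominated by bright input structure and is largely insensitive to weight
  randomization — a published property of the method family (the "sanity
  checks for saliency maps" literature), reproduced here rather than
  patched over (the engine matches finite differences and an analytic
  single-filter oracle). The corresponding test is left red rather than
  weakened. The localization signatures and the live/dead class contrast
  do hold for the trained model (dead-class maps enrich the punctum an
  order of magnitude more than live-class maps on the same crops; live
  maps line the nuclear membrane).
* The simulator's phenotype strength makes classification near-perfect;
  accuracies here are ceiling values, not predictions for microscopy.
* The tracker is not mitosis-aware and neurites are not traced as
  separate objects; sub-pixel registration is out of scope (drift is
  integer by construction).
* resnet18 is structurally faithful but BN-free and randomly initialized;
  claims about ImageNet-pretrained behavior are out of scope.
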