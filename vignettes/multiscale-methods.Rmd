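---
title: "Methods: multiscale uncertainty-aware tumor characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale uncertainty-aware tumor characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histomulti)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the design decisions taken where the design was
genuinely open, and what the synthetic experiments do and do not show.

## The pipeline

A patch pair couples a 10× field (tissue architecture) with the
co-registered 40× view of its central quarter (cellular detail; the 4×
linear scale matches the objective ratio). Two encoders produce
representations `Z10` (convolutional feature map) and `Z40` (transformer
tokens with per-layer, per-head attention). Five mechanisms act on these:

1. **Uncertainty-aware consistency (PAUAC).** Each branch's Monte Carlo
   head runs `T` stochastic passes under dropout; the predictive
   distribution is the pass mean and its Shannon entropy the uncertainty.
   The loss is the unit-mean of `w_j * KL(P10_j || P40_j)` with
   `w_j = exp(-alpha * (H10_j + H40_j))`, so the model is pushed toward
   cross-magnification agreement mostly where it is confident, and
   inherently ambiguous regions are not over-penalized.
2. **Structural attention regularization (SACGR).** Superpixels (SLIC)
   become graph nodes; spatially adjacent superpixels are joined with
   Gaussian color-kernel weights, sparsified to at most 8 neighbors per
   node. Transformer attention is head-averaged, symmetrized, pooled to
   node pairs by token-pair means, row-normalized, and penalized by the
   mean squared deviation from the equally row-normalized tissue adjacency.
   A companion smoothness term averages `A_ij ||f_i - f_j||^2` along edges.
3. **Curriculum scheduling (MPCS).** Patch complexity combines the
   grayscale histogram entropy (bits, 256 bins, luminance
   `0.299R + 0.587G + 0.114B`) with the population variance of nucleus
   counts over an 8x8 subtile grid (densities in nuclei per pixel).
   Selection probability is a sigmoid around a threshold `mu_t` set to a
   ramped quantile of the pool's scores.
4. **Morphometry fusion (TDMM).** Nucleus centroids induce an exact
   discrete Voronoi tessellation; per-pixel channels are region area,
   distance to the nearest centroid, and the owning region's neighbor
   count, each min-max normalized. Morphometry tokens are fused into image
   tokens by single-head scaled-dot-product cross-attention and classified
   by a two-layer perceptron on the mean-pooled fused embedding.
5. **Positional contrastive alignment (CCCRA).** Within a patch pair, each
   40× token and the co-registered cell of the 10× feature map are a
   positive pair; the other tokens are negatives. Scores are
   `(cos(z_i, z_j) + gamma * cos(p_i - 0.5, p_j - 0.5)) / tau` and the loss
   is InfoNCE with the positive included in the denominator.

Training minimizes
`L_sup + lambda1 * L_PAUAC + lambda2 * L_SACGR + lambda3 * L_CCCRA`
with AdamW, linear warm-up and cosine decay, early-stopping on validation
Dice when masks are available (validation AUC otherwise).

## Parameters

| Parameter | Default | Units / range | Notes |
|---|---|---|---|
| `T_mc` | 10 | passes | Monte Carlo passes per head |
| `dropout_rate` | 0.3 | — | MC heads only, not the encoders |
| `alpha` | 1.0 | per nat | PAUAC sharpness; no published value exists, so it is exposed and documented |
| `tau` | 0.07 | — | InfoNCE temperature |
| `gamma` | 0.3 | — | positional sensitivity |
| `max_neighbors` | 8 | edges/node | graph sparsification |
| `color_bandwidth` | 51 (`0.2*255`) | 8-bit color units | Gaussian edge kernel |
| `lambda1, lambda2, lambda3` | 1.0, 0.5, 0.5 | — | composite weights; unpublished, exposed in config |
| `smoothness_weight` | `0.1*lambda2` | — | companion term scale |
| `beta` | 1.0 | per `xi` unit | curriculum sigmoid steepness |
| `lambda^1, lambda^2` (complexity) | 1, 1000 | — | put entropy (~4 bits) and density variance (~1e-3) on a common O(1) scale |
| quantile ramp | 0.2 → 0.8 over half the epochs | — | threshold schedule |
| `lr`, `weight_decay` | 1e-4 (desk runs 1e-2), 0.01 | — | AdamW; betas (0.9, 0.999) |
| `hidden_dim`, `n_heads` | 768/12 at full scale; 32–64/4 desk-scale | — | both reachable through `encoder_config()` / `model_config()` |

Entropy is reported in **bits** throughout (the curriculum threshold scale
of ~4 bits presumes an 8-bit alphabet); inside the PAUAC weight, entropies
are converted to nats so `alpha` shares the natural-log scale of the KL
term.

## The synthetic generator

`slide_spec()` + `generate_patch_pair()` render a high-resolution canvas:
low-frequency smoothed Gaussian noise in an eosin palette, elliptical
hematoxylin nuclei, and (with probability `tumor_fraction`) an elliptical
tumor blob holding denser, more pleomorphic nuclei whose center always
lies inside the 40× field of view. The 40× patch is the central
quarter-side crop at native resolution; the 10× patch is the 4× block-mean
downsample of the whole canvas, so co-registration is exact by
construction (observed mean absolute error is quantization-level, well
under the 8/255 contract). Masks, centroid tables (0-based `x,y,radius,cls`
in the 40× frame) and JSON manifests give complete ground truth, and
identical spec + seed reproduce files byte-for-byte.

What the generator does *not* emulate: stain physics and scanner
characteristics, tissue folds, bubbles and other artifacts, nucleus
clustering/overlap beyond density changes, and the label noise of human
annotation. Passing tests therefore demonstrate the correctness and the
qualitative behavior of the mechanisms — not clinical performance on real
slides. The default conditions (512 px canvas at full scale, 256 px in the
desk-scale studies; 60 background vs 180 blob nuclei; radius 6 ± 1.5 px;
`tumor_fraction` 0.5) make the classification task intentionally learnable
so that training dynamics, not task noise, dominate the studies.

## Numerical choices

- KL uses the natural log with `1e-12` flooring of the denominator
  distribution; `0 log 0 := 0`. The loss aggregates units by the mean so
  composite weights transfer across batch sizes. The structural loss is
  likewise a mean over ordered off-diagonal node pairs.
- Both the tissue adjacency and the attention adjacency are row-normalized
  before comparison; a symmetric pre-normalization matrix (`W`) is kept
  alongside, and the smoothness term uses it. (A matrix cannot be
  simultaneously symmetric and row-stochastic in general; keeping both
  resolves that tension explicitly.)
- Voronoi ownership is exact brute-force nearest-centroid on the pixel
  grid; ties go to the lowest centroid index. Constant morphometry
  channels min-max-normalize to zero.
- Attention source for SACGR is the last encoder layer, head-averaged
  (`layer_set = "all"` averages all layers).
- Quantiles use R's type-7 (linear interpolation) convention.
- The 40×-branch dense prediction used for Dice works at token resolution:
  per-token class probabilities against the block-majority downsampled
  mask.
- Positions for the contrastive loss are centered at `(0.5, 0.5)` before
  the cosine so raw coordinates do not collapse to all-positive
  similarities; an entity exactly at the center contributes positional
  similarity 0.

## Design decisions in open territory

- **KL direction** defaults to `KL(P10 || P40)` as printed in the source
  formulation; a symmetric variant is available (`direction =
  "symmetric"`).
- **Curriculum direction.** The printed selection sigmoid gives *high*
  probability to *complex* samples, which contradicts easy-to-hard
  training. `sample_batch()` therefore blends from `1 - P_select` weights
  to `P_select` weights linearly over the ramp; both raw modes remain
  available (`mode = "anti"` / `"pro"`).
- **Cell-level contrastive granularity.** An earlier patch-level wiring
  (one pooled embedding per pair) proved unlearnable: pooled outputs of two
  unrelated frozen encoders share no pair-specific signal, and the InfoNCE
  loss stayed at `log N`. The shipped design pairs each 40× token with the
  co-registered 10× feature cell — the same tissue at the same location —
  which learns reliably and matches the stated cell-level intent.
- **Cross-magnification NMI** is computed on these cell-level embeddings
  (k-means, k = number of classes, seeded, 10 restarts). Patch-level
  clusterings sit at the NMI ceiling whenever both views separate the
  classes, which makes the metric blind exactly where it should
  discriminate.
- **Smoothness gradient routing.** Letting the smoothness term's gradient
  flow into the attention logits measurably *fought* the structural loss
  (it rewards attending to similar features anywhere). The companion term
  therefore updates the value projections only; attention shape belongs to
  the structural MSE.
- **Ablation bookkeeping.** A parameter group whose loss is switched off
  receives no optimizer update at all — not even weight decay — so each
  ablation mode leaves the untouched module exactly at initialization, and
  comparisons isolate the intended effect. Training-dynamics quantities
  (validation KL, off-graph mass, NMI) are read from the final epoch;
  headline Dice/AUC from the early-stop checkpoint.
- **Backbones.** The full-scale pretrained encoders are out of scope;
  the package trains the MC heads, the last attention layer's projections,
  the contrastive projections and the fusion block over frozen random
  reference encoders. This isolates the five mechanisms, which is the
  package's subject.

## Problem sizes in the shipped studies

The test-suite studies use 128–256 px canvases (32–64 px patches, 4–16
tokens), 24–200 patch pairs, 2–10 epochs and 3–5 seeds; the curriculum
study uses a 500-patch pool. The acceptance script trains the full model
and three ablations on 120 pairs over three seeds. These sizes make the
full suite reproducible in minutes on one CPU while keeping every
qualitative effect (consistency, attention shaping, curriculum ordering,
alignment) measurable and seeded.

## Known limitations

- Frozen random backbones bound achievable absolute performance; the
  package's claims are directional and structural, not benchmark-level.
- The trainer is classification-first; dense segmentation is represented
  at token resolution only.
- SLIC here is a compact reimplementation (grid-seeded local k-means with
  adjacency-constrained color merging), adequate for regularization
  studies but not tuned for boundary recall on real tissue.
- Single-head cross-modal fusion by default (multi-head available through
  configuration).
- The contrastive batch draws negatives within a patch pair; memory banks
  or cross-pair negative pools are out of scope.
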