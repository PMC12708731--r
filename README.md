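# histomulti

Multiscale, uncertainty-aware tumor characterization for paired-magnification
histopathology, as a tested R library with a desk-scale trainer and a fully
synthetic data generator.

## The problem

Whole-slide images are read at several magnifications at once: low power
(10×) shows tissue architecture, high power (40×) shows nuclear detail. A
model that classifies or segments tumor from patch pairs should (i) make
*consistent* predictions across magnifications, (ii) attend along
*histologically plausible* neighborhoods rather than spurious texture, (iii)
learn *easy-to-hard*, (iv) exploit *nuclear morphometry* alongside stain
appearance, and (v) keep the two magnifications' *representations aligned*
at the cell level. `histomulti` implements these five mechanisms as
composable losses, schedulers and metrics:

- **PAUAC** — uncertainty-aware consistency. Each branch runs `T` Monte
  Carlo dropout passes; the predictive distribution is
  `P(y|X) = (1/T) Σ_t softmax(h_t(Z))`, its Shannon entropy `H` quantifies
  uncertainty, and the consistency loss is the mean of
  `w_j · D_KL(P_j^(10) ‖ P_j^(40))` with `w_j = exp(−α (H_j^(10) + H_j^(40)))`,
  so confidently inconsistent units are penalized hardest.
- **SACGR** — structural attention regularization. SLIC superpixels form a
  tissue graph `G = (V, E)` with Gaussian color-kernel edge weights
  (sparsified to ≤ 8 neighbors per node); transformer attention is pooled to
  node pairs and penalized by `mean (A_ij − A_ij^attn)²`, with a companion
  smoothness term `Σ A_ij ‖f_i − f_j‖² / Σ A_ij` along edges.
- **MPCS** — curriculum scheduling. Patch complexity
  `ξ = λ¹·E(X) + λ²·σ²_nuc(X)` combines texture entropy (bits) with
  nuclei-density variance; selection follows the sigmoid
  `P_select = 1/(1 + exp(−β (ξ − μ_t)))` with a quantile-ramped threshold
  `μ_t`, sampling easy patches first and hard ones later.
- **TDMM** — morphometry fusion. Discrete Voronoi tessellation of nucleus
  centroids yields per-pixel area / distance / neighbor-count channels;
  image and morphometry tokens are fused by cross-attention
  `F = softmax(Q K'/√d_k) V` with `Q = E_img W_Q`, `K = E_morph W_K`,
  `V = E_morph W_V`, then classified by a small MLP.
- **CCCRA** — positional contrastive alignment. Cell-level embeddings of the
  same tissue location at both magnifications are positives in an InfoNCE
  loss over combined scores `(sim(z_i, z_j) + γ·sim(p_i, p_j))/τ`
  (cosine similarity, τ = 0.07, γ = 0.3).

Everything is trained under the composite objective
`L_total = L_sup + λ¹ L_PAUAC + λ² L_SACGR + λ³ L_CCCRA` with AdamW
(lr 1e-4 at paper scale, weight decay 0.01, warm-up then cosine decay) and
evaluated with Dice, AUC, cross-magnification NMI, attention precision and
mean predictive entropy.

Because the real benchmark corpora are gated, gigapixel and GPU-scale, the
package ships a seeded generator of co-registered 10×/40× H&E-like patch
pairs (elliptical nuclei, eosin/hematoxylin palette, tumor blobs with denser
and more pleomorphic nuclei) with ground-truth masks, centroid tables and
manifests — every loss, scheduler and metric is exercisable on a laptop CPU.

## Worked example

```r
library(histomulti)

spec     <- slide_spec(seed = 42, canvas_px = 256, tumor_fraction = 0.5)
manifest <- generate_dataset(spec, 40, file.path(tempdir(), "demo"))

pair <- generate_patch_pair(spec, 1)
pair$label                                        # "tumor"
nrow(pair$centroids)                              # 92 nuclei in the 40x frame
texture_entropy(pair$image40)                     # 3.85 bits
nuclei_density_variance(pair$centroids, 64)       # 0.000327 nuclei / px

fit <- train(manifest, model_config(), composite_loss_config(),
             train_config(epochs = 6, warmup_epochs = 2, batch_size = 8,
                          seed = 1),
             out_dir = file.path(tempdir(), "demo_run"))
str(fit$metrics)
#> $ dice               : num 0.905
#> $ auc                : num 1
#> $ nmi                : num 0.745
#> $ attention_precision: num 1
#> $ mean_entropy10     : num 0.988
#> $ mean_entropy40     : num 0.867
#> $ val_kl             : num 0.149
#> $ off_graph_mass     : num 0.343
```

Reading the numbers: `dice` compares the 40× branch's token-level tumor
prediction with the downsampled ground-truth mask; `auc` scores the fused
patch classifier; `nmi` measures agreement of seeded k-means clusterings of
the two views' cell-level embeddings; `attention_precision` is the fraction
of the top 20% attention mass landing inside tumor; `val_kl` is the raw
cross-magnification divergence PAUAC suppresses; `off_graph_mass` is the
attention fraction on non-adjacent superpixel pairs that SACGR suppresses;
entropies are in bits (≤ 1 for two classes).

The ablation harness (`ablate()`) trains `full`, `no_pauac`, `no_sacgr` and
`no_cccra` configurations across seeds and summarizes medians/IQRs — on
synthetic data the full model shows lower cross-magnification KL than
`no_pauac`, lower off-graph attention mass than `no_sacgr`, and higher
cell-level NMI than `no_cccra`.

A thin CLI lives at `inst/scripts/histomulti`
(`histomulti generate|train|evaluate|ablate|score --config cfg.yaml --seed 1
--out DIR`).

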