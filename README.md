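# spafuse

Spatial domain detection for spatial multi-omics data — RNA plus a second
modality (ATAC peaks or ADT proteins) measured on the same tissue section —
with optional injection of a per-spot embedding from a pre-trained
single-cell language model (e.g. scGPT).

## Who this is for

Analysts of spatial multi-omics platforms (MISAR-seq, SPOTS,
Spatial-CITE-seq, 10x Visium CytAssist + protein) who want to partition a
tissue section into spatial domains — spatially coherent regions with a
distinct molecular profile — using *both* modalities and, when available,
the richer per-spot representation a single-cell foundation model produces
from the expression profiles.

## The model

With N spots, omics matrices X₁ ∈ ℝ^(N×D₁), X₂ ∈ ℝ^(N×D₂), coordinates
P ∈ ℝ^(N×2), and an optional language-model embedding Emb_f ∈ ℝ^(N×D_f):

1. **Graphs.** A spatial kNN graph G_s connects each spot to its k₁ = 3
   nearest neighbours in Euclidean space. Each embedding (PCA of X₁ and X₂,
   and Emb_f) gets a correlation graph connecting each spot to the k₂ = 20
   spots with the highest Pearson correlation of embeddings. Directed
   selections are OR-symmetrized; graph convolutions use the normalized
   operator D^(−1/2)(A+I)D^(−1/2).
2. **Encoders.** Three graph-convolutional encoders (for Emb_f, Emb₁,
   Emb₂), each applied with two graphs (spatial + its embedding graph),
   give six latents Z = A σ(A σ(A X W⁰) W¹) W² ∈ ℝ^(N×64) (third layer
   linear, no biases).
3. **Attention fusion.** Five fusion sites combine pairs of latents: per
   spot, scoreₖ = tanh(Rₖ W_ω)·μ_ω, weights α = softmax(score + ε), fused
   = Σₖ αₖ Rₖ. Hierarchy: (LLM-spatial ⊕ omics1-spatial), (LLM-feature ⊕
   omics1-feature), those two fuse to the modality-1 latent, (omics2-spatial
   ⊕ omics2-feature) to the modality-2 latent, and a final fusion yields
   Emb ∈ ℝ^(N×64).
4. **Losses.** Mean (over spots) squared Frobenius row norms: four
   reconstruction terms through mirrored decoders, plus two
   cross-modality correspondence (cycle) terms — e.g. EA₁ is decoded by the
   *other* modality's decoder, re-encoded, and compared to itself. Total =
   α₁L_rec1 + α₂L_rec2 + α₃L_recfs + α₄L_recfe + β₁L_cor1 + β₂L_cor2,
   trained full-graph with Adam.
5. **Domains.** The final embedding is clustered with a Gaussian mixture
   whose components share one full covariance matrix (the mclust EEE
   family), EM from seeded k-means restarts. Supervised evaluation:
   homogeneity, V-measure, AMI, NMI, ARI.

The zero-embedding ablation (`embedding_provider("zero")`) replaces Emb_f
with zeros, isolating the language-model contribution while running the
identical architecture.

## Worked example

```r
library(spafuse)
sim <- simulate_spatial_multiomics(rows = 12, cols = 12, n_domains = 3, seed = 42)
fit <- spafuse(sim$rna, sim$mod2, sim$coords, n_domains = 3, epochs = 100, seed = 42)
print(fit)
#> Spatial multi-omics domain model
#>   144 spots, latent width 64, embedding source: pca
#>   trained 100 epochs, final total loss 241.09
#>   3 spatial domains (sizes: 48, 48, 48)
compute_metrics(fit$domains, sim$truth)
#> homogeneity  1.0000
#> v_measure    1.0000
#> ami          1.0000
#> nmi          1.0000
#> ari          1.0000
round(coef(fit), 3)
#>        s.llm     s.omics1        e.llm     e.omics1    1.spatial    1.feature
#>        0.026        0.974        0.185        0.815        0.645        0.355
#>    2.spatial    2.feature final.omics1 final.omics2
#>        0.566        0.434        0.829        0.171
```

The fit recovers all three planted domains exactly (all five agreement
metrics equal 1). `coef()` reports the mean attention weight each fusion
site assigns to its inputs: here the omics embedding dominates the
(fallback PCA) "LLM" branch, the modality-1 branch leans on the spatial
view, and the final fusion favours the RNA branch — the per-spot,
per-domain detail behind these means comes from `summarize_attention(fit)`.
`plot(fit)` draws the domain map; `plot(fit, "loss")` the training curve.

A command-line interface wraps the same pipeline:

```sh
Rscript inst/cli/spafuse simulate --out fixture --seed 1
Rscript inst/cli/spafuse run --config config.yaml --out results
Rscript inst/cli/spafuse evaluate --labels results/domains.tsv --truth fixture/truth_labels.csv
```

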