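---
title: "Methods: graph-autoencoder fusion of spatial multi-omics with language-model embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph-autoencoder fusion of spatial multi-omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spafuse)
```

## The problem and the model

Spatial multi-omics assays measure two molecular layers — typically RNA plus
chromatin accessibility (ATAC) or surface proteins (ADT) — at the same spots
of one tissue section, with known 2-D coordinates. Spots are not single
cells and capture efficiency is low, so each layer alone is noisy; the goal
is to partition spots into *spatial domains*, spatially coherent regions
with distinct molecular identity.

`spafuse()` fuses three information sources per spot: the two omics layers
(as PCA embeddings `Emb1`, `Emb2`) and an optional external per-spot
embedding `Emb_f` produced by a pre-trained single-cell language model from
the spot's expression profile. The architecture is a six-branch graph
autoencoder:

* each of three encoders (one per source) is a three-layer graph
  convolution `Z = A·σ(A·σ(A·X·W0)·W1)·W2` with a rectifier σ on the first
  two layers and a *linear* third layer, no bias terms;
* each encoder runs twice — once with the spatial kNN graph, once with its
  own correlation kNN graph — giving six 64-wide latents;
* five attention sites fuse them hierarchically into the final embedding
  (per spot: `score_k = tanh(R_k W)·mu`, softmax weights over inputs,
  weighted sum), and the learned weights are retained for interpretation;
* training minimizes four reconstruction terms (mirrored decoders) plus two
  cross-modality correspondence cycles, each a mean-over-spots squared
  Frobenius row norm, with per-term weights (all default 1) under Adam.

The final embedding is clustered by a Gaussian mixture with one shared full
covariance matrix (the EEE family of model-based clustering), the model
family classically used for this task in the spatial transcriptomics
literature.

Key modelling assumptions: the two omics layers are measured on the *same*
spots (alignment is an inner join on spot IDs, not registration); spatial
proximity is informative but not decisive (hence separate spatial and
feature graphs whose balance is *learned* per spot by attention); and 64
latent dimensions suffice to separate domains.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `k1` | 3 | spatial-graph neighbours per spot; small, because lattice neighbours beyond the immediate ring add mostly redundant smoothing |
| `k2` | 20 | correlation-graph neighbours; larger, because feature similarity is noisy and benefits from averaging |
| `pca_dim` | 50 | PCA width of both omics embeddings (clamped to the rank bound); the standard regime for kNN graphs on expression data |
| `latent_dim` | 64 | width of every latent entering attention |
| `hidden_dim` | 256 | encoder hidden layer; wide enough to be non-limiting at these input widths |
| `epochs`, `learning_rate` | 200, 1e-3 | full-graph Adam; the loss typically plateaus well before 200 epochs on desk-scale data |
| `loss_weights` | all 1 | per-term weights (`rec_1`, `rec_2`, `rec_fs`, `rec_fe`, `cor_1`, `cor_2`); a grid search over these is a user-level loop, not built in |
| `epsilon` | 1e-8 | additive constant in the attention softmax; provably weight-neutral (softmax shift invariance), kept purely for numerical hygiene and verified invariant in the tests |

Normalization defaults per modality: library-size scaling to the median
depth + `log1p` for RNA and ATAC; centered log-ratio across features within
each spot for ADT (the community conventions for those data types). Both
are exposed and overridable; matrices already flagged normalized pass
through untouched.

## Embedding providers

`Emb_f` enters through a provider interface so the package never depends on
model weights:

* `external_file` — a precomputed embedding (e.g. scGPT output, typically
  512-wide) read from delimited text, rows in aligned spot order.
  `match_vocabulary()` reports which gene symbols a model's vocabulary
  covers; unmatched genes are only excluded from the language-model input,
  never from the omics analysis.
* `zero` — the all-zeros embedding: the ablation that removes the
  language-model signal while exercising the identical architecture. Its
  correlation graph is undefined (zero variance), so that branch reuses the
  modality-1 graph; the encoder output of a zero input is exactly zero, and
  attention then learns to down-weight it.
* `mock` — a seeded random linear projection of the normalized expression
  plus Gaussian noise: informative by construction, used in tests.
* `pca_fallback` (the default) — PCA of the expression matrix; the sensible
  weight-free default for users without an external model.

## What the generator emulates — and what it does not

`simulate_spatial_multiomics()` produces a `rows × cols` lattice (default
20 × 20) split into `n_domains` contiguous regions (blocks by default,
matching the compact annotated regions of real brain/lymph sections;
stripes and Voronoi layouts available). Per domain and feature, log-mean
shifts are drawn with SD `effect_size × 0.5`, 0.5 being roughly the
within-domain SD of log-normalized counts at the simulated depths, so
`effect_size` reads as "mean shift in noise-SD units". RNA counts are
negative binomial (dispersion 0.5) with independent dropout (default 0.2);
ADT is continuous log-normal; ATAC is sparse binarized Bernoulli.
`make_informative_embedding()` plants per-domain Gaussian anchors plus
noise, standing in for a language model whose embedding carries domain
signal.

The generator deliberately omits several properties of real data: spot
bleed and segmentation error, spatially smooth confounders (tissue-wide
gradients), library-size/domain confounding, batch effects, and the
gene-level semantic structure a real language model encodes. Passing the
recovery tests therefore shows the pipeline is *correct and sensitive under
its own model*, not that it will match annotation-level accuracy on real
tissue.

## Numerical choices

* **Ties** in kNN and top-correlation selection break toward the lowest
  spot index (stable `order()`), making graphs platform-reproducible.
* **Symmetrization** is logical OR; graph convolutions use
  `D^(-1/2)(A+I)D^(-1/2)` (self-loops injected only here). A
  `raw_adjacency` switch runs the literal bare-adjacency recursion instead.
* **PCA signs** are fixed by making each component's largest-magnitude
  loading positive, so embeddings are bitwise-stable.
* **Initialization** is Glorot-uniform under the run seed; training is
  deterministic given the seed and single-threaded BLAS.
* **Gradients** come from a small reverse-mode tape written for this
  architecture and are checked against central finite differences in the
  test suite (tolerance 1e-5 relative on sampled entries).
* **Constant embedding rows** get correlation 0 (avoiding 0/0) with a
  warning; all-zero library spots stay zero with a warning; a singular
  pooled covariance in the mixture gets diagonal jitter (1e-6 of the mean
  variance) with a warning.
* **EM details**: 5 seeded k-means restarts, best final log-likelihood
  wins; the winning restart's log-likelihood trace is returned and asserted
  non-decreasing in the tests.

## Open design choices

Where the method description leaves room, the package fixes these choices:

* The encoder for `Emb_f` **shares weights** across its spatial-graph and
  embedding-graph applications (one encoder used twice); the same holds for
  each omics encoder.
* The correspondence cycles (`cor_1`, `cor_2`) run through the **spatial
  graph**, the structure shared by both modalities.
* Each of the five attention sites has **its own** `W`/`mu` parameters —
  independent parameters are the weaker assumption.
* One `k2` serves all three correlation graphs.
* Vocabulary matching is exact and case-sensitive by default
  (case-insensitive available), since gene-symbol case conventions differ
  by organism.
* Metric normalizations are fixed and documented: NMI uses the arithmetic
  mean of the entropies; AMI uses the max-entropy denominator with the
  exact hypergeometric expected mutual information; entropies are natural.
* Domain labels are 1-based integers (R convention); all metrics are
  invariant to relabeling.
* The 2-D visualization export (`project_2d()`) is classical metric MDS of
  latent distances — deterministic and dependency-free; it is a linear
  layout and will not unroll non-linear manifold structure the way UMAP
  would.
* Hierarchical containers are accepted in R's native form
  (`SingleCellExperiment` via `read_modality(format = "sce")`) alongside
  delimited text and 10x-style Matrix Market directories.

## Problem sizes used in the checks

The shipped tests and `scripts/acceptance.R` exercise: graphs up to
N = 100–200 against brute-force O(N²) oracles; encoder/decoder equality
with dense layer-by-layer evaluation on 100 random graphs with N ≤ 20
(tolerance 1e-9); the full pipeline on the default 20 × 20 lattice (400
spots, 200 epochs); and the informative-vs-zero embedding ablation on five
seeds at 100 epochs with modality-2 effects zeroed — sizes chosen so the
whole suite runs in minutes on one CPU while every check retains power.

## Known limitations

* Full-graph training only — memory and time scale with N²-sparse
  operators and dense N × 256 activations; adequate to ~10⁴ spots, no
  minibatching.
* Exactly two omics modalities; no histology images; no cross-section
  batch correction or registration.
* The language model itself is out of scope: the package consumes its
  embeddings from a file and cannot validate how they were produced.
* Model selection for the number of domains is the user's (annotation
  count in the evaluations here); no BIC sweep is run by default.
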