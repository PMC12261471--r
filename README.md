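# topofuse

Drug–target interaction (DTI) prediction that fuses **persistent-homology
features** of drug molecular images and protein contact maps with
**sequence embeddings**, classifies candidate pairs with a heterogeneous
graph neural network, and evaluates under random and cold (unseen-entity)
splits.

## Who this is for

Computational drug-discovery researchers who want (a) a fully testable,
pure-R reference implementation of image-based persistent homology
featurization (sublevel cubical filtrations, Betti curves, persistence
landscapes), (b) a gated multimodal fusion + GraphSAGE-style link
classifier trained end to end, and (c) a leakage-careful evaluation
protocol for DTI benchmarks, including unseen-drug/unseen-target splits.

## The model

For an image channel with pixel values γ ∈ [0, 255], thresholds
0 = t₁ < … < t₅₀ = 255 define sublevel sets Xₘ = {pixels with γ ≤ tₘ},
a nested cubical filtration. Persistent homology records birth–death pairs
of connected components (H₀) and loops (H₁). Each channel is vectorized as
Betti curves (50 + 50 entries) plus first persistence landscapes
λ₁(x) = maxᵢ tent(bᵢ, dᵢ)(x) sampled at 100 bins (100 + 100), and the four
channels (gray, R, G, B) concatenate to a 1200-D topological vector per
entity.

Sequence embeddings (768-D drug, 1024-D protein, pluggable or mocked) and
topological vectors are projected by two-layer ReLU heads into a 512-D
latent space and fused per entity kind by a learnable gate

    α = σ(W[f_seq; f_topo] + b),   f = α ⊙ f_seq + (1 − α) ⊙ f_topo,

so each fused entry is a convex combination. Fused vectors seed a
bipartite graph whose message edges are positive *training* interactions
only; two mean-aggregation GNN layers (separate direction weights, batch
norm, dropout) produce node embeddings, and an MLP scores concatenated
pairs. Training: binary cross-entropy, Adam, early stopping with patience
5, best-validation checkpoint restored; experiments average five seeded
runs (AUROC, AUPRC, sensitivity, specificity).

## Worked example

```r
library(topofuse)

# a synthetic benchmark with planted low-rank interaction structure:
# 200 drugs x 150 targets, 8 latent dimensions, 5% interaction density
data <- gen_dti_dataset(seed = 11)
fit <- topofuse(data, split = random_split(data$pairs, seed = 11), seed = 1)
summary(fit)
#> Fused topological/sequence DTI model
#>
#> fusion: dynamic   seed: 1   epochs: 11 (best 6)
#> final train loss 0.2665, best val loss 0.4263
#> final mean gate weight alpha: drugs 0.511, targets 0.540
#> test metrics: AUROC 0.8511  AUPRC 0.8564  sensitivity 0.7974  specificity 0.7266
```

Training ran 11 epochs (each a shuffled minibatch pass over the training
pairs) before the validation loss stalled, restored the epoch-6
checkpoint, and ranks held-out pairs with AUROC ≈ 0.85 — the planted
latent structure is recovered from the fused features. The gate weights
stay near 0.5 because both modalities of this synthetic dataset carry the
same latent signal.

The topological featurization is usable on its own:

```r
img <- render_molecule("c1ccccc1", size = 64)   # benzene, built-in renderer
diag <- cubical_persistence(split_channels(img)$gray)
subset(diag, dim == 1 & death - birth > 128)    # one long-lived loop: the ring
#>   birth death dim essential
#> 2     0   255   1     FALSE
length(image_vector(img))                       # the 1200-D feature vector
#> [1] 1200
```

A thin command-line front end with `featurize` / `train` / `evaluate` /
`split` / `synth` subcommands lives at `inst/cli/topofuse.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/topofuse.R", package="topofuse"))') synth --dataset_dir data`).

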