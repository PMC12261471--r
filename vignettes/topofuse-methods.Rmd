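---
title: "Methods: topological feature fusion for drug-target interaction prediction"
author: "topofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: topological feature fusion for DTI prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofuse)
```

## The model

`topofuse` predicts binary drug-target interactions (DTIs) from two
complementary per-entity representations:

1. **Topological features.** Each drug is depicted as a 2-D molecular image
   (dark skeleton on white) and each protein as a contact-map image. For a
   single-channel image with 8-bit values $\gamma_{ij}$ we take thresholds
   $0 = t_1 < t_2 < \dots < t_N = 255$ and the sublevel sets
   $X_m = \{\Delta_{ij} : \gamma_{ij} \le t_m\}$, a nested sequence of
   cubical complexes. Persistent homology over this filtration records a
   birth-death pair for every connected component ($H_0$) and loop ($H_1$).
   Diagrams are vectorized two ways: *Betti curves*
   $\beta_d = [\beta_d(t_1), \dots, \beta_d(t_N)]$ counting features alive
   at each threshold, and the first *persistence landscape*
   $\lambda_1(x) = \max_i f_{(b_i,d_i)}(x)$, where $f_{(b,d)}$ is the tent
   function rising from $b$, peaking at $(d-b)/2$, and falling to $d$,
   sampled at $B$ bin centers. With $N = 50$ and $B = 100$ each of the four
   channels (gray, red, green, blue) contributes $2N + 2B = 300$ entries,
   so every entity carries a 1200-D topological vector.
2. **Sequence embeddings.** Exported language-model embeddings (768-D for
   drug SMILES, 1024-D for protein sequences), or deterministic mocks when
   no export is available.

Both representations pass through two-layer ReLU projection heads into a
common 512-D latent space. A per-entity-kind gate fuses them:
$\alpha = \sigma(W [f_{\text{seq}}; f_{\text{topo}}] + b)$ and
$f = \alpha \odot f_{\text{seq}} + (1-\alpha) \odot f_{\text{topo}}$, an
elementwise convex combination. The fused vectors become node features of a
bipartite heterogeneous graph whose message edges are the *positive
training* interactions only; two GraphSAGE-style layers compute
$h' = \mathrm{ReLU}(\mathrm{BN}(h W_{\text{self}} + \bar h_{\mathcal N}
W_{\text{nbr}} + b))$ with direction-specific neighbor weights, batch
normalization, and dropout. An MLP on the concatenated pair embeddings
yields the interaction probability. Everything is trained end to end with
binary cross-entropy, Adam, and validation-loss early stopping (patience
5), restoring the best-validation checkpoint.

## Conventions the persistence computation fixes

The literature leaves several image-persistence details open; the package
fixes them as follows and tests them against an independent boundary-matrix
reduction oracle.

* **Complex construction.** Pixels are 2-cells together with all their
  edges and vertices (closure "T-construction"). Two diagonal pixels share
  a corner vertex, so foreground components are vertex-adjacent
  (8-connected) and holes are 4-connected components of the complement.
  This is the convention under which the Euler identity
  $\beta_0 - \beta_1 = V - E + F$ holds at every threshold, which the test
  suite asserts.
* **Essential classes.** The full rectangle is connected and contractible,
  so exactly one $H_0$ class never dies; its death is recorded as 255 and
  flagged `essential`. No $H_1$ class is essential in 2-D.
* **Liveness.** A bar $(b, d)$ counts toward the Betti curve at threshold
  $t$ iff $b \le t < d$; the flagged essential bar also counts at
  $t = 255$. The flag matters: a genuine loop death *at* 255 (a hole
  filled by the last-activating pixel) must not count at 255, otherwise
  the final complex would not report $\beta_0 = 1$, $\beta_1 = 0$.
* **Merges.** Elder rule; ties broken by the smallest linearized pixel
  index of the component root, making diagrams byte-deterministic.
* **Value snapping.** Pixel values are rounded half-up to integers at
  ingestion and activate at the smallest grid threshold $\ge$ their value;
  zero-persistence pairs are dropped.
* **Landscape domain.** Landscapes are sampled on the fixed domain
  $[0, 255]$ at the centers of $B$ equal subintervals, so features are
  comparable across images; a per-diagram domain would renormalize away
  scale information.
* **Grayscale.** ITU-R 601 luminance $0.299R + 0.587G + 0.114B$, rounded.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `thresholds` | 50 | filtration levels from 0 to 255 inclusive |
| `bins` | 100 | landscape sampling points on [0, 255] |
| `latent` | 512 | shared projection width |
| `gnn_hidden` | 256, 128 | widths of the two GNN layers |
| `mlp_hidden` | 64 | pair-classifier hidden width |
| `dropout` | 0.2 | after each GNN layer, training only |
| `lr` | 1e-3 | Adam step size |
| `batch_size` | 512 | supervision-edge minibatch size per optimizer step |
| `patience` | 5 | early-stopping patience, epochs |
| `holdout_fraction` | 0.2 | entities held out in cold splits |

Hidden widths, dropout, and learning rate are conventional defaults; the
threshold/bin counts, latent width, patience, split ratios (70/10/20
random; 7/8-1/8 after cold holdout), and five-seed averaging are the
pipeline's defining constants.

## Numerical choices

* **Epochs and batching.** An epoch is one shuffled pass over the training
  pairs in minibatches of `batch_size` supervision edges; every step runs
  a full-graph forward (all nodes participate in propagation) supervised
  on that batch. Early stopping therefore monitors validation loss after
  full passes, the granularity its patience constant presumes.
* **Full-graph batch normalization.** Because every step's forward covers
  the entire node set of a type, the batch statistics are the population
  statistics of the current parameters. The evaluation-mode statistics
  therefore default to the statistics of the latest training pass
  (`bn_momentum = 1`). An exponentially lagged average (momentum well
  below 1) mixes statistics of stale parameter iterates into evaluation;
  early in training this inflates the validation loss and can trigger
  spurious early stopping. The momentum remains configurable.
* **Early stopping** counts consecutive epochs without strict validation
  improvement; the first epoch always improves on the initial infinity, so
  a never-improving run trains exactly `1 + patience` epochs.
* **Gate initialization.** Zero weights and bias, so training starts at
  the static baseline $\alpha = 0.5$ and any preference for a modality is
  learned, not seeded.
* **Isolated nodes** (cold-split holdouts) receive a zero neighbor mean
  and are embedded from their own features alone.
* **AUROC** uses the Mann-Whitney rank formula with half-credit ties;
  AUPRC is step-interpolated average precision; sensitivity/specificity
  are taken at a fixed 0.5 threshold.
* **Cold splits.** `unseen_drugs`/`unseen_targets` send every interaction
  of the held-out entities to the test set and divide the remainder
  7/8-1/8. `cold_both` partitions the entity universe itself and keeps
  only within-group pairs, discarding cross-group pairs (`"unused"`), the
  only way to make validation *and* test entity sets fully disjoint from
  training on both sides.

## What the synthetic generators emulate

`gen_topo_image()` plants disks and annuli (dark on light, matching the
sublevel order of skeletal molecule drawings) with known Betti numbers, so
the whole image pipeline can be checked against ground truth. It does not
emulate stroke textures, anti-aliasing, or the depiction conventions of
chemistry toolkits.

`gen_dti_dataset()` plants a low-rank interaction structure: latent vectors
$u_d, v_t \in \mathbb R^8$, positives where the noisy inner product exceeds
the density quantile (default density 0.05 over a 200 x 150 grid, noise
s.d. 0.5 — a regime where labels are strongly but not perfectly determined
by the latents), negatives count-matched for balance. Sequence embeddings
are noisy linear images of the latents; topological vectors are either
signal-bearing or pure noise, to probe the fusion gate. Test performance
on this benchmark (five-seed mean held-out AUROC, reported by
`scripts/acceptance.R`) shows that the pipeline recovers plantable latent
structure end to end; it does **not** show that topological features of
real molecular images carry comparable signal, which depends on real data
and real embeddings outside this package's scope.

## Known limitations

* The built-in SMILES renderer is a deterministic stand-in covering a
  restricted grammar; it preserves ring topology (the property the
  persistence features consume) but not chemically meaningful geometry.
  A chemistry-toolkit renderer can be plugged in via the `renderer`
  argument.
* Message passing is transductive over positive training edges only.
  Excluding evaluation edges prevents label leakage but means absolute
  metrics are not comparable to pipelines that propagate over all known
  interactions.
* **Gate behavior under pure-noise features.** When one modality is pure
  per-entity noise, one might expect the trained gate to settle above 0.5
  on the informative side. In practice it settles slightly *below* 0.5:
  the gate is driven by the training-loss gradient, and fixed noise
  vectors are perfectly discriminative node identifiers, so up-weighting
  them reduces training loss even though the informative side generalizes
  better (a counterfactual sweep of the gate bias shows training loss
  decreasing toward the noise side while validation loss decreases toward
  the signal side). The per-epoch `alpha_trace()` makes this dynamic
  visible; interpreting final gate weights as modality "importance" is
  only warranted when both modalities carry real signal.
* Landscapes use only level 1; persistence images and deeper landscape
  levels are out of scope.

## Problem sizes used in the checks

Oracle equivalence is asserted on 100 random images up to 10 x 10 over
8-threshold grids (exact multiset equality of diagrams); the planted
benchmark trains five seeds on the 200 x 150 grid with default widths;
unit tests use smaller widths (8-32) chosen to exercise every code path
quickly.
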