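---
title: "Methods: heterogeneous-graph attention for miRNA-disease association inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneous-graph attention for miRNA-disease association inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hgmda)
```

## Problem and model

`hgmda` infers unobserved miRNA–disease associations by link prediction
on a heterogeneous graph with three sub-graphs: disease–disease and
miRNA–miRNA similarity graphs, and the bipartite graph of known
associations. The underlying biological assumptions are the standard ones
of this literature: functionally similar miRNAs associate with similar
diseases, diseases close in the MeSH hierarchy share molecular etiology,
and the observed association matrix is a very incomplete, positives-only
sample of the true bipartite relation.

The pipeline is: (1) disease semantic similarity from MeSH tree-number
DAGs plus a Gaussian interaction profile (GIP) kernel, and miRNA
functional similarity (a user input, typically MISIM) plus its GIP
kernel, each pair averaged elementwise; (2) similarity-weighted random
walks embedded by a hierarchical-softmax skip-gram model; (3) a
multi-head graph attention (GAT) encoder on the bipartite sub-graph;
(4) a fully connected pair scorer trained with cross-entropy, L2
regularization and uniform negative sampling. Each stage is exposed as
ordinary functions (`semantic_similarity()`, `gip_kernel()`,
`sample_walks()`, `embed_nodes()`, `gat_forward()`), and `hgmda()` /
`hgmda_cv()` assemble them.

### Semantic similarity

Disease DAGs are built from dot-delimited tree numbers; node identity is
the tree-number string, so two diseases overlap exactly when their
tree-number sets share prefixes. A disease's own terms contribute 1;
an ancestor contributes `delta` times the best contribution among its
children (`delta = 0.5`), computed by one reverse-topological pass. The
pairwise similarity is overlap mass normalized by the two semantic
values. Diseases that appear without any tree number are kept as
single-node DAGs (similarity 0 to everything but themselves) rather than
dropped, and a warning is emitted; the GIP component still provides a
usable similarity for them, which is the main reason the integrated
matrix averages the two sources unconditionally instead of falling back
to GIP only where the semantic entry is zero.

### GIP kernels

`gamma = gamma_prime / mean(squared profile norm)` with
`gamma_prime = 1`; the kernel is `exp(-gamma * d^2)` on binary
interaction profiles. The bandwidth normalization makes the kernel scale
adapt to matrix density, so the same defaults work on sparse real data
and denser synthetic data.

### Weighted walks and embeddings

Transition probabilities are the integrated similarity rows with the
diagonal zeroed and each row renormalized; self-transitions are excluded
because a self-loop contributes no skip-gram context. Walks are length
20, 10 per start node; the skip-gram uses window 5, 64 dimensions,
hierarchical softmax, minimum count 1 (no node is dropped), 5 epochs,
initial learning rate 0.025 with linear decay. Walk count and epoch count
are not prescribed by the method's description and follow common
DeepWalk practice; both are exposed in `hgmda_control()`. Training is
single-threaded by construction, so a fixed corpus and seed reproduce the
embedding matrix bitwise.

### GAT encoder

Two layers, 16 heads. The attention scorer is
`LeakyReLU(a^T [W h_i || W h_j])` with negative slope 0.02; softmax
normalization runs over each node's neighbourhood including an explicit
self-loop (that is also what gives isolated nodes a defined output). All
layers except the last concatenate heads, each head producing
`F / heads` features so the width stays `F`; the last layer's heads each
produce `F` features and are averaged. Layer activations are LeakyReLU
(slope 0.2). Per-head output sizes and slopes are implementation choices
exposed in `gat_params()` / `hgmda_control()`.

Two implementations of the layer mathematics ship in the package: plain
R matrix algebra (`engine = "r"`) and fused C++ kernels
(`engine = "cpp"`, the default) whose inner loops are feature-major for
cache locality with BLAS for the dense products. The test suite checks
their agreement to 1e-12 and checks the analytic gradients of the whole
model against central finite differences at relative 1e-4.

### Scorer, loss, training

Raw similarity rows are projected to `F` dimensions by trainable `Wd`,
`Wm` and combined with the refined node features, by concatenation
(default) or summation. The predictor is a three-layer fully connected
network (hidden widths 128 and 64 — depth is prescribed, widths are ours)
with a sigmoid output. The loss is the *sum* of binary cross-entropy over
positives and sampled negatives plus `lambda * ||Theta||^2`
(`lambda = 5e-4`); the optimizer is full-batch Adam (learning rate 0.001)
with weight decay 5e-5 added to the gradient. Both the explicit penalty
and the optimizer weight decay are applied because the method specifies
both; they are independently configurable, and the redundancy is
deliberate rather than an oversight. Negatives are drawn once per
training run, not per epoch, matching a fixed negative set in the loss.
Training runs up to 500 epochs with early stopping after 50 epochs
without improvement; on the synthetic acceptance datasets the loss is
still slowly decreasing at 500 epochs, so the cap is what usually binds.

## Cross-validation and leakage control

Positives and an equal number of uniformly sampled negatives are
shuffled together and split into five near-equal folds. For each fold the
package, by default, removes the held-out positives from the association
matrix before recomputing the GIP kernels, the integrated similarities,
the embeddings and the attention edge list (`mask_test_edges = TRUE`).
The alternative — building the graph once from all known associations —
lets every test positive influence its own features and optimistically
biases the estimate; it is retained as `mask_test_edges = FALSE` because
published comparisons in this area typically use it. The test suite
asserts that under masking no held-out positive ever appears in a fold's
edge list.

Metrics: confusion-matrix metrics at threshold 0.5; AUC from midranks
(ties count one half, identical to trapezoidal ROC integration); AUPR by
the average-precision estimator rather than trapezoidal interpolation of
the PR curve, which can be optimistic. Ties in AUPR and in candidate
rankings are broken by stable order / lexicographic miRNA name so results
are reproducible.

## Synthetic data: what it does and does not show

`simulate_mda()` generates matched latent blocks of miRNAs and diseases:
associations are Bernoulli(0.8) within a matched block and
Bernoulli(0.05) across, disease DAGs are random prefix-sharing
tree-number chains within a block (depth up to 4), and functional
similarity is the block indicator plus Gaussian noise (sd 0.1),
symmetrized, clipped to [0, 1]. These defaults are the acceptance
conditions used throughout the tests; 40 x 40 with two blocks keeps a
five-fold CV of the full pipeline to a few minutes of CPU.

The generator reproduces the *structural* premises of the method —
cluster-correlated associations, hierarchy-induced disease similarity,
noisy functional similarity — but not the properties of real HMDD data:
extreme sparsity (~2.9% density vs ~40% here), heavy-tailed degree
distributions, hundreds of entities, disease terms with multiple distant
MeSH ancestors, and name noise across database dialects. Passing the
planted-recovery tests therefore demonstrates the pipeline is correctly
assembled and can learn block structure through masked CV; it does not
certify real-data ranking quality. On this synthetic geometry the bare
dot-product ablation is close to chance because the two skip-gram
embedding spaces are trained independently and share no coordinate
system; the trained GAT and projections are what align them.

## Numerical choices and degenerate inputs

- Similarity matrices are symmetrized by averaging when asymmetry
  exceeds 1e-8, the diagonal is forced to 1, and out-of-range values are
  clipped to [0, 1] with a warning.
- Scores exactly 0 or 1 are clamped to [1e-7, 1 - 1e-7] before logs in
  the exported loss (with a warning); the training loop computes the
  gradient through the sigmoid as `f - y`, which needs no clamping.
- Attention softmax subtracts the per-neighbourhood maximum before
  exponentiation.
- Parameter initialization is Glorot-uniform everywhere, biases zero;
  attention dropout is not implemented (the reference setting is 0).
- An all-zero association matrix, an all-zero similarity row (isolated
  node), a non-square similarity file, a malformed pair-list row, a
  cyclic DAG and an unknown disease name are all hard errors with
  specific messages; a disease without tree numbers is a warning plus a
  single-node DAG.
- All index orders are lexicographic (radix sort, locale-independent),
  so matrices do not depend on file row order.

## Problem sizes used by the tests

Unit tests run on 8–20 node graphs; the oracle comparisons use 100
random DAG pairs (up to 12 nodes) and 100 random metric instances; the
end-to-end acceptance checks use the 40 x 40 generator defaults with
three seeds and full five-fold CV (about 5–6 minutes), and the gradient
check covers every parameter of a 5 + 5 node model.

## Known limitations

- The miRNA functional similarity is an input; the package does not
  recompute MISIM from disease associations.
- Raw-feature ablations (`raw_gat_dot`) need equally many miRNAs and
  diseases, since similarity rows are used directly as node features.
- Mini-batching and GPUs are out of scope; graphs of a few hundred nodes
  train full-batch on one CPU in seconds per hundred epochs.
- The per-disease case-study protocol (negatives excluding the target
  disease, top-50 checking against later databases) is implemented as
  `exclude_negatives` + `rank_candidates()` + `verify_candidates()`, but
  the validation databases themselves must be supplied by the user.
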