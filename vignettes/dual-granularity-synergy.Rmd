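---
title: "Dual-granularity modeling of drug combination synergy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-granularity modeling of drug combination synergy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Two drugs are *synergistic* in a cell line when their combined effect exceeds
what a null model of additive interaction predicts. Reference models —
Bliss independence, Loewe additivity, HSA, and ZIP — each turn a measured
dose-response surface into a synergy score whose sign classifies the
combination. `dgsynergy` treats synergy prediction as binary classification
over (drug 1, drug 2, cell line) triples: given the two molecular structures
and the cell line's gene expression profile, predict the probability that the
combination is synergistic.

The model couples two granularities:

* a **coarse module**: a hypergraph whose nodes are drugs and cell lines and
  whose hyperedges are the training triples (each hyperedge joins exactly two
  drugs and one cell line), convolved to give each entity a globally informed
  embedding;
* a **fine module**: interaction-aware attention over molecular
  substructures, modeling how parts of each drug attend to parts of the other
  and to the cell line.

## Preprocessing

**Labels.** Each reference-model score available for a triple votes positive
when it exceeds zero; the label is the majority vote. A tied vote falls back
to the sign of the mean available score, and a tie with mean exactly zero is
dropped — a deterministic rule that uses all the information in the row.
Missing individual scores simply abstain.

**Symmetrization.** Synergy is unordered in the drugs, so every labeled
triple is expanded to both (d1, d2, c) and (d2, d1, c). Duplicate
observations of the same unordered triple are first collapsed by majority
vote over their labels (dead ties dropped and logged). All downstream
machinery preserves this symmetry: cross-validation assigns a sample and its
mirror to the same partition, and the order-independence analysis quantifies
how far the trained model deviates from exact symmetry.

**Drugs.** SMILES are canonicalized (OpenBabel), parsed into molecular
graphs — heavy atoms as nodes, bonds as edges — and featurized with a
78-dimensional binary vector per atom: a 44-wide one-hot atom-type block
(43 named elements plus an "other" bucket), 11-wide one-hot blocks for
degree, hydrogen count, and implicit valence (0–10, larger values clamped
into the last bucket), and one aromaticity flag. The implicit valence is
taken as the implicit-hydrogen count, the convention of the DeepDDS-style
featurization this block layout follows; for SMILES without explicit
hydrogens the two coincide. Each drug also gets a circular ECFP6 fingerprint
— diameter 6 bonds, i.e. radius 3, the conventional reading of the name
(`fp_radius` overrides it) — folded from OpenBabel's 4096-bit output to 1024
bits by bitwise OR. Fingerprints feed the reconstruction loss and are not
seen by the classifier directly.

**Cell lines.** Expression matrices are restricted to a landmark gene list
(the LINCS L1000 "Landmark Gene Set" in real use) and z-scored per gene with
the population (1/n) standard deviation. When a split is active the
statistics come from training cell lines only, so held-out cell lines cannot
leak into normalization; zero-variance genes are dropped and logged.

## Architecture

**Initialization.** Three GIN layers (`h' = MLP((1+eps) h + sum of
neighbours)`, eps fixed at 0, two-layer MLPs with ReLU) update atom features.
After each layer a SAGPool step scores nodes with a one-layer GCN, keeps the
top `ceil(ratio * n)` (ratio 0.5; ties broken toward lower atom index for
determinism), gates the surviving features with `tanh(score)`, and mean-pools
them into that layer's substructure token. Pooling is hierarchical: layer
l + 1 runs on the subgraph layer l retained. The three per-layer tokens are
concatenated jumping-knowledge style and projected to the molecular
embedding. Cell lines pass through a two-layer MLP ([512, 384] by default).
Encoder variants (GCN, GAT with 1/2/4 heads) and readout variants (add, max,
mean) are configuration switches for ablation.

**Coarse module.** Node features (drug embeddings and cell embeddings
projected to a common width) are propagated through four hypergraph
convolution layers `X' = ReLU(Dv^-1/2 H De^-1 H^T Dv^-1/2 X Theta)` with
identity hyperedge weights, widths [768, 384, 384, 384] by default. The
fourth layer's input is the projected input features plus the third layer's
output (a residual connection), then convolved. Hyperedges come from
**training** triples only; entities unseen in training are isolated nodes
that self-propagate unchanged (`M[v, v] = 1`), which is also why leave-out
scenarios are intrinsically harder for this module.

**Fine module.** Each drug contributes its three per-layer substructure
tokens; the cell line contributes one token (its embedding projected to
token width). Four-head scaled dot-product cross-attention runs over the
three pairs (drug A/drug B, drug A/cell, drug B/cell) in both query/key
directions, and each attended query set is mean-pooled, yielding six
interaction vectors per sample. One shared set of cross-attention weights
serves all six directions — this makes the A-attends-B and B-attends-A
vectors provably equal for identical drugs and keeps the bundle
swap-equivariant. Self-attention over the six tokens followed by a single
shared-weight linear layer (the same weights applied to each token) and
concatenation gives the fine embedding.

**Prediction.** The coarse triple representation (drug 1, drug 2, cell node
embeddings concatenated) and the fine embedding are concatenated and fused
by a one-layer highway network, `y = T(x) * G(x) + (1 - T(x)) * x`, with the
gate bias initialized to -1 so training starts carry-dominant. A two-layer
MLP with a 2-way softmax outputs the synergy probability.

**Loss.** A weighted sum, default weights (1.0, 0.1, 0.1):

* *classification*: cross-entropy;
* *reconstruction*: mean squared difference between the cosine-similarity
  matrix of the hypergraph node embeddings and the cosine similarity of the
  original descriptors — ECFP6 fingerprints for the drug block, expression
  rows for the cell block, summed; there is no cross-block term because the
  two descriptor spaces are incommensurable;
* *contrastive*: in the hypergraph sample-embedding space, positives are
  pulled toward their normalized centroid and pushed from 1:1-sampled
  negatives through a hinge on cosine distance with margin 0.5 (cosine
  distance lives in [0, 2], so 0.5 is a quarter of the range). Single-class
  batches skip the term and log it.

The per-epoch log records all three components, and the test suite asserts
`total = w_cls * cls + w_rec * rec + w_con * con` to 1e-6 on every epoch.

## Training and evaluation

Adam (default learning rate 4e-4, up to 2000 epochs) with minibatches,
early stopping on validation cross-entropy (patience 50, min-delta 1e-4),
and restoration of the best-validation parameters. One seed controls
splitting, initialization, dropout, shuffling, and negative sampling; two
fits with the same seed produce bit-identical epoch logs.

Cross-validation is five-fold with a 3:1:1 train/validation/test ratio in
three scenarios: *random* (grouped by unordered triple so mirrored twins
never straddle partitions), *leave-drug-pair-out* (grouped by unordered drug
pair), and *leave-cell-line-out* (grouped by cell line). In the leave-out
scenarios the validation fold is held out at the group level too; otherwise
early stopping would peek at test-adjacent entities. Folds balance group
counts, the simplest deterministic rule.

Eight metrics are reported: AUC-ROC (rank-based with tie correction),
AUC-PR (average precision with tied scores grouped), accuracy, balanced
accuracy, F1, precision, recall, and Cohen's kappa, all thresholded at 0.5
where a threshold applies.

## The autodiff engine

No neural-network framework is declared as a dependency: the package carries
a ~400-line reverse-mode automatic differentiation engine over dense base-R
matrices (dynamic tape, rebuilt each forward pass, so the data-dependent
top-k pooling needs no special casing). Multi-head attention is a single
fused tape node with a hand-derived backward. Every operator's gradient is
property-tested against central finite differences, which is the main reason
to trust training at all; the attention forward is additionally pinned to an
independent hand-computed oracle.

## The synthetic fixture

Real use targets DrugComb/GDSC2-scale downloads; development and testing run
on a generated toy universe whose defaults are 30 drugs, 12 cell lines, 64
genes, 600 triples, seed 7, target positive rate 0.3. Drugs are assembled
from a small fragment grammar (alkyl chains, benzene, pyridine, amides,
halogens) so every SMILES is chemically valid; two thirds of the drugs carry
a pyridine motif. Cell lines come from three Gaussian expression clusters
(cluster means N(0,1) per gene, unit noise), two of which are
"synergy-sensitive". The planted rule — synergistic iff both drugs carry
the motif and the cell line is in a sensitive cluster — yields a base
positive rate near 0.3, and triples are sampled stratified by latent label
to land the target exactly. Reference-model scores share a latent magnitude
|N(2, 1)| signed by the rule plus per-model N(0, 0.6) noise, so majority
voting, disagreements, and occasional 2–2 ties are all exercised; voting
recovers the latent label for over 99% of triples.

What the fixture does *not* emulate: realistic pharmacology, dose-response
surfaces, correlated score models, class imbalance drift across cell lines,
or assay noise structure. Passing tests therefore demonstrate that the
implementation learns a planted structure of the intended kind, not that it
matches the performance attainable on real screens. One caveat worth naming:
because cluster identity is recoverable from an unseen cell line's
expression profile, the leave-cell-line-out scenario on the fixture is
easier than its real-data counterpart; the test suite asserts a performance
*drop* relative to random CV, not a collapse.

## Problem sizes and presets

The `"reference"` preset carries the method's full-scale hyperparameters (GIN [128, 128,
128], cell MLP [512, 384], hypergraph [768, 384, 384, 384], 4 heads, dropout
0.3, lr 4e-4, up to 2000 epochs). The tests and the reproduction script use
the `"compact"` preset — the same architecture at one quarter width, up to
150 epochs, learning rate 2e-3, dropout 0.2, full-batch updates — which the
package treats as its reference desk-scale configuration: a full training
run on the default fixture takes a couple of minutes on one CPU and reaches
ceiling performance on the planted rule.

## Numerical choices and edge cases

* Ties in SAGPool scores retain the lower atom index; equal-score retention
  is thereby deterministic.
* Zero-variance genes are dropped before z-scoring; zero-norm rows in cosine
  similarity contribute zero rows rather than NaN.
* Isolated hypergraph nodes use the degree-safe self-propagation rule.
* A 2–2 label vote falls back to the sign of the mean score; an exact-zero
  mean drops the sample.
* Dead-tied duplicate labels are dropped, not guessed.
* The classification head is a 2-way softmax; the reported probability is
  the positive class.
* Min-max normalization of atom importance maps a constant (or singleton)
  layer to 1.

## Known limitations

* Transductive entity vocabulary: prediction requires drugs and cell lines
  present in the fitted bundle (new SMILES would need a refit of nothing but
  the data bundle, but the current API does not splice them in).
* The exact published forms of the hypergraph normalization and the
  contrastive term live in supplementary material not available here; the
  standard HGNN propagation and a margin form on cosine distance are used
  and documented above as this package's definitions.
* Single-threaded CPU training only; the design target is desk-scale
  reproducibility, not GPU throughput.
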