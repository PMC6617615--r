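---
title: "Graph-convolutional classification of molecules into biosynthetic precursor categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-convolutional classification of molecules into biosynthetic precursor categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Alkaloids — nitrogen-containing secondary metabolites — derive their skeletons
from a small set of biosynthetic starting substances: amino acids such as
L-tyrosine or L-tryptophan, terpenoid precursors such as secologanin or
isopentenyl diphosphate, and a few others.  For most known alkaloids the
pathway, and hence the starting substance, is unknown.  Predicting the
starting substances of a compound from its structure alone is a *multilabel*
classification problem: a compound synthesised by condensation of several
precursors belongs to several categories at once, and a compound may also
match none.

`mgcnn` implements a molecular graph convolutional neural network (MGCNN)
for this problem, together with the evaluation harness and the
fingerprint/descriptor baselines needed to judge it.

## The model

A molecule is reduced to an abstract undirected graph: vertices are atoms
labelled only by element symbol, edges are bonds with order, aromaticity,
charge and stereochemistry deliberately discarded.  Hydrogens are explicit
vertices by default, since the input representation is a one-hot encoding of
the element over the training-set alphabet and H is an element like any
other; a flag removes them for heavy-atom-only experiments.

One **convolution stage** updates each atom's feature vector from its closed
neighbourhood with weights indexed by graph distance:

$$ v_i^{c+1} = \mathrm{ReLU}\Big( W_c(0)\, v_i^c + \sum_{j \sim i} W_c(1)\, v_j^c + b_c \Big) $$

Only distances 0 (the atom itself) and 1 (bonded neighbours) occur inside
the neighbourhood sum, so a stage carries exactly two weight matrices (plus
an optional bias, on by default; `use_bias = FALSE` gives the strict
bias-free form).  **Max-pooling** then replaces each atom's vector by the
element-wise maximum over the same closed neighbourhood.  We reuse the
convolution's "including the vertex itself" convention for pooling because
the pooling operation is otherwise underspecified; both operators therefore
see identical neighbourhoods.  After `n_stages` such stages (default 3,
width 128 throughout, so the receptive field of an atom is its radius-6
environment), a **gather layer** sums all atom vectors into one molecule
vector — making the whole network exactly invariant to atom reordering —
and K independent **paired-softmax heads** map it to per-category
probability pairs $(y_{kp}, y_{kn})$, $y_{kp}+y_{kn}=1$.  Because each pair
is normalised separately, categories do not compete: a molecule can receive
several positive calls, or none.  A positive call is $y_{kp} > 0.5$
(strictly); the threshold is a parameter of `predict()`.

The training loss for one molecule is the summed paired cross-entropy

$$ L = -\sum_{k=1}^{K} \big[ \hat y_{kp}\log y_{kp} + \hat y_{kn}\log y_{kn} \big], $$

with log arguments clamped below at `loss_epsilon` (default `1e-10`) so the
loss stays finite under saturated softmax outputs.  Reported training loss
is always the *mean* of per-molecule losses, independent of batching.

## Training

Weights are optimised with Adam (learning rate `1e-3`, standard moment
constants) for a fixed number of epochs (default 300).  Minibatches of 32
molecules are the default: a training epoch then performs several stochastic
updates, which is what lets the loss converge within roughly a hundred
epochs; full-batch training (one update per epoch) is available via
`batch_size` but needs correspondingly more epochs.  Inverted dropout is
applied to the one-hot input layer and after each pooling layer (defaults
0.2 and 0.2).  The published protocol this package follows describes "80%
dropout on the input layer"; we read that figure under the keep-probability
convention of the era's implementations (drop 0.2), because a literal 0.8
drop probability on the input removes nearly all structural signal from
small molecules — with it, the network cannot even fit its own training set
on the synthetic tasks below.  Both rates are plain drop probabilities in
this package and fully configurable, so the literal reading
(`dropout_input = 0.8`) remains one line away.

Initialisation is He-style scaled normal for the convolution stages (ReLU
appropriate) with zero biases.  The classifier head starts at exactly zero:
the gathered molecule vector's magnitude grows with molecule size, and a
randomly initialised head saturates the softmax pairs before the first
update (the loss would start at the clamp value rather than at its
theoretical no-information value $K\ln 2$).  With a zero head the first
epoch starts at exactly $K \ln 2$ per molecule.

Every source of randomness — initialisation, dropout masks, minibatch
shuffling, fold assignment — is derived from the `seed` in
`training_config()`, and two runs with identical seed, data and
configuration reproduce loss curves and weights bitwise.  Checkpoints are
single JSON files storing the architecture, alphabet, category names,
configuration and all weights at 17 significant digits, which round-trips
IEEE doubles exactly: a reloaded checkpoint predicts bit-identically.

Unknown elements at prediction time are a hard error per molecule (the
compound is skipped with a warning and listed in the result), never a
silent zero encoding, because an all-zero one-hot row changes the meaning
of the convolution sum.

## Evaluation

`cross_validate()` implements five-fold and leave-one-out cross-validation
with seeded, unstratified fold assignment.  When the same compound
contributes several samples, the harness deduplicates to one sample per
(compound, label row) by default and always assigns folds per compound, so
a compound never appears on both sides of a split.  "Accuracy" for category
k is defined as per-category binary accuracy — the fraction of held-out
samples whose thresholded call matches the label for k — and the global
average is the unweighted mean over categories.  This is the simplest
definition consistent with per-category accuracy bars plus a global average
("Av") in the work this package reimplements, which never states its
definition; the per-category 2×2 confusion tables are kept in the report so
any other summary can be recomputed.  `count_statistics()` compares how
many categories each compound was assigned to against the truth: mean
per-compound counts on both sides, the Pearson correlation between
per-category compound totals, and an OLS regression of predicted on
original totals with 95% confidence intervals (identity = perfect).
`stage_sweep()` repeats the cross-validation at several stage counts with
everything else fixed.

## Baselines

`run_baseline()` trains one independent binary classifier per category —
mirroring the network's independent heads — on any fixed descriptor matrix:
random forest, single-hidden-layer neural network, or radial-kernel SVM,
each with a small grid search (RF: `mtry` ∈ {√p, p/4}; NN: size ∈ {4, 8} ×
decay ∈ {0.01, 0.1}; SVM: cost ∈ {1, 10} × gamma ∈ {1/p, 0.1}) performed on
a 75/25 split inside each training fold.  `ecfp_fingerprints()` provides
1024-bit extended-connectivity fingerprints of diameter 2, computed by
OpenBabel (ECFP2) and folded from the toolkit's 4096 bits to 1024 by OR-ing
congruent positions.  External descriptor tables (e.g. from a descriptor
generator run elsewhere) enter through `read_descriptor_csv()`.

`select_features()` implements correlation-network descriptor reduction:
constant variables are dropped as non-informative, variables with
$|r| > 0.6$ (strict inequality, absolute value by default — strongly
anti-correlated variables are equally redundant) are linked into a
correlation network, and one seeded-random representative is kept per
connected component.  Both the threshold and the absolute-value choice are
arguments.

## The synthetic molecule generator

Real training data (the curated alkaloid pathway set) cannot be bundled, so
the package generates seeded synthetic datasets that exercise every code
path.  A molecule is grown as a random heavy-atom tree over {C, N, O, S}
under approximate valence capacities (C 4, N 3, O 2, S 2), with one
optional ring closure of size 5 (probability 0.5) and hydrogens attached to
remaining free valences; default sizes are 6–16 atoms, heavy fraction 0.6,
heavy-element probabilities C .60 / N .12 / O .20 / S .08.  These defaults
give every built-in rule a positive rate between 0.2 and 0.8 at n = 500.
Graphs are connected, respect the size range, and need not be chemically
valid — the network consumes topology and element identity only, which is
exactly what the generator controls.

Labels come from decidable structural rules evaluated on the final graph
(so labels are self-consistent by construction): element presence
(radius-0 information), presence of a 5-ring, and an element pair at graph
distance 2 (radius-2 information).  The rules deliberately need different
receptive-field radii so that deepening the network has something to gain,
which is what the stage-sweep experiment measures.

What passing on synthetic data does and does not show: the tasks prove the
operators, gradients, training loop and harness work end to end and that
the architecture's receptive field behaves as designed.  They do not
emulate the size (20–60+ atoms), bond-type diversity, class imbalance or
label noise of real natural-product data, so synthetic accuracies say
nothing quantitative about accuracy on real compound sets.

A known limitation surfaced by these tasks: detecting the *presence of a
ring* is a global property — on these graphs it is equivalent to the edge
count reaching the vertex count — and the max-pooling stages sit between
the convolution's degree information and the gather sum, so the exact
counting argument is not representable.  The network memorises the ring
task's training folds completely when dropout is off, yet its held-out
accuracy on that rule plateaus in the mid-0.8s at n = 200 with or without
dropout — a generalisation limit of the architecture on global properties,
not a regularisation artifact — short of the 0.9 the element-presence rule
comfortably exceeds.  The acceptance suite keeps the 0.9 expectation for
both rules and documents this one as the architecture's measured shortfall
rather than relaxing the bar.

## Numerical and design choices

* Pooling ties break toward the vertex itself, then the first-listed
  neighbour; tie-breaks only affect gradient routing, never forward values,
  so permutation invariance of the forward pass is exact.
* The oracle-style double-loop convolution used in the tests is an
  independent transcription of the stage equation; the package path is a
  batched dense/indexed implementation with C++ kernels for pooling,
  neighbour sums and ReLU.
* Problem sizes in the acceptance artifacts: 100 random operator instances,
  20×20 permutation probes, CV5 at n = 200 (two-rule task, 300 epochs) and
  n = 300 (distance-2 task, 150 epochs, stage counts 1 vs 3).  The 150-epoch
  runs reflect where the loss curves plateau (around epoch 100, consistent
  with the protocol this package follows); the criterion they serve is an
  inequality between depths, which is insensitive to the exact budget.
* Multi-fragment inputs (salts, mixtures) are accepted as disconnected
  graphs; every operator is well defined per component.
* `LOOCV` trains one model per sample and is intended for small n.

## Reproducing the shipped numbers

`scripts/acceptance.R --seed <s> --out <path>` regenerates all synthetic
inputs from the seed, runs the full pipeline and writes every measured
quantity (operator-oracle gaps, invariance error, gradient error, CV
accuracies, stage-sweep gain, feature-selection counts, loss identities) as
JSON.  The test suite asserts the same properties at fixed seeds.
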