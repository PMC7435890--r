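---
title: "Latent-space molecular similarity with a SMILES variational autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-space molecular similarity with a SMILES variational autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

"Find the 50 molecules most similar to my query" is the canonical unsupervised
question in cheminformatics, and its answer depends almost entirely on the
encoding used. Fingerprint methods (MACCS keys, Morgan/circular, atom pairs,
topological torsions, and the rest) each project a molecule onto a different
set of hand-designed structural features; Tanimoto similarities computed from
different fingerprints of the *same* pair of molecules routinely disagree
wildly. The clozapine panel bundled with this package is a sharp example: of
eight molecules with measured ability to inhibit clozapine uptake, only four
make the top 50 of *any* fingerprint ranking against clozapine, and the most
potent inhibitor (prazosin) appears in exactly one encoding, at a Tanimoto
similarity of 0.37.

`vaesim` implements an alternative: learn a continuous representation of
chemical space with a variational autoencoder (VAE) over SMILES strings, and
measure similarity as a function of Euclidean distance in the learned latent
space. Because the encoder is trained to make reconstruction possible, the
latent vector must retain what is structurally essential, and distances in
that space reflect the whole training distribution rather than a fixed
feature list.

## Model

A molecule's SMILES string is padded to a fixed window and one-hot encoded
character by character (`Cl` is two characters — the vocabulary is strictly
character-level, and the pad symbol occupies one vocabulary slot). At
reference scale the window is 248 positions over a 40-symbol vocabulary.

The encoder applies three valid 1-d convolutions with ReLU (9, 9 and 10
output channels; kernels 9, 9, 11), flattens, and maps through a
SeLU-activated fully connected layer to a bottleneck, from which two linear
heads emit the posterior mean `mu` and log-variance `logvar` of a diagonal
Gaussian over the 100-dimensional latent space. Training samples the latent
vector with the reparameterization trick, `z = mu + exp(logvar/2) * eps`.
The decoder maps `z` through a SeLU-activated linear layer, a 3-layer GRU
with 488 hidden units, and a linear/softmax head back to per-position symbol
scores. The loss is binary cross-entropy against the one-hot target plus the
closed-form KL divergence from the standard normal, unweighted. ADAM at
learning rate 1e-4 with batch size 128, Xavier-uniform initialisation,
no dropout and no pooling. All of this is implemented in vectorised base R
with hand-derived backpropagation; the gradients are pinned against central
finite differences in the test suite.

### Axis orientation

The printed layer sizes are only mutually consistent under an unusual axis
convention: the first convolution declares 248 *input channels* (the sequence
positions) and convolves along the 40-symbol axis, shrinking it
40 → 32 → 24 → 14 so that 10 channels × 14 = 140 feeds the `Linear(140, 100)`
bottleneck. Likewise the decoder head emits 248 values per GRU step, which
forces the GRU to be unrolled over the 40-symbol axis with softmax over the
248 positions. `vae_config(orientation = "paper")` (the default) reproduces
exactly these sizes. The conventional sequence-model layout — convolve along
the 248 positions, unroll the GRU over positions, softmax over the symbols at
each position — is available as `orientation = "conventional"` and is what
the reduced desk-scale configuration uses, because at small scale it is the
standard, better-behaved choice for sequence reconstruction.

### Two smaller wiring decisions

* The printed encoder lists *three* `Linear(140, 100)` maps: one followed by
  SeLU, then the mean and variance heads. We read this as a shared
  SeLU-activated 140 → 100 branch feeding 100 → 100 mean and log-variance
  heads, which uses every printed layer once; the bottleneck dimension and
  the `Linear(140, 100)` contract are unaffected.
* No start/stop tokens are used; the end of the decoded string is inferred
  from trailing pad symbols. The decoder is driven from `z` alone (no teacher
  forcing), so decoding is a pure function of `z`.
* The reconstruction loss is computed over all `max_len x vocab` entries,
  pad rows included; `mask_pad = TRUE` excludes pad rows for users who want
  the variant, but it is off by default since no masking rule is part of the
  reference configuration.

### Inference representation

A molecule's latent representation for all similarity work is the posterior
mean `mu`, not a sample: similarity between two fixed molecules should not be
a random variable, and `mu` is the distribution's centre. Reconstruction
accuracy is likewise evaluated through `mu`, making reported accuracies
deterministic given a checkpoint.

## The similarity metrics

For latent vectors `x, y` the package computes

```
E-Sim(x, y)  = 1 / (1 + d(x, y)),   d = Euclidean distance, x, y in R^100
EU-Sim(u, v) = 1 / (1 + d(u, v)),   u, v the first two UMAP dimensions
```

Both lie in (0, 1], equal 1 exactly at identity, are symmetric, and
`1/sim - 1` recovers a true metric. The typeset source formula is ambiguous
about whether the sum of squared differences sits under a radical; since the
accompanying text speaks plainly of "the Euclidean distance", the radical
reading is the default and the literal squared-sum reading is available via
`squared = TRUE` throughout.

Latent vectors are normalised across the corpus before comparison
(`normalize_latents()`). The reference protocol states that vectors are
normalised but not how; the default here is per-dimension min-max to [0, 1],
which is scale-free and keeps all dimensions commensurate. Z-scoring and
pass-through are selectable, and every embedding records the scheme applied
in its `normalization` attribute. Normalisation happens before UMAP
projection (the projection inherits the tag), one of several defensible
orderings; since UMAP is itself driven by the same Euclidean geometry, the
choice mainly affects the projection's scale, not its topology.

UMAP runs through the umap-learn reference implementation with default
parameters (`n_neighbors = 15`, `min_dist = 0.1`) and a fixed, recorded
random state. UMAP layouts are reproducible only per (input set, seed,
library version); published 2-d maps cannot be reproduced coordinates-for-
coordinates, and EU-Sim should be read as a visualisation-space similarity.

## The fingerprint baseline

The nine standard fingerprints (Atom Pair, Avalon, FeatMorgan, Layered,
MACCS, Morgan, Pattern, RDKit, Torsion) are computed by RDKit through a
bundled batch helper, with Tanimoto similarity, top-k tables and the
fingerprint-vs-latent scatter assembled in R. The hashed fingerprints
default to radius 2 and **1024 bits**: these parameters were calibrated once
against the published clozapine-vs-inhibitor panel, which reproduces every
pinned cell (MACCS 0.80, Morgan 0.53, Atom Pair 0.68 for olanzapine; MACCS
0.66 for chlorpromazine; Atom Pair 0.51 for quetiapine; Torsion 0.37 for
prazosin) to within ±0.01 — at 2048 bits the atom-pair and torsion values
fall outside that band. Pattern, Avalon and Layered fingerprints are
toolkit-version-sensitive; every table records the toolkit version, and only
the four stable encodings are treated as reference values.

## Synthetic data

Training the reference model takes days on a GPU and a multi-million
molecule corpus; nothing desk-scale can reproduce its Table of full-scale
accuracies (95.60 / 94.38 / 94.42 % valid reconstructions on
3.1 M / 1.24 M / 1.86 M molecules), and this package does not claim to.
What it does instead is make the *mechanism* testable. The
`generate_synthetic_smiles()` generator assembles random single-bonded
skeletons over {C, N, O, S, F} with valence bookkeeping, optional branching
(default probability 0.25) and at most one 5–6-membered ring (default
probability 0.3), 3–14 heavy atoms, every string validated and canonicalized
by the toolkit and deduplicated. A seeded spec is a pure function: same spec,
same corpus.

The generator emulates the *shape* of the learning problem — variable-length
strings over a closed grammar with rings, branches and heteroatoms — not
drug-like chemistry: no aromatic systems are assembled (though
canonicalization sometimes introduces aromatic notation), no charges, no
stereochemistry, no multi-ring scaffolds. Passing the desk-scale tests
therefore demonstrates that the architecture, codec and training loop learn
to reconstruct structured molecular strings; it says nothing about
ZINC-scale chemistry.

### Desk-scale study conditions

The scaled-down protocol used in the acceptance checks: 2,000 synthetic
molecules (canonical SMILES ≤ 24 characters), the reduced configuration
(`reduced_vae_config()`: window 24, latent 16, kernels 3/3/3, one 64-unit
GRU layer, conventional orientation, learning rate 2e-3 — raised from the
full-scale 1e-4 as appropriate for a model three orders of magnitude
smaller), 25 epochs, batch 128. This trains in about a minute on one CPU and
reaches ≥ 90 % valid decoded outputs on its training set with a wide margin
(typically ~100 % valid; perfect reconstructions stay low, as expected for a
KL-regularised model without teacher forcing at this budget). Epoch count
and early stopping are not specified at reference scale; the trainer
defaults to early stopping on validation loss with patience 5 when a
validation set is supplied, and to a fixed epoch count otherwise.

## Data handling

Corpora are split 50/20/30 into train/validation/test. Partition sizes are
floors of the fractions with the remainder assigned to the *last* partition
— the rule that reproduces the published counts (6,202,415 records →
3,101,207 / 1,240,483 / 1,860,725). Shuffling is a pure function of the
seed.

Checkpoints are versioned JSON carrying the configuration, the ordered
vocabulary, the initialisation seed, all parameters and the training
history, so any embedding is reproducible from a checkpoint alone.

## Numerical notes

* Decoder probabilities are clamped to [1e-7, 1 − 1e-7] inside the BCE and
  its gradient.
* `decode_one_hot()` breaks argmax ties toward the lowest vocabulary index,
  making decoding fully deterministic.
* The all-vs-all similarity matrix computes row-wise differences rather than
  the `||a||² + ||b||² − 2a·b` expansion; the expansion's cancellation error
  breaks the exact unit diagonal that the identity axiom requires.
* Min-max normalisation sets zero-range dimensions to 0 with a warning
  rather than dividing by zero.
* ReLU units sitting exactly at their kink (which genuinely occurs with
  zero-initialised biases and sparse one-hot inputs) make finite-difference
  gradient checks disagree with the (sub)gradient; the test suite jitters
  parameters off the kink before checking.

## Limitations

* The desk-scale model memorises a small corpus; generalisation claims
  require the full-scale corpus and budget.
* Latent similarity is only as meaningful as the space the model was trained
  on; embeddings of molecules far outside the training distribution (e.g.
  drugs encoded by a model trained on tiny synthetic molecules) are
  mechanically valid but chemically uninformative.
* EU-Sim depends on a stochastic projection and is for visualisation-space
  reasoning only.
* Maximum-common-substructure similarity, grammar/junction-tree encoders and
  de-novo generative design are out of scope.
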