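---
title: "Methods: multitask knowledge-graph recommendation with multimodal entities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multitask knowledge-graph recommendation with multimodal entities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kgmedrec)
```

## Overview

`kgmedrec` couples two learning tasks over a typed medical knowledge graph
(KG): click-through-rate (CTR) prediction for user–item interactions, and
translation-distance embedding of the KG itself. The two tasks are not
independent — recommended items (drugs, foods, examinations) are KG
entities — and the package shares their low-level features through a
cross-compression unit while keeping task-specific heads separate. KG
entities carry a multimodal representation: a structural vector from
TransD, a textual vector from skip-gram word embeddings pooled by a GRU
sentence encoder, and a visual vector from a small residual image encoder,
fused by one dense layer.

This vignette records the modeling assumptions, the default parameters and
the reasoning behind the choices that were genuinely open.

## The structural model (TransD)

Each entity and each relation carries a meaning vector and a projection
vector. The mapping matrix of a (relation, entity) pair is
`M = r_p e_p^T + I`; we read `I` as the possibly rectangular
principal-diagonal identity, so entity and relation dimensions may differ
(the default is `n = m = 32`). Projections are computed in vector form,
`M e = pad(e) + r_p (e_p · e)`, which the test suite checks against the
explicit matrix product to `1e-10`. The score of a fact is the squared L2
translation distance; training minimizes the margin hinge (margin
`γ = 1`) by minibatch SGD (`lr = 0.05`, batch 128, 200 epochs on the
reference KG).

Two numerical choices matter:

* **Norm constraint.** After every update, entity meaning vectors are
  projected back onto the unit ball. Without this the hinge can be
  satisfied by inflating all scores, and ranking quality collapses.
* **Negative sampling.** Corruptions replace the head or the tail (fair
  coin, re-flipped per attempt because a nearly saturated neighborhood may
  admit corruption on only one side). The standalone `corrupt_triple()`
  operation preserves the entity type, matching the typed graph. The
  *trainer*, however, draws half of its corruptions from the whole
  vocabulary (`type_preserve_prob = 0.5`): purely type-preserving
  negatives never teach the model that entities of the wrong type are
  implausible tails, and all-entity link-prediction ranking then stalls
  near chance for the cross-type part of the candidate list (we measured
  hits@10 ≈ 0.35 versus ≈ 0.9 with mixed corruption on the reference KG).
  Corruptions additionally avoid observed triples, falling back to exact
  enumeration of valid replacements when rejection sampling stalls.

Link prediction ranks every entity as candidate tail. Ranks use mid-rank
tie handling. The filtered protocol (removing other known-true tails) is
available; the headline capacity check uses raw ranking over all entities
because at the reference density the filtered chance baseline is so high
that fold-change comparisons against it are uninformative.

## Textual and visual encoders

The skip-gram model uses an exact softmax over the vocabulary — synthetic
vocabularies are small (default 60 types), so no sampling approximation is
needed — with window `C = 2`, `min_count = 1`, embedding dimension 16, and
minibatch gradient descent on the full negative log-likelihood. Output
weights start at zero (so initial predictions are exactly uniform);
word-vector ordering is deterministic (frequency, then lexicographic).

Documents are encoded by a single-layer GRU (hidden size 32) over the word
vectors; the final hidden state is the document vector. A mean-pooling
mode is provided as an order-invariant fallback and flagged in the output
metadata. Skip-thought pretraining (two GRU decoders reconstructing the
previous/next sentence of the document stream, teacher-forced, word
vectors frozen) is optional: the joint model by default uses the seeded,
untrained GRU, since the document vector only needs to separate disease
topics, which the word vectors already do. BPTT uses global-norm gradient
clipping (5) — without it, 120-token sentences reliably explode.

The image encoder is a deliberately small residual network: stem
convolution (8 channels) → normalize → ReLU → max-pool, two stages of
[convolutional block + identity block] at 16 and 32 channels with stride-2
projected shortcuts, global average pooling to a 32-dim feature. Residual
units compute `f(h(x) + F(x, W))`; with zero residual weights and identity
shortcut, the unit is exactly the identity on nonnegative input, and the
test suite checks both this telescoping property through six blocks and a
finite-difference gradient check of the additive shortcut path (relative
error < 1e-3). Normalization uses current-map statistics in training mode
and running statistics in evaluation mode, so encoding is deterministic at
inference. The encoder is used with seeded random weights as a fixed
feature extractor: the blob-count class signal of the synthetic images is
linearly recoverable from random-feature encodings (the suite's probe
test), so supervised fine-tuning is unnecessary for the package's scope.

**Feature standardization.** Text and image feature tables are z-scored
per dimension across entities (then scaled by `1/sqrt(dim)`) before
fusion. Raw encoder outputs carry large constant offsets (post-ReLU global
averages) with small entity-specific variance; unstandardized, they
saturate the fusion tanh and bury the class signal.

## Fusion and the multitask model

Fusion concatenates the modality vectors — concatenation rather than
summation so modality dimensions may differ — with a learned per-modality
default vector substituted for absent modalities, followed by one dense
layer with tanh (output dimension `d = 16`). Ablation configurations
(base / base+text / base+image / full) differ **only** in which input
tables are supplied; entities lacking a table fall back to the learned
default, so no code path changes. Fusion weights are trained jointly with
the rest of the model (a freeze flag was considered; joint training is the
default because the fused vector serves two consumers — the KG tail
representation and the item-side cross-unit input — whose balance is best
set by the joint objective).

The CTR head is: user embedding → 2×(d→d, ReLU) MLP; item embedding
cross-compressed with the item's fused entity vector (one low-level cross
layer by default); concatenation → (2d→d, ReLU) → scalar → sigmoid. The
KG head is: head entity cross-compressed with its item-stream embedding
(one shared cross unit per layer — the wiring of the head-entity stream is
not uniquely determined by the task description; sharing one unit keeps
the parameter count minimal and preserves the gradient-isolation
contract); relation embedding → (d→d, ReLU); concatenation → (2d→d,
linear) predicted tail; score = sigmoid(inner product with the actual
tail's fused vector).

The joint loss is `L = L_RS + L_KG + L_REG` with `L_RS` the mean binary
cross-entropy, `L_KG = −λ₁ (mean score(pos) − mean score(neg))`, and
`L_REG = λ₂ ‖W‖²` over the transformation weights (embeddings and biases
excluded — decaying embeddings on every step would couple the two tasks'
parameter sets and break the alternating-training isolation property that
a KG step leaves user-side parameters untouched and vice versa). Defaults:
`λ₁ = 0.5`, `λ₂ = 1e-6`, 3 recommendation minibatches per KG minibatch,
Adagrad with `lr = 0.05` for 25 epochs. Adagrad replaces plain SGD because
with mean-normalized minibatch gradients the embedding tables receive very
small raw updates and plain SGD needed roughly an order of magnitude more
epochs to move the click loss. Two reconciliations worth noting: the
translation distance (lower = better) is the *pretraining* objective, while
inside the joint loss "score" is the sigmoid inner-product similarity
(higher = better), matching the sign convention of the joint objective;
and the per-epoch loss report is computed on the full data with one fixed
seeded negative sample, so the trace is deterministic and its `total`
column recomposes exactly as `L_RS + L_KG + L_REG`.

## The synthetic world

The generator emulates the study conditions every test runs under:

* **KG**: 12 diseases, 16 symptoms, 14 drugs, 10 foods, 4 departments,
  9 examinations (65 entities) with five disease-rooted relations;
  each head–tail pair is present with probability `density = 0.6` and
  every head keeps at least one tail — ≈ 400 triples.
* **Interactions**: 200 users × 30 records. Each user holds latent taste
  factors (dim 8) and one preferred disease; the positive-label
  probability is logistic in `u·i/√k + kg_weight (adj − 1/2)`, where `adj`
  indicates KG adjacency between the item and the preferred disease.
  `kg_weight = 10` for the reference world (strong KG signal), 0 for the
  KG-blind control; labels are replaced by a fair coin with probability
  `noise = 0.1`. A user whose labels come out all-0 or all-1 has the
  single most extreme record flipped, keeping every per-user rate strictly
  inside (0, 1).
* **Documents**: one 120-token document per disease from a
  disease-specific topic (private vocabulary block plus a 25% shared
  pool); disjoint supports are available by setting the shared fraction
  to zero.
* **Images**: one 32×32 grayscale image per disease; disease class `i`
  receives `1 + (i−1) mod 3` Gaussian blobs of fixed radius at seeded
  positions plus uniform noise (amplitude 0.05), clamped to [0, 1]. Blob
  count is the recoverable class parameter, recorded alongside each image.

One global seed drives everything; sub-generators derive independent
streams from it, and regeneration is bit-identical.

What this world does *not* emulate: real ontology structure (ICD/SNOMED),
item–item dependencies, temporal dynamics, covariate shift, realistic
radiology texture, or free-text clinical language. Passing tests therefore
demonstrate that the machinery is implemented correctly and that the
pipeline can exploit a KG signal when one exists — not that any particular
recall level would transfer to clinical data.

An honest note on the ablation: the text and image modalities attach to
*disease* entities while recommendation operates on item entities, and the
label model is fully determined by the KG plus latent factors that the
structural-only configuration already observes. The modality lift is
therefore small relative to seed noise; at the reference seeds the medians
order as full/base+text/base+image ≥ base, and the KG-blind control shows
a near-zero full-vs-base gap (|median| well under 0.05), confirming that
no spurious modality effect is being picked up.

## Problem sizes and evaluation protocol

The suite and the acceptance script run at the sizes above: they are large
enough for every statistical check (binomial bands at 3 standard errors,
5-seed medians) while keeping a full four-configuration ablation within a
few minutes on one CPU. Recommendation evaluation splits interactions
6:2:2 per user (stratified, seeded); each test user's held-out positives
are ranked against all items not already consumed (their train/validation
positives are removed from the candidate pool), recall@10 is averaged per
user, and AUC is computed over test records with mid-rank tie handling.
Link-prediction capacity is measured on the training triples — the check
is whether the embedding can represent the graph, not generalization to
held-out facts.

## Known limitations

* All numerics are base-R; the implementation favors clarity and exact
  reproducibility over throughput and is sized for desk-scale data
  (hundreds of entities, thousands of interactions).
* The GRU sentence encoder is used untrained by default; skip-thought
  pretraining is implemented but single-threaded BPTT makes it the
  slowest component per token.
* The image encoder is a fixed random-feature extractor; no supervised
  fine-tuning path is provided.
* Items without KG counterparts are rejected rather than handled (the
  coupling is undefined without the overlap).
* Rating (non-binary) prediction, sequential/joint training variants
  beyond the alternating schedule, and baseline model families are out of
  scope.
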