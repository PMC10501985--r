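---
title: "Deep-feature retrieval of histology patches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep-feature retrieval of histology patches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histocbir)
```

## The retrieval model

`histocbir` performs query-by-example retrieval of H&E-stained tissue
patches. A patch is represented by a *deep feature*: the activation of an
intermediate layer of a pre-trained convolutional backbone, reduced from its
`H x W x C` spatial form to a one-dimensional descriptor. The stored
descriptors form a feature bank; at query time the query patch's descriptor
is scored against every bank row with cosine similarity
`s(q, x) = <q, x> / (||q|| ||x||)` and candidates are returned in decreasing
similarity. Cosine makes ranking invariant to positive per-vector rescaling,
which is why descriptors are stored un-normalized.

The underlying assumptions are those of transfer learning: a network trained
on natural images yields intermediate activations discriminative enough for
tissue morphology, without fine-tuning. Which layer and which reduction work
best is an empirical question, so the package treats both as first-class,
swept parameters rather than fixed choices.

### Reductions

Three reduction operators collapse a map to a vector:

* **GAP** — per-channel spatial mean, length `C`. Spatially invariant.
* **GMP** — per-channel spatial max, length `C`. Spatially invariant and
  elementwise ≥ GAP on every channel.
* **FLATTEN** — row-major linearization (channel index fastest), length
  `H·W·C`. Retains spatial layout; retrieval is invariant to any fixed
  permutation of positions, so only consistency of the memory order matters,
  and it is fixed once here.

### The catalogue

The nine supported backbones, their square input sizes (224, 299, 331 or
480 px), pixel-normalization modes and tapped layers are shipped as a
versioned JSON catalogue rather than code. The catalogue records each
layer's `H`, `W`, `C` and the resulting pooled (`C`) and flattened
(`H·W·C`) descriptor lengths; at extraction time every backend output is
validated against it and a mismatch is a hard error. Shape drift between
backbone implementations is the main silent-failure mode in this kind of
pipeline, and a catalogue mismatch should stop an indexing run, not warn.

Two cataloguing choices were genuinely open. The NASNetLarge layer family
uses the `normal_concat_*` naming throughout, treating an inconsistent
spelling of `normal_concat_12` found in some published materials as the same
layer. Xception defaults to three representative layers (entry flow, last
middle-flow block, exit flow); the ten-layer variant covering all eight
middle-flow outputs is available behind `list_backbones(extended = TRUE)`.

### Preprocessing

Patches are decoded to RGB (grayscale replicated, alpha dropped), resized to
the backbone's input side with bilinear interpolation (the interpolation is
not dictated by the retrieval model; bilinear is the conventional default
and `resize_patch()` exposes nearest-neighbour for sensitivity checks), and
normalized per backbone:

* `SCALE_SYMMETRIC`: `x/127.5 − 1`, exactly spanning [−1, 1] on 0..255.
* `SCALE_UNIT_IMAGENET`: `x/255`, then per-channel `(x − mean)/sd`.
* `BGR_ZERO_CENTER`: channel reversal then subtraction of per-channel means,
  no scaling.
* `IDENTITY`: unchanged.

The ImageNet channel statistics used by the two centering modes are data in
the catalogue (conventional values: BGR means 103.939/116.779/123.68; unit
means 0.485/0.456/0.406 with sds 0.229/0.224/0.225), overridable per call —
they are conventions of the pre-trained weights, not constants of the
method. No stain normalization is applied anywhere in the default pipeline;
it is deliberately out of scope.

## The extraction backend

The network itself is an injected interface: a function
`(backbone, layer, input) -> H x W x C map` wrapped by `new_backend()`. The
built-in `seeded_backend()` is a deterministic random-projection extractor:
it block-averages the normalized input to the layer's spatial grid,
RMS-normalizes it, and applies a fixed random linear map from the three
colour channels to `C` channels followed by a ReLU, with weights drawn once
per (backbone, layer) from a seed derived from the backend seed and the
layer name. It is sensitive to colour and coarse texture — exactly the
signals the synthetic patch classes carry — and it never touches the
caller's RNG stream. It is not a convolutional network and makes no claim to
semantic features; it exists so that indexing, banking, ranking, evaluation
and selection are all exercised end-to-end, offline, with bit-reproducible
results. A backend wrapping pre-trained weights plugs into the same
interface and is validated against the same catalogue.

## The feature bank

Banks persist as a single HDF5 file: dataset `/features` stored in 32-bit
floating point (a 400-patch flatten bank can reach 400 x 1.8M values, so
storage halving matters), with labels, ids and provenance as a JSON metadata
attribute plus a schema version. Similarity is always computed in 64-bit.
To make the persistence round trip an exact identity, the in-memory matrix
is rounded through float32 at bank construction; the rounding is an explicit,
documented part of the storage contract rather than a hidden property of the
file format.

## Ranking determinism

Ties in cosine similarity occur in practice (duplicated patches) and are
broken by ascending item id so that P@k is reproducible. For tie-breaking to
engage, duplicated vectors must score *bit-identical* similarities; BLAS
matrix-vector products can round identical rows differently depending on
their position in the matrix, so similarities are accumulated per candidate
in a fixed order (`colSums` over the transposed bank) instead. Zero-norm
vectors — query or bank row — are an error, not a silent similarity of 0: a
zero GAP descriptor indicates a dead layer or a backend bug upstream.

## Evaluation framework

Every bank item queries the bank of the remaining `N − 1` items
(leave-one-out), and `P@k = I_r/K` is computed at each depth, by default
`k ∈ {5, 10, 50, 100}`. **MAP@k here is the plain mean of P@k over
queries** — not interpolated mean average precision from the IR literature;
the naming follows common usage in patch-retrieval benchmarking, and the
distinction matters when comparing numbers across papers. Confusion matrices
at depth k put the query class on rows and the retrieved class on columns;
entry (i, j) is the mean over class-i queries of the fraction of their top-k
items in class j (macro-averaged over queries, so rows sum to 1 and the
diagonal is per-class mean P@k).

`GLP_m@k = P_ref@k − P_m@k` quantifies the gain (positive) or loss of a
reference configuration. Three selection procedures build on it:

* **Reduction selection** — the reduction maximizing the grand mean of P@k
  over all layers, backbones and depths; the per-backbone average gain/loss
  table of GAP against GMP and FLATTEN is attached for audit. Exact ties
  resolve in the fixed order GAP, GMP, FLATTEN.
* **Layer selection** — unanimous per-depth argmax wins outright; otherwise
  the candidates are the per-depth winners and the choice minimizes the
  total deficit `Σ_k (max_layer P@k − P_cand@k)`. The published benchmark
  describes this rule qualitatively ("minimizes the loss"); the total
  deficit across depths is this package's formalization, and the pairwise
  gain/loss report is always attached so the choice is auditable. Remaining
  ties prefer the smaller descriptor, then the earlier name.
* **Backbone comparison** — one (chosen layer, fixed reduction) row per
  backbone, ranked by P@5 descending, ties by P@10 then name.

Applied to the bundled published benchmark cells, the layer-selection rule
reproduces the published choices for all three conflicted backbones
(MobileNetV2 `block_14_add`, NASNetLarge `normal_concat_12`, VGG16
`block5_pool`).

```{r}
select_best_layer(benchmark_layer_cells("MobileNetV2"))$layer
```

## Synthetic data: what it emulates and what it does not

Two generators provide fixtures with known expectations.

`generate_feature_bank()` draws class `c` as `separation · e_c + noise`,
with orthonormal standard-basis centroids (requiring `dim ≥ n_classes`) and
isotropic Gaussian noise. Orthogonality makes two regimes exactly
analyzable: at `separation = 0` the items are exchangeable and leave-one-out
precision has expectation `(per_class − 1)/(N − 1)`; at
`separation ≫ noise_sd` every query's `per_class − 1` class mates dominate
the ranking and `MAP@k = 1` for `k ≤ per_class − 1`. Defaults (4 classes x
100 items) mirror the canonical balanced four-class breast-histology patch
collection, with class names invasive/insitu/benign/normal; `dim = 64`,
`separation = 4`, `noise_sd = 1` give a clearly structured but not degenerate
default bank.

`generate_patch_dataset()` writes PNG patches in class subdirectories with a
CSV manifest. Classes differ in mean colour (hue angles equally spaced) and
stripe frequency, both with amplitude proportional to `separation`, over
pixel Gaussian noise (`noise_sd = 8` on the 0..255 scale by default). The
default 64 px side keeps the canonical 400-image collection cheap to
generate; patch geometry is irrelevant to the pipeline contracts being
exercised.

Neither generator attempts histological realism — no stain simulation, no
nuclei, no spatial tissue structure. Passing tests on synthetic data
demonstrate that the machinery (extraction plumbing, banking, ranking,
metrics, selection) is correct and deterministic; they say nothing about the
discriminative power of any particular backbone on real tissue, which
requires real data and pre-trained weights.

## Numerical choices and degenerate inputs

* Similarities in 64-bit regardless of the bank's 32-bit storage.
* Tie tolerance in selection procedures: `1e-12` on P@k cells, which are
  ratios of small integers and exact in double precision.
* `top_k` beyond the candidate list, evaluation with `N ≤ max(k)`, empty
  candidate sets, heterogeneous vector provenance, duplicate ids and
  zero-norm vectors are all explicit classed errors rather than silent
  degradation.
* All randomness (backend weights, generators) flows from explicit seeds
  through an RNG-state-preserving scope; repeated runs are bit-identical.

## Problem sizes used in the test suite

The suite validates the leave-one-out protocol at the canonical 400-item
bank size (dimension 32), the ranking oracle on 100 random banks of up to
50 x 16, chance-level calibration on 50 independent 100-item banks
(4 x 25, dimension 16), and image-pipeline runs on 4 x 5 to 4 x 8 patch
collections at 24 px through VGG16-shaped layers. These sizes are chosen so
the full suite completes in well under a minute while every contract is
exercised at, or above, the scale at which its behaviour changes.

## Known limitations

* The built-in backend is a random projection; absolute retrieval numbers on
  real histology require a pre-trained backend supplied by the user.
* The bank is a flat index; ranking is exact brute force over all rows (no
  approximate nearest-neighbour structures), which is the intended protocol
  up to a few thousand patches.
* Only balanced-class expectations are derived analytically; the confusion
  matrix macro-averages over queries, which differs from pooling retrieved
  items when retrieval counts are unbalanced.
* No stain normalization, augmentation, WSI tiling, recall/F-measure, or
  statistical testing of precision differences.
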