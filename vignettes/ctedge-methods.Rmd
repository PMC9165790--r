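---
title: "Edge-aware CT-like image segmentation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-aware CT-like image segmentation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
open design questions were settled the way they were. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The problem

Computed-tomography slices show soft-tissue lesions as compact bright blobs
inside a larger body region. Delineating them automatically runs into two
failure modes: generic edge detectors fire on noise as readily as on true
anatomy, and region classifiers blur boundaries because boundary pixels are
a vanishing fraction of the image. `ctedge` combines an explicit
edge-point pipeline (detect, cluster, de-noise, score, link) with two small
convolutional networks — a patch classifier and an encoder–decoder pixel
labeler — all trainable in minutes on one CPU core.

## Synthetic phantoms as the study condition

Every stage is exercised on seeded synthetic phantoms
(`phantom_params()`, `generate_phantom()`):

* one body ellipse with semi-axes about 0.35 and 0.28 of the frame
  (roughly 70% coverage), random orientation and a small center jitter;
* zero to three lesions: discs with base radius 6–14 px whose boundary
  radius is modulated by cosine harmonics of order 2–4 with amplitudes up
  to 6% each, giving smooth, closed, non-circular outlines;
* intensities background 0.05, body 0.55, lesion 0.85 (gray levels in
  [0, 1]) and additive Gaussian noise with standard deviation 0.05 — a
  contrast-to-noise regime where boundaries are visible but individual
  pixels are unreliable;
* a 1:4 lesion:normal image ratio (`lesion_fraction = 0.2`), mirroring a
  200/800 tumor/normal dataset composition; the lesion-bearing subset is
  chosen by a seeded shuffle so the ratio is exact, not approximate.

Ground truth is exact: the binary lesion mask and an edge map holding the
8-connected inner boundary pixels of the lesions and the body ellipse.
Identical parameters and seed reproduce a phantom bit for bit.

What the phantoms do **not** model: CT physics (beam hardening, HU
calibration, reconstruction streaks), textured parenchyma, 3-D slice
correlation, and anatomy other than one convex body. Passing tests
therefore demonstrate correctness of the algorithms and trainability under
controlled contrast and noise — not clinical performance.

## Edge-information integration

* **Detection.** 3×3 Sobel magnitude, replicate-padded, normalized so a
  unit intensity step responds with 1. Pixels at or above `f_low`
  (default 0.1) are candidates; `f_high` (default 0.3) flags strong ones;
  the per-point response is `max(0, g − f_low)`. The dual threshold keeps
  faint-but-real boundary evidence while the cluster stage, not the
  detector, is responsible for rejecting isolated noise responses.
* **Clustering.** Single-linkage agglomeration under the Chebyshev metric
  (radius 2 px by default): edges are pixel chains, and Chebyshev linkage
  is the metric consistent with 8-connectivity. The implementation buckets
  points on a grid so only neighboring cells are compared; a property test
  checks it against an O(n²) union-find oracle.
* **Noise elimination.** Clusters with fewer than `f0` points are dropped.
  `f0` trades recall of short true edges against noise suppression: an
  isolated impulse raises a ring of at most 8 candidates, merged impulse
  pairs up to 16, so `f0` around 20 removes impulse noise while boundary
  chains (hundreds of points) are untouched. The default `f0 = 8` is the
  permissive setting for low-noise use.
* **Position scores.** `score = min(1, 2A′/(f_L+f_H)) · exp(−j/n_c)`,
  with `A′` the thresholded response, `j` the 0-based within-cluster rank
  (by decreasing response) and `n_c` the cluster size. The exponential
  rank attenuation realizes "down-weight redundant members of a cluster"
  while a single-point cluster keeps exactly its normalized response.
* **Similarity algebra.** Feature vectors are min–max normalized
  (a constant feature maps to 0), similarity is the bounded
  `h_p = 1/(1+d)` with `d` Euclidean; the super-pixel similarity smooths
  `h_p` through the row-normalized measure matrix `F`
  (`h_k = S h_p Sᵀ`) and renormalizes so self-similarity is exactly 1.
  With `F` the identity, `h_k = h_p`. The per-point weighted proportion is
  `G_H = Σ_f m_f h_{k,f}` with weights below `1/(10p)` zeroed. These
  formulas are the package's own, deliberately simple, reading of an
  edge-weighting scheme whose published algebra is not evaluable as
  printed; each choice is bounded, symmetric where it should be, and unit
  tested against brute-force evaluation.
* **Linking.** Per cluster, greedy nearest-neighbor chaining from the
  highest-scoring point; ties break on lowest `(row, col)` everywhere, so
  the output is deterministic.

## The patch classifier

The fixed architecture (six 5×5 kernels, 2×2 max pool, sixteen 5×5
kernels, 2×2 max pool, fully connected, two-way softmax) gives the size
chain 28 → 24 → 12 → 8 → 4 for a 28-pixel input and 50 → 46 → 23 → 19 → 9
for a 50-pixel input; odd pooling inputs drop their trailing row/column.
Design points the architecture description leaves open were fixed as:
ReLU after convolutions, cross-entropy loss, SGD with momentum 0.9, and a
2-logit softmax output (equivalent to a single sigmoid for two classes,
but symmetric with the segmenter's classifier). A patch is labeled
positive when the central 8×8 window contains a ground-truth edge pixel —
centering avoids border ambiguity; the labeling rule is a stated
convention of this package, since no canonical rule exists for
patch-level "edge segmentation success".

## The encoder–decoder segmenter

Default architecture (3 stages, channels 4/8/16, 3×3 kernels):

* **Encoder.** Two conv + indexed max-pool stages (128 → 64 → 32). Each
  2×2 pooling window stores its argmax position (ties: first in row-major
  window order); storing indices instead of feature maps is the cheap way
  to preserve boundary information through down-sampling.
* **Dilated bottleneck.** The deepest stage drops pooling and stacks
  dilated convolutions with rates 1, 2, 4 — a combined receptive field of
  side 15 at quarter resolution — growing context with no extra weights
  and no further resolution loss. At build time the bank is min–max
  rescaled to its initialization range, the package's operational reading
  of "normalize the up-sampled filter bank".
* **Decoder.** Each stage unpools through the stored indices (sparse,
  exactly one nonzero per window), superimposes the encoder feature map of
  the same resolution pixel by pixel (the multi-scale fusion idea; it also
  gives training a direct gradient path to fine-scale intensity evidence),
  then densifies with `E′ = conv(E)·packet/(packet+1) + E` — a residual
  "dense decode" whose packet scale (default 4) tempers the filter term.
  A dilated head (rate 2) emits two per-pixel scores; softmax–argmax
  yields the labels, ties to the lower class id.
* **Loss and optimization.** Weighted cross-entropy plus `1 − softDice`
  on the lesion class. The lesion-class weight is computed from the
  training set so both classes carry equal total mass (capped at 100);
  pixels within 2 px (Chebyshev) of a true edge get weight 3 — the
  operational form of "the boundary detail loss coefficient increases".
  Updates are Adam (step 2e-3, batch 4 images) under global gradient-norm
  clipping at 5. He initialization and leaky ReLU (slope 0.1) keep the
  narrow feature maps trainable. This combination was chosen because the
  obvious alternative — momentum SGD with a hand-set class weight — is
  bistable on heavily imbalanced masks: depending on the seed it can
  collapse into the all-background local optimum and never recover.
  Analytic gradients of the full network are verified against finite
  differences in the test suite.

The numbers the package's own acceptance script computes at desk scale:
250 phantoms (seeded), 200 for training, 30 epochs, 50 held out; it
reports pixelwise accuracy of the first run and lesion recall averaged
over three training seeds. These sizes keep a full run near ten minutes on
one core; they are stated here as the package's chosen benchmark
condition.

## Numerical conventions

* All convolutions are correlations (no kernel flip), zero same-padding in
  the networks, replicate padding for the Sobel stage so flat frames give
  zero response at borders.
* Pooling ties take the first maximum in row-major window order; argmax
  ties take the lowest class id; chaining ties take the lowest
  `(row, col)`.
* Dice of two empty masks is 1 by convention; recall with no relevant
  pixels is reported as missing (`NA`), never as 0.
* "Within 1 px" in edge-localization reports means Chebyshev distance at
  most 1 (the 8-neighborhood), matching the package-wide 8-connectivity
  convention; means and medians are Euclidean.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state (`withr::with_seed`); train histories are bit-reproducible.

## Known limitations

* The phantom generator produces one convex body; multi-organ scenes,
  occlusions and texture are out of scope.
* The edge-similarity algebra (`h_p`, `h_k`, `G_H`) is one consistent
  reading of an under-specified scheme; alternative readings would change
  point weights but not the clustering or linking machinery.
* The segmenter is two-class; extending to multi-class labeling would need
  per-class Dice terms and a wider head.
* Checkpoints store doubles without compression; models are small (tens of
  kilobytes), so no effort was spent on quantization.
* Training-time measurements are hardware-dependent and intentionally
  never asserted; only loss and quality metrics are.
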