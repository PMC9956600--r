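---
title: "Detecting standing dead trees in aerial RGB tiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting standing dead trees in aerial RGB tiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(snagdetect)
```

## The problem

Standing dead trees (snags) matter for forest-health monitoring and
carbon accounting, but finding them across large forests is laborious.
Nadir RGB tiles from survey drones show dead crowns as sparse,
gray-brown structures against green canopy — a detectable signature,
complicated by three things: crowns span a wide range of apparent
sizes, small crowns are easily lost to downsampling in deep feature
extractors, and several common objects (discoloured live crowns, bare
soil) have nearly the same colour as dead wood.

`snagdetect` implements a two-stage detector built around three ideas:

1. a **hierarchical windowed-attention backbone** that models
   long-range context at a cost linear in image size;
2. a **balanced feature pyramid** that averages all scales at one
   reference resolution, refines the average with a non-local
   (all-pairs) attention block, and redistributes it to every level, so
   small-object levels receive semantic context from coarse levels and
   vice versa;
3. **dynamic training**, which adapts the positive/negative assignment
   threshold and the regression-loss shape to the evolving quality of
   the region proposals.

Everything — including reverse-mode automatic differentiation — is
implemented in R on base matrices, so the whole pipeline runs and
trains on a single CPU at reduced scale.

## Backbone

The image is cut into 4 × 4 patches; each patch is flattened to a
48-vector and linearly embedded to `C` channels.  Four stages of
transformer blocks follow; between stages, *patch merging* gathers
every 2 × 2 token neighbourhood (concatenate → layer-norm → linear
4c → 2c), halving resolution and doubling channels.  The stage outputs
U1..U4 have strides 4, 8, 16, 32 and channels C, 2C, 4C, 8C.

Each block computes multi-head self-attention inside non-overlapping
M × M token windows,

\[ \mathrm{Attn}(Q, K, V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt d} + B\right) V, \]

where `B` is a learned relative-position bias, a table of
\((2M-1)^2\) entries per head indexed by the relative coordinates of
each token pair.  Blocks alternate between plain windows (W-MSA) and
windows shifted by ⌊M/2⌋ (SW-MSA): the map is cyclically shifted,
attention is computed with an additive mask that forbids pairs that
were not contiguous before the shift, and the shift is undone.  This
gives cross-window information flow while keeping the
\(4hwC^2 + 2M^2hwC\) cost (see `wmsa_cost()`) linear in `h·w`.
Attention and MLP sub-layers are both residual with pre-layer-norm and
a GELU MLP.

Numerical choices: softmax is computed shift-by-max; grids that do not
divide by M are zero-padded with padded keys masked out (padding never
leaks into real tokens — this is tested); no absolute position
embedding is added, since the relative bias carries position.  The
linear patch embedding is read as the standard learned projection of
the raw patch vector.  Dropout and stochastic depth default to off.

## Pyramid neck with balanced enhancement

A top-down pyramid turns U1..U4 into S1..S4: S4 is U4 through a
transformer block; each lower level is
`block(lateral(U_i) + expand(S_{i+1}))`, where *patch expanding* is the
inverse of merging (linear c → 2c, then rearranging channel quarters
into a 2 × 2 spatial block — doubling resolution, halving channels, so
the top-down path needs no extra reshaping at any width).  The expand
path carries two blocks by default and the lateral path one; all three
counts are configurable, and the reduced test profile uses one each —
at desk scale the extra blocks add cost without measurable benefit on
synthetic scenes.  Each level is finally projected to a common width
`D` (default 256; the head convention — the architecture does not fix
it).

The balance step resizes all four levels to the S2 resolution —
bilinear interpolation upward (half-pixel-centre convention, fixed so
the hand-computed test oracles are reproducible), max-pooling downward
(kernel = stride = the integer scale factor) — and averages them with
equal weight 1/L.  The average is refined by an embedded-Gaussian
non-local block: similarity \(f(x_i, x_j) = e^{\theta(x_i)^\top \phi(x_j)}\),
normalised over all positions (softmax), value map `g`, channel
reduction D → D/2 inside the block, output projection and a residual
connection.  Unlike windowed attention, the non-local similarity is
*not* scaled by \(1/\sqrt d\); the implementation cancels the scaling
internally, and the 2 × 2 double-loop oracle test pins this convention.
The refined map is resized back to every level and added, giving
P1..P4.

One reading decision: the fused level is implemented as element-wise
addition of the lateral and upsampled maps followed by one transformer
block; a per-channel weighting of the fusion is not implemented, as no
construction for the weights is specified anywhere and plain addition
is the standard choice.

## Detection head and dynamic training

A shared RPN (3 × 3 neighbourhood gather + linear, GELU, then
objectness and box-delta layers) scores one anchor scale per level
(side = 8 × stride) at aspect ratios {0.5, 1, 2}.  Proposals are
decoded, clipped, filtered by NMS at 0.7 and capped (1000 train / 300
test).  RoI-Align pools each proposal's level (chosen by matching
√area to the level's anchor scale) into a 7 × 7 grid by averaging 2 × 2
bilinear samples per bin; a fully connected layer then feeds a
snag/background softmax and a 4-vector box regression.  None of the
anchor/sampling budgets are architecturally fixed; defaults follow
common two-stage practice and sit in `det_config()`.

Training assigns a proposal to the positive class iff its best IoU
against ground truth reaches the *current* threshold `T_now`
(inclusive), starting at 0.5.  Each iteration records the k-th largest
proposal-vs-truth IoU (k at the 75th-percentile rank) and the k-th
smallest centre-coordinate regression error (k = 10; the error of a
proposal is the mean of its |dx| and |dy| in encoded coordinates —
width/height are deliberately excluded).  Every 100 iterations `T_now`
becomes the mean of the recorded IoU statistics (clamped to
[0.4, 0.9]) and the smooth-L1 transition `beta_now` the median of the
recorded error statistics; records are then cleared.  The smooth-L1
loss is

\[ \ell(x) = \begin{cases} 0.5\,x^2/\beta_{now} & |x| < \beta_{now} \\ |x| - 0.5\,\beta_{now} & \text{otherwise} \end{cases} \]

— continuous with continuous derivative at the joint.  Before the
first boundary the defaults (0.5, 1) apply.  Two rank ambiguities were
resolved as: the recorded statistic is a *rank* (quantile) of the
per-iteration list, not a count; and errors are recorded after the
assignment of the same interval.  The optimiser is AdamW (lr 1e-4,
batch 4, linear decay, up to 100 epochs, early stop after 20 epochs
without validation improvement); one source names SGD for comparison
runs only, and AdamW is the configuration followed here.

## Synthetic scenes: what they emulate, what they do not

The generator (`generate_scene()`) emulates 512 × 512 nadir tiles:
textured green canopy (base colour, low-frequency waves, white noise),
live crowns as irregular green blobs, dead crowns as unions of 3–7
jittered disks plus radial branch strokes — the sparse defoliated
silhouette — in a gray-brown colour model, and two confuser types
(discoloured live crowns, bare-soil blobs) that sit close to dead wood
in colour.  Dead crowns alone are annotated; each box is the tight
envelope of the crown's *visible* support (overpainted pixels
excluded), and the realised size class follows the 32² / 96² area
thresholds.  Small/large crown radii default to (4, 9) and (50, 70) px
so the two populations straddle those thresholds.  Determinism: every
scene is a pure function of its seed; dataset seeds fan out from a
master seed by a fixed affine hash.

What passing synthetic tests does **not** show: real crowns vary with
species, sun angle and phenology; occlusion comes from parallax, not
painting order; soil and understory have spatial structure the
generator lacks.  Synthetic results validate the machinery (losses
decrease, proposals align, metrics compute correctly), not field
accuracy.

The **easy profile** (`scene_config_easy()`) used by the CPU-scale
training runs is 128 × 128 tiles, 2–4 dead crowns of radius 5–16 px,
no confusers, no overlap, and a widened colour margin.  The
end-to-end checks train the reduced model profile (C = 24, depths
(1, 1, 2, 1), M = 4, D = 32, lr 1e-3) on 200 such scenes for 4 epochs
(~200 optimiser steps) and evaluate on 50 held-out scenes; the
single-scene overfit check runs 40 steps at lr 2e-3.  These problem
sizes were chosen so a complete run finishes in minutes on one core
while leaving a wide margin over the AP50 = 0.5 sanity bar.

## Evaluation conventions

Matching is greedy in descending score order; each detection consumes
the unmatched ground-truth box of highest IoU at or above the
threshold, so one box over two truths counts one TP and one FN.  The
P-R curve pools detections across the dataset; AP is the 101-point
average of the right-envelope interpolated precision (the COCO
convention; an exact all-point integral is available via
`interpolation = "all_points"`).  Reported recall and F1 are taken at
the score threshold that maximises F1, and that threshold is printed —
the operating point of a published table is otherwise unknowable.
Size-stratified AP averages IoU 0.50:0.05:0.95 over ground truth in
the area class, ignoring detections that match an out-of-class box.
True negatives are reported as not applicable: detection has no
meaningful TN count.  Degenerate boxes score IoU 0 with a warning;
zero-denominator precision/recall return 0 with an explicit flag.

## Data pipeline decisions

Boxes are 0-based half-open throughout; COCO files use (x, y, w, h).
"Random rotation" in augmentation is restricted to k·90° so box remaps
stay exact — arbitrary angles would change box semantics.  Tiling
drops residual margins rather than padding (edge policy otherwise
unspecified), and re-stitching the tiles reproduces the covered region
bit-exactly.  Split counts are floor(n·f) for train and validation
with the remainder to test (568 source tiles → 397/56/115); augmented
copies inherit their source tile's split, and augmented copies of test
tiles are dropped entirely, because the test split must contain no
augmented data.  The augmentation multiplicity is configuration, not a
fixed constant.  Image I/O supports PNG and TIFF; geographic centres
require a caller-supplied geotransform.

## Known limitations

* Training at the full profile (C = 96, 512 × 512 tiles) is
  prohibitively slow in pure R; the package is a faithful, testable
  implementation of the architecture, not a GPU trainer.  Published
  field-accuracy figures are not reproducible here: the underlying UAV
  dataset is private and the headline numbers were produced at GPU
  scale.
* The R autodiff engine supports exactly the operations this detector
  needs; it is not a general framework.
* `coef()` returns the flattened parameter vector (1.8 M entries for
  the reduced profile) — useful for checkpoint diffing, not for
  inspection.
* Checkpoints are `.rds` files written at run time by the CLI; no
  cross-version stability is promised.
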