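---
title: "Methods: multiscale convolutional attention for brain tissue segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale convolutional attention for brain tissue segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mscaseg` segments skull-stripped T1-weighted brain volumes into
cerebrospinal fluid (CSF), gray matter (GM) and white matter (WM), plus
background. This vignette describes the model, the losses, the evaluation
metrics and the synthetic phantoms the package uses to exercise the whole
pipeline on a desk-scale CPU budget. Code chunks are illustrative and not
evaluated when the vignette is built.

## The network

The segmenter is a five-stage 3D encoder–decoder. Each encoder stage halves
all three spatial axes with a strided convolution, so a patch is reduced by
factors 2, 4, 8, 16 and 32; the decoder mirrors this with five transposed
convolutions (kernel and stride 2) and concatenates the encoder feature map
of matching resolution before each decoder stage. All convolutions are
followed by instance normalization and a GELU nonlinearity. The default
channel plan is (32, 64, 128, 256, 320); the `arch_config_tiny()` preset
used throughout the examples shrinks it to (8, 16, 32, 64, 64).

The distinctive ingredient is the **3D multiscale convolutional attention
(MSCA) block** used in the deeper halves of the encoder and decoder stages.
A block computes, for input features $X$:

$$\mathrm{Att} = \mathrm{Conv}_{1\times1\times1}\Big(\sum_{i=0}^{3}
\mathrm{Sca}_i\big(\mathrm{Conv_D}(X)\big)\Big), \qquad
\mathrm{Out} = \mathrm{Att} \otimes X,$$

where $\mathrm{Conv_D}$ is a $5^3$ depth-wise aggregation convolution,
$\mathrm{Sca}_0$ is the identity, and each $\mathrm{Sca}_i$ for
$i \in \{1,2,3\}$ is a chain of three depth-wise *strip* convolutions of
extent $k_i \in \{5, 7, 11\}$ along the x, y and z axis in turn. A strip
triple of extent $k$ has the same receptive field as a dense $k^3$ kernel at
a fraction of the parameters, and the three extents give the attention map
a multiscale character. The $1\times1\times1$ convolution mixes channels and
the result reweighs the block input element-wise. `msca_params()`,
`msca_init()` and `msca_block()` expose the block on its own:

```{r}
library(mscaseg)
prm <- msca_params(channels = 16)
wts <- msca_init(prm)
y <- msca_block(x, wts)   # x: (16, X, Y, Z) feature array
```

Every decoder stage carries a $1\times1\times1$ segmentation head, so one
forward pass yields five softmax predictions at resolutions $1/16$ through
full. `build_network()`, `forward_pass()` and `describe_network()` build,
run and summarise the network.

## Losses

Training minimises
$L_\mathrm{total} = L_\mathrm{Seg} + \lambda\, L_\mathrm{Data}$.

**Deep-supervised segmentation loss.** Each of the five heads is trilinearly
upsampled to label resolution, renormalised per voxel, and scored with the
sum of a soft Dice loss and a cross-entropy; the per-head sums are combined
with weights $(1/32, 1/16, 1/8, 1/4, 1/2)$ so that finer heads dominate.
The Dice term averages the per-class soft overlap over the three tissue
classes (background is excluded from this average, mirroring common practice
for class-imbalanced medical volumes). The cross-entropy averages over
**all** voxels, background included: background voxels must carry a
supervised target, since after instance normalization a uniform background
window is indistinguishable from a uniform tissue window by intensity
statistics alone, and only an explicit background target lets the network
learn to emit class 0 there.

**Edge-overlap data-quality loss.** Real annotation errors concentrate at
tissue boundaries. Each training patch is assigned a quality weight
$W_\mathrm{Data} \in [0,1]$: the Dice overlap between the slice-wise Canny
edge map of the raw intensity patch and that of its label patch
(`canny_edges()`, `edges_of_labels()`, `quality_weight()`). A patch whose
label boundaries sit on image edges scores near 1; a patch whose labels have
been displaced (eroded, dilated, jittered) scores lower. $L_\mathrm{Data}$
is $W_\mathrm{Data}$ times the cross-entropy of the full-resolution head, so
suspect patches contribute proportionally less extra gradient. Setting
`lambda_ = 0` ablates the term. Two conventions close the degenerate cases:
two empty edge maps give weight 1 (a background-only patch carries no
evidence of label error), and exactly one empty map gives 0.

All pieces — including the softmax, the trilinear upsampling and the
per-voxel renormalisation — are differentiated analytically in
`total_loss_grad()`, which the test suite checks against central finite
differences.

## Training and inference

`train_model()` runs patch-based SGD: every iteration samples
foreground-biased patches (with probability `fg_bias` the patch is centred
on a tissue voxel, drawn class-balanced so that small structures such as WM
are seen as often as large ones), scores each patch's label quality on the
raw intensities, augments with axial flips and right-angle rotations,
standardises intensities with the volume's z-score, and applies an SGD step
with momentum 0.99 and weight decay $3\times10^{-5}$ under a poly learning
rate $0.01\,(1 - e/E)^{0.9}$ stepped per epoch. `predict_volume()` runs
Gaussian-weighted sliding-window inference with 50% overlap and crops back
to the input shape.

Two desk-scale caveats are worth stating. First, with $32^3$ patches the
fifth encoder stage has a $1^3$ spatial extent, where instance
normalization degenerates (a single location normalises to zero, leaving
only the learned shift); the deepest head therefore contributes little, and
its deep-supervision weight of $1/32$ keeps that harmless. Second, the
iteration counts used in the examples and tests (hundreds, not the
$500 \times 250$ of a full schedule) are deliberately small so that
everything runs in minutes on one CPU; segmentation quality is accordingly
far below what the architecture reaches at scale.

## Phantoms

Since real MRI cohorts are out of scope, `generate_phantom()` builds
synthetic supervision: three nested ellipsoidal shells (CSF outside GM
outside WM) with per-tissue mean intensities, a smooth multiplicative
polynomial bias field, and Rician noise — the standard T1 artefact model.
`corrupt_labels()` produces controlled annotation errors (morphological
erosion/dilation, boundary jitter, random class swaps) with a severity
knob, which is what the quality-weighting experiments corrupt. The
phantoms are deliberately simple: they have no gyral folding, no partial
volume effect and no skull remnant, so absolute scores on them do not
transfer to real brains; they are fixtures for exercising and testing the
machinery, not a benchmark.

## Metrics

`evaluate_segmentation()` reports per-class Dice (percent) and the 95th
percentile Hausdorff distance (HD95, mm). HD95 computes, for each voxel of
one mask, the exact Euclidean distance to the nearest voxel of the other
mask via a distance transform, takes the 95th percentile of each directed
distance set, and symmetrises with the maximum; it is robust to stray
voxels that dominate the plain Hausdorff distance. Empty masks make the
distance undefined and yield `NA`, which the macro average skips and
reports. `paired_test_bonferroni()` provides the paired t-test with
Bonferroni correction used when comparing per-case scores of two models.
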