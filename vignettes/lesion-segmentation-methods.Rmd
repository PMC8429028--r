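---
title: "Segmenting diabetic-retinopathy lesions with an encoder-attention-decoder network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting diabetic-retinopathy lesions with an encoder-attention-decoder network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Diabetic retinopathy (DR) produces four characteristic lesion types in color
fundus photographs: microaneurysms (MA, small round dark-red capillary
distensions and the earliest detectable sign), hemorrhages (HE, larger
irregular dark-red bleeds), hard exudates (bright yellow lipid deposits with
sharp boundaries) and soft exudates (pale cotton-wool spots with fuzzy
boundaries). Pixel-level segmentation of all four classes, followed by
connected-component counting, gives clinicians lesion loads they can map
directly onto grading guidelines. `eadseg` implements such a pipeline
end-to-end: geometric normalization of the photographs, joint image/mask
augmentation, a convolutional encoder-attention-decoder segmentation
network, a training protocol with a plateau learning-rate schedule, and a
component-overlap evaluation metric, all testable on a built-in synthetic
image generator.

## The network

The model is a U-shaped fully convolutional network with three
modifications aimed at small, low-contrast lesions.

**Encoder.** A stem convolution (3x3, `base_channels` filters) is followed
by the *only* max-pooling layer in the whole network. Every later
downsampling step is a stride-2 convolution inside a residual block:
repeated pooling discards exactly the high-frequency evidence that tiny
microaneurysms live in, while strided convolutions keep the reduction
learnable. Each encoder stage doubles the channel count. The residual
blocks use a bottleneck: the two internal 3x3 convolutions run at
`out_channels / bottleneck_ratio` (default ratio 4) before a third
convolution restores the output width; a *conv block* projects its shortcut
through conv+BN (used when shape changes, stride 2), an *identity block*
adds the input directly. All kernels are 3x3.

**Dual attention.** The two deepest encoder maps pass through a dual
attention module: a shared conv-BN-ReLU, then a position attention module
(PAM) and a channel attention module (CAM) whose outputs are summed. PAM
forms an N x N affinity between all spatial positions (N = H'W'), softmax-
normalized per row, and replaces each position by the affinity-weighted sum
of value-projected positions; CAM does the analogue across the C channels
with a C x C affinity. Both add their result to the input through a
learnable scalar initialized at zero, so the modules start as identities
and the network eases into using global context. Because the affinity is
quadratic in map area, configuration validation rejects attention on maps
larger than 64 x 64 positions.

**Dilated block and decoder.** At the bottom of the encoder three
sequential 3x3 convolutions with dilation rates (1, 2, 5) enlarge the
receptive field to 17 x 17 without further downsampling; the mixed,
pairwise-unequal rates avoid the gridding artifact of stacked equal
dilations. The decoder mirrors the encoder: bilinear 2x upsampling
followed by a convolution (chosen over transposed convolution to avoid
checkerboard artifacts), concatenation with the encoder map of the same
scale, dropout (default rate 0.5), and a fusing convolution. A final 1x1
convolution produces one sigmoid channel per lesion class: the problem is
multi-label (lesions of different classes may touch), not multi-class.

Channel widths per stage are not uniquely determined by the design brief;
this implementation doubles from `base_channels` per stage with bottleneck
width `out/4`, and pairs one conv block with one identity block per stage,
following ResNet stage conventions. The dilated block sits after the
attention module at the deepest stage.

## Training protocol

Training minimizes `BCE + (1 - Dice)`, averaged over classes, with Adam at
learning rate 1e-4, batch size 2 and dropout 0.5 (package defaults mirror
that protocol; the bundled desk-scale configurations raise the rate and
shrink dropout because their networks are far smaller). The Dice term is
smoothed by 1 in numerator and denominator so empty-mask classes are well
defined. The monitored quantity is the mean training loss per epoch: when
it fails to decrease for 5 consecutive epochs the learning rate is
multiplied by 0.1, and after 15 epochs without decrease training stops;
the best-loss parameters are kept. Both rules are implemented as a pure
state machine over the loss sequence (`simulate_schedule()`), so their
semantics are testable without a network: a loss that plateaus from epoch
1 drops the rate at epoch 6 and stops at epoch 16. "Improvement" means
any decrease; there is no minimum delta. Datasets are split 2:1
train:test (81 images split 54/27), with no overlap. A validation
partition is not part of the protocol; the split helper accepts any ratio
should one be wanted.

## Preprocessing and augmentation

Fundus photographs arrive at many sizes with a black frame around the
circular field of view. `normalize_image()` crops to the tight bounding
box of pixels whose maximum channel exceeds a threshold (default 10/255;
the frame is never perfectly black), pads the short side symmetrically
with black so height equals width (odd remainder to bottom/right), and
resizes to 1024 x 1024 — aspect ratio of the content is preserved because
padding precedes the square resize. Masks follow the identical transform
with nearest-neighbor resampling (bilinear would bleed labels) and
re-binarization; `to_train_resolution()` then takes both to the network
input size (512 by default), and `invert_record()` maps predictions back
to original coordinates.

Augmentation applies, per emitted sample, a random *subset* of: horizontal
flip, vertical flip, per-axis scaling (0.9-1.1), translation (up to 10% of
the side) and rotation (within 15 degrees), composed into a single affine
resample. Magnitude ranges are package defaults, exposed in
`augment_config()`. The expansion factor is 5 with originals always
included. Out-of-frame regions are filled with black, matching the fundus
background.

## The evaluation metric

Pixel-exact confusion counting underestimates detections that are merely
outlined imprecisely, and lesion counting alone says nothing about
localization. The package therefore scores by component matching: with
detected components `D_1..D_N` (union `D`) and true components `G_1..G_M`
(union `G`), a pixel is **TP** iff it lies in `D ∩ G`, in a `D_i` with
`|D_i ∩ G|/|D_i| > σ`, or in a `G_j` with `|G_j ∩ D|/|G_j| > σ`; **FP**
iff it lies in a `D_i` disjoint from `G` or in `D_i \ G` for an
under-matched `D_i`; **FN** symmetrically on the truth side; **TN**
otherwise. The inequality is strict; at `σ = 0` any detection touching
the truth is credited in full, and `σ = 0.2` is the default working
point. When rules of several categories apply to one pixel, TP wins.
Sensitivity, specificity, precision, accuracy and F1 follow from the
pooled counts. Connectivity is 8 by default (4 available); ROC/AUC and
precision-recall/AUPR curves are computed at pixel level on the raw
sigmoid probabilities, with trapezoidal areas. Components are extracted
with `igraph` over the pixel-adjacency graph; the test suite checks the
whole metric against a literal brute-force transcription of the set rules
and against BFS flood fill.

## The synthetic generator

`generate_image()` emulates what the pipeline needs from real data: a
circular field of view on a black frame (exercising border removal), a
reddish-orange background with smooth shading and noise, dark curvilinear
vessel-like strokes (the classic false-positive source for hemorrhage
detectors), and the four lesion classes with their clinical morphology —
MA as 2-5 px near-circular dark-red dots, HE as 5-20 px irregular dark-red
blobs, hard exudates as 4-15 px sharp bright-yellow blobs, soft exudates
as 10-25 px pale blobs whose boundary is Gaussian-feathered *in the image
only*; masks always record the exact pre-blur support, mirroring how
annotators outline cotton-wool spots. Lesions are placed by rejection
sampling without inter-class overlap, wholly inside the field of view,
until a per-class target area fraction is met; the default fractions (MA
0.10%, HE 1.03%, hard 0.90%, soft 0.38% of total image area) follow the
published per-dataset averages for a widely used benchmark. Generation is
deterministic per seed.

What the generator does *not* emulate — illumination gradients from real
optics, the optic disc and macula, camera noise statistics, inter-grader
annotation variance, and the extreme foreground/background imbalance of
4288 x 2848 clinical frames — bounds what the tests can show: a passing
suite demonstrates the machinery (geometry, gradients, metric, protocol)
is correct and the network can fit fundus-like signal, not that clinical
benchmark performance would be reproduced.

## Numerical choices and problem sizes

Feature maps are `C x (H·W·n)` matrices; 3x3 convolutions run as im2col +
GEMM in compiled code, with a pure-R shifted-GEMM reference kept as an
oracle; the full backward pass is verified against central finite
differences. Bilinear 2x upsampling is a sparse separable operator whose
backward pass is its exact transpose. Batch norm uses batch statistics in
training (momentum 0.1 running estimates for inference) and epsilon 1e-5;
softmax rows are max-shifted; BCE clips probabilities at 1e-12; dropout is
inverted. Max-pool ties route the gradient to the first maximum in tap
order. He initialization for convolutions; attention scales start at 0.

The shipped test and demonstration configurations are deliberately small
so a laptop CPU can run them: 64-128 px images, 8-16 base channels, tens
of epochs. They are scale models of the 512-px, 64-channel default
configuration, which the same code runs unchanged; only wall-clock, not
correctness, depends on the scale. The overfit check (4 images at 128 px,
width 16, Dice > 0.9) uses learning rate 5e-3 without dropout, appropriate
for memorization rather than generalization.

## Known limitations

- Training is single-device, CPU-oriented; at the full 512/64
  configuration a GPU framework would be orders of magnitude faster.
- The position-attention memory footprint limits attention to maps of at
  most 64 x 64 positions; attention on shallower stages is rejected
  rather than approximated.
- No photometric augmentation or illumination normalization is provided.
- AUC/AUPR are pixel-level; component-level curves are not implemented.
- The multi-label head trains all four classes jointly; training one
  class at a time is possible by setting `num_classes = 1` and supplying
  single-class masks.
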