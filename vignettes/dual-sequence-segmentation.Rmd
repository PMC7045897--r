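---
title: "Dual-sequence MRI tumor segmentation: model and methods"
author: "ddunet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-sequence MRI tumor segmentation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Nasopharyngeal carcinoma is delineated for radiotherapy on MRI, where the
tumor shows different signatures on different pulse sequences: on
T1-weighted images part of the lesion can be nearly isointense with normal
tissue (a hypointense sub-region carries no tumor contrast), while on
T2-weighted images the lesion is bright but so is some normal tissue next
to it. Neither sequence alone suffices; a segmentation model that fuses
both can resolve what each one leaves ambiguous. `ddunet` implements a
fully automatic pipeline for this setting: paired-sequence preprocessing,
a dense dual-path encoder-decoder network trained with a soft Dice loss,
3D connected-component post-processing, and a patient-level
cross-validation harness, together with a synthetic phantom generator that
reproduces exactly this dual-ambiguity structure so the whole pipeline is
testable without patient data.

## The network

Each sequence enters through its own encoder block (three 3x3
convolutions; group normalization and a leaky ReLU, slope 0.1, after the
first two; the third at stride 2 for downsampling). The two paths are
concatenated channel-wise and fused by a dense connectivity block: `m`
micro-blocks, each the sequence GN - LReLU - 1x1 conv (bottleneck, 4K
channels) - GN - LReLU - 3x3 conv (K channels), where micro-block `i`
receives the concatenation of the block input and all previous micro-block
outputs, so the width after `m` micro-blocks is `in + mK`. A transition
block (GN, 1x1 convolution compressing back to the dense input width, 2x2
average pooling) ends the fusion stage. Further encoder stages downsample
to the bottleneck; one decoder block per downsampling (3x3 transposed
convolution at stride 2, concatenation with the matching encoder features,
two 3x3 convolutions with GN and LReLU) restores the input resolution, and
a 1x1 convolution with a pixel-wise sigmoid emits the probability map.
The single-sequence ablation differs only at the entry: one path, whose
first-stage output feeds the dense block directly.

With `s` encoder stages the network downsamples `s + 1` times (the extra
halving is the transition pooling), so there are `s + 1` decoder blocks
and the input size must be divisible by `2^(s+1)`; the default four stages
give five decoder blocks on 256x256 inputs. Skip connections tap the last
pre-downsampling feature map of each encoder stage, the pre-pooling
transition output, and (at full resolution) the concatenated first-stage
features of both paths. Two stated decoder readings conflict — three-conv
decoder blocks at stride 2 would shrink the maps and could never restore
the input size — so the decoder convolutions run at stride 1.

Group normalization is used instead of batch normalization because
training runs at batch size 1, where batch statistics are meaningless; the
default of 8 groups requires every normalized width to be divisible by 8
(tiny test configurations use 4 groups for the same reason). All
convolutions are zero-padded to preserve spatial size; weights are
He-uniform initialized from a recorded seed, so builds and inference are
bit-reproducible.

## Training

The objective is the soft Dice loss `1 - (2 sum(pg) + s) / (sum p + sum g
+ s)` with smoothing `s = 1` by default, which keeps the loss defined on
slices with empty masks. Optimization is Adam at learning rate 1e-4
(defaults `beta1 = 0.9`, `beta2 = 0.999`), batch size 1, 200 epochs, with
per-sample augmentation: a horizontal flip with probability 0.5 and a
spatial rescale drawn from [0.9, 1.1] applied identically to both channels
and the mask (nearest-neighbour for the mask, so it stays binary).
"Re-scaling" is read as spatial zoom; an intensity-scaling variant is
selectable. All slices in range are trained on, including those with empty
masks, and the final-epoch weights are the model — no early stopping and
no checkpoint selection.

Two numerical safeguards matter at small scale. First, gradients are
clipped to a global L2 norm of 1 before each update: small
group-normalized networks trained with a pure Dice objective on
mostly-empty slices otherwise show catastrophic mid-training collapse into
the all-background solution (a near-constant feature map makes the GN
variance tiny and its gradient explosive). Second, the final classifier
bias starts at +1, biasing the initial output toward foreground; starting
near the empty attractor can saturate the sigmoid before the lesion
gradient takes hold. Both are configuration options (`clipNorm`, the
initialization is fixed) and neither changes the objective.

## Preprocessing

The chain is fixed: (1) rigid co-registration of channel 1 onto the
channel-2 grid; (2) 50% in-plane downsampling of everything to
channel-1-like resolution (linear interpolation for images,
nearest-neighbour for the mask, floor division for odd sizes); (3)
per-volume min-max normalization of the images (constant volumes map to
zero); (4) zero-padding / centered cropping of each slice to the network
input size. The mask travels through the identical geometric operations
as the images so voxel correspondence is exact, and binarity is preserved
at every stage; a strict mode resamples the mask linearly and re-binarizes
at 0.5 instead. Registration runs on raw intensities and normalization
follows it.

Registration maximizes histogram-based mutual information (32 bins) over a
rigid transform (translation + rotation about the fixed-volume centre;
translation-only and affine are selectable — rigid is the natural model
for same-session intra-patient sequences), optimized by a (1+1)
evolutionary strategy: a Gaussian perturbation of the parameters is
accepted when it improves the metric, the search radius (initial 0.004,
growth 1.05 on success) shrinks on rejection, and the budget is 300
iterations. The translation starts at the intensity centre-of-mass
alignment (the standard moments initializer). Transforms that leave less
than half of the fixed grid covered by the moving volume are rejected:
without that floor, mutual information rewards shrinking the overlap.
The registration never returns a transform whose metric is worse than the
identity.

## Post-processing and evaluation

The sigmoid output is thresholded at 0.5 (ties to foreground), connected
components are labeled in 3D (26-neighbourhood by default; 6 and 18 are
exposed because the choice changes component counts), and every component
confined to a single axial slice is removed — a 2D per-slice network has
no out-of-plane context, so isolated single-slice detections are almost
always false positives. Nothing else is done: no hole filling, no
smoothing, no largest-component selection.

Evaluation compares binary volumes voxel-wise: Dice `2TP/(2TP+FP+FN)`,
sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, computed per patient on
the pooled 3D volume. Degenerate cases follow declared conventions: Dice
is 1 when both masks are empty (agreement on absence, logged), sensitivity
and precision are reported as missing — never as 0 — when their
denominator is empty. Cross-validation splits patients (never slices)
into k folds differing by at most one in size; the dual-versus-single
comparison trains all three input variants under identical folds and
seeds and compares per-fold mean Dice with a two-sided Mann-Whitney U
test (exact for small untied samples; per-patient pooling is available
but per-fold means are the default sample, k per model).

## The phantom

The generator emulates the statistical structure the pipeline assumes: a
head-sized tissue ellipsoid on a dark air background; inside it,
axis-aligned ellipsoidal lesions (per-axis radii drawn uniformly from a
configured mm range) that are hyperintense on channel 2; bright confuser
blobs on channel 2 only, voxel-disjoint from the lesions; on channel 1 the
lesion appears at its own level except for a connected hypointense
sub-region — a half-space cut through the lesion whose plane offset is
solved (binary search on the unit-ball cap volume after mapping the
ellipsoid to a sphere) so it covers a configured fraction of the lesion
volume. Channel 1 is sampled on its own coarser grid, displaced by a
configurable misregistration offset; the channels get independent
additive Gaussian noise, clipped to non-negative. The gold mask marks
exactly the lesion voxels of the channel-2 grid, mirroring masks drawn on
the T2-weighted series. Identical seeds give bit-identical studies.

Default geometry follows clinical head protocols — channel 1 at
0.93 x 0.93 x 4 mm, channel 2 at 0.48 x 0.48 x 4 mm, 4 mm slices — on a
128 x 128 x 32 testing-scale grid (full 256 x 256 is a configuration
away). Intensity levels (air 0.02, tissue 0.35, channel-1 lesion 0.6,
channel-2 lesion and confusers 0.85, noise sd 0.05) are free parameters
chosen to give clear but not trivial contrast; no cohort intensity
statistics exist to calibrate them against. The head ellipsoid exists for
registration realism: a uniform bright background would make the
centre-of-mass initializer meaningless and the mutual-information
landscape structureless.

What the phantom does *not* model: irregular lesion shapes, bias fields,
k-space artifacts, partial-volume effects, or realistic tissue texture.
Passing tests on phantoms therefore demonstrates that the machinery is
correct — geometry, losses, gradients, bookkeeping, metrics — not that
the trained network reaches any particular accuracy on clinical images.

## Problem sizes used in the tests

The automated checks run the real pipeline end to end at reduced scale,
chosen so each stage still exercises its full code path: the overfit
check trains a base-8 four-stage network on ten copies of one 64 x 64
slice for 100 epochs (final Dice loss well under 0.05, post-processed
Dice 1.0 on its own mask); the input-comparison check uses 12 phantom
patients at 32 x 32 after preprocessing, two-stage networks (8/16
channels, K = 8, m = 2), 2-fold cross-validation, 14 epochs at Adam
5e-4, replicated over three seeds with the directional expectation that
the dual model's mean Dice is at least each single-sequence model's in
the majority of replicates. At this scale individual folds are noisy (a
tiny net on six patients can train poorly), which is why the criterion is
directional and majority-based rather than a fixed accuracy. The
learning rates of these small fixtures are higher than the 1e-4 clinical
default because the fixtures take two orders of magnitude fewer steps.

## Known limitations

The network runs on CPU in R; the full-size default configuration is
practical for inference and small studies but not for 200-epoch training
runs on a clinical-scale cohort.
Registration is rigid/affine only — no deformable model — and the
mutual-information metric uses hard histogram binning rather than Parzen
windows. The decoder's exact skip tap points and per-stage widths are
configuration-relative design choices; no published weight values exist
to compare against.
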