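---
title: "Anti-aliased blur-attention segmentation of cell nuclei"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anti-aliased blur-attention segmentation of cell nuclei}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blurseg)
```

## The problem

Nucleus segmentation assigns every pixel of a microscopy image to nucleus or
background and, beyond that, separates the individual nuclei from one
another. It is hard for the usual reasons: heterogeneous illumination, stain
and magnification differences across samples, small and densely packed
objects, and noise. `blurseg` implements an encoder–decoder convolutional
network for this task whose distinctive ingredients are *anti-aliased*
(blur-pooled) downsampling, channel/spatial *blur attention*, a *pyramid blur
pooling* decoder module, and auxiliary strided skip connections — together
with everything needed to exercise the method end to end on synthetic data:
preprocessing, training with pretraining/fine-tuning, object-level
evaluation, and a seeded scene generator.

## Anti-aliased pooling

Plain strided max pooling aliases: shifting the input by one pixel can change
the pooled features substantially. Blur pooling decomposes max pooling into
dense (stride-1) max evaluation, low-pass filtering, and naive subsampling:

```
blur_max_pool(x) = subsample_s( k * densemax_2x2(x) )
```

where `k` is a normalized binomial kernel (`make_blur_kernel(3)` is the
`[1,2,1]` tent squared). Because `k` sums to one, constants pass through
unchanged; because the low-pass filter sits between the max and the
subsampling, small input shifts perturb the output far less than with plain
stride-2 max pooling. The test suite quantifies this operationally: over
random images, the mean feature drift under a 1-pixel circular shift is
strictly smaller for `blur_max_pool()` than for plain max pooling.

Numerical conventions, chosen once and fixed:

* the blur kernel defaults to size 3 (configurable); size 1 degenerates to
  ordinary convolution/pooling;
* padding is *reflect* (mirror without edge repetition), so borders do not
  darken;
* the dense max window is 2×2 at stride 1, with windows clamped at the
  border so the pre-subsampling map keeps the input size;
* subsampling starts at index 0 (top-left phase), giving output side
  `ceiling(n / stride)`.

The stride-1 "blur convolution" used as the network stem (`blur_conv()` with
`stride = 1`) *does* apply the low-pass filter after the learned convolution
— i.e. the anti-aliasing is kept even when no subsampling happens. That is a
deliberate reading of an underdetermined design point; setting
`blur_kernel_size = 1` recovers the plain-convolution alternative.

## Blur attention

The attention module refines a feature map `F` in two steps, both built from
pooled descriptors in which one path is *blur-pooled* rather than
max-pooled:

* **Channel attention** `M_CB = σ(MLP(avgpool(F)) + MLP(blurpool(F)))`.
  The first descriptor is the global spatial average per channel; the second
  is obtained by repeatedly applying stride-2 blur-max-pooling until the map
  reaches 1×1. Both pass through the *same* two-layer perceptron
  (reduction ratio `mlp_ratio`, default 8). Because each pooling halves the
  side with a ceiling, the descriptor chain always terminates without
  padding, whatever the input side.
* **Spatial attention** `M_SB = σ(f3x3([chanmean(F); blur(chanmax(F))]))`.
  The channel-max plane is smoothed once by the blur kernel (blur pooling
  without subsampling — its degenerate stride-1 form); the two planes are
  concatenated and filtered by a learned 3×3 convolution. The filter is 3×3
  exactly (not the 7×7 some attention blocks use).

The module output is `F_out = (M_CB ⊗ F) ⊗ M_SB` with broadcasting. Both
attention maps are computed *from the same input map* and applied in
channel-then-spatial order; this follows the printed form of the composition
rather than the sequential convention in which the spatial unit sees the
channel-refined features. Since both maps take values in (0, 1), the output
never exceeds the input in magnitude — an invariant the tests assert,
together with agreement with explicit-loop oracles of both units.

The perceptron weights are assumed *shared* between the two channel
descriptors; with per-descriptor weights the sum in `M_CB` could absorb any
two linear maps, so sharing is the stronger (and conventional) reading.

## Network architecture

`cba_config()` pins every hyperparameter:

| parameter | default | meaning |
|---|---|---|
| `input_size` | 192 | input side (must divide by `2^depth`) |
| `input_channels` | 1 | grayscale input |
| `base_channels` | 24 | stem width; doubled at every DN block |
| `depth` | 4 | DN/UP pairs |
| `blur_kernel_size` | 3 | binomial low-pass side |
| `mlp_ratio` | 8 | attention MLP reduction |
| `pbp_bins` | 1, 2, 4, 8 | pyramid grid sizes |
| `aux_strides` | 2, 4, 8 | auxiliary skip strides |

The encoder applies a stride-1 blur convolution (C1) and four **DN blocks**;
each DN block doubles the channels with a 3×3 convolution, applies blur
attention, and halves the side with stride-2 blur-max-pooling. For a 192
input the side sequence is 192 → 96 → 48 → 24 → 12. Where channels change
is not fixed by the block diagram alone; putting the doubling convolution
*before* the attention lets the attention act on the richer representation.

Auxiliary features are extracted from the C1 output by blur convolutions at
strides 2, 4 and 8 (sides 96/48/24) and concatenated with the DN outputs of
equal size in the decoder, so that full-resolution information reaches the
upsampling path directly.

Each **UP block** fuses the decoder stream with its skips (concatenation
order: decoder, DN features, auxiliary features), applies the **pyramid blur
pooling** module, and doubles the side with a 3×3 stride-2 transpose
convolution. PBP pools its input to 1×1, 2×2, 4×4 and 8×8 grids (dense max +
blur filter + adaptive block averaging, so sides that the bin does not
divide are handled without padding), filters each grid with a dilated 3×3
convolution (dilation = bin) that reduces channels to C/4, upsamples each
branch back with nearest-neighbour interpolation (bit-reproducible, unlike
bilinear), and concatenates the branches with the input: 2C output channels.
PBP is applied *before* the transpose convolution — multi-scale context is
gathered before the resolution changes. The dilated-convolution reading of
the pyramid branches ties the receptive field to the bin index; it is an
interpretation of a module described only diagrammatically, and is
documented as such.

The head is a 1×1 convolution plus logistic sigmoid producing one foreground
probability per pixel. Channel widths halve through the decoder
(512 → 256 → 128 → 64 → 32 at base width 32). With the default
`base_channels = 24` the model has ≈ 6.6 million trainable parameters
(`count_parameters()`), the scale of a compact encoder–decoder segmenter; a
base width of 32 would more than double that budget, which is why 24 is the
default.

All inference is deterministic: two forward passes with the same weights and
input agree bit for bit. The reverse-mode tape that trains the network is
checked against central finite differences on a reduced configuration, and a
gradient-flow test asserts that every parameter leaf receives gradient (no
dead branch in the wiring).

## Preprocessing

* `normalize_image()` converts RGB to luminance (ITU-R 601 weights), rescales
  8-/16-bit ranges to [0, 1], and resizes bilinearly to the network input
  side. It is idempotent on already-normalized input.
* `wavelet_lowpass()` denoises with a single-level 2-D biorthogonal wavelet
  transform (`bior1.3`, periodized). The three detail subbands are
  soft-thresholded at the universal threshold `σ√(2 log N)` with `σ`
  estimated from the median absolute deviation of the diagonal subband, and
  the image is reconstructed and clipped. The wavelet family is fixed by the
  method; the sub-family (`bior1.3`) and the threshold rule are this
  package's choices, since only the family is prescribed. Denoising is
  applied after grayscale conversion and before resizing. The transform is
  implemented in the package (no wavelet package ships with the runtime) and
  tested for perfect reconstruction and against an independent
  reimplementation.
* `tile_image()` splits large images into non-overlapping `P×P` patches
  (default 250), reflect-padding non-divisible sides and recording the
  padding so `untile_image()` is an exact inverse. A 1000×1000 image yields
  16 patches; instance labels are relabelled per patch.
* `augment_stream()` yields seeded random augmentations: right-angle
  rotations, flips, optional free-angle rotation (bilinear for images,
  nearest-neighbour for label maps, mirror-filled corners), and random crops
  to the network size. The stream keeps a private RNG state, so identical
  seeds give identical streams and the global RNG is untouched.
  `augment_epoch()` draws a fixed-size epoch (e.g. expanding a 536-image
  corpus into 2372 crops of 192×192).

## Evaluation metrics

Pixel-level: Dice `2|A∩B|/(|A|+|B|)`, precision `TP/(TP+FP)`, recall
`TP/(TP+FN)`, and F1 as their harmonic mean. Degenerate conventions: Dice is
1 when both masks are empty; precision is 1 with no predicted positives;
recall is 1 with no true positives; F1 is 0 when precision + recall = 0.

Object-level: the aggregated Jaccard index. Ground-truth nuclei are visited
in ascending label order and matched one-to-one to the not-yet-used
predicted nucleus with maximal Jaccard index (ties to the lowest predicted
label). Matched pairs accumulate `Σ|G_i∩P_i| / Σ|G_i∪P_i|`; a ground-truth
nucleus with no overlapping candidate adds its own area to the denominator,
and all unmatched predicted nuclei add their pixel counts to the
denominator. Hence any over- or under-segmentation lowers the score, and the
score is not symmetric in its arguments. The one-to-one consumption rule is
the established aggregated-Jaccard convention; the defining sum alone does
not forbid reuse, so the convention is stated here explicitly. Dataset-level
numbers are unweighted per-image means by default; `metrics_table(pooled =
TRUE)` additionally reports pixel metrics pooled over the whole set, since
either aggregation is defensible.

`instances_from_probability()` turns the network's semantic probability map
into instances by thresholding (default 0.5), removing components below
`min_size` pixels, and labelling 8-connected components in raster order.

## The synthetic scene generator

`generate_scene()` emulates the situations the method is meant to face:
elliptical nuclei of configurable size/eccentricity, optional
touching/clustering (labels stay distinct; contested pixels go to the
nearest nucleus in normalized ellipse distance), per-nucleus intensity
jitter, a smooth multiplicative illumination gradient, Gaussian read noise
and Poisson shot noise; fluorescence mode renders bright-on-dark grayscale,
histology mode dark nuclei on a pink-ish textured background via a fixed
hematoxylin/eosin-like linear colour mixing (a synthetic stand-in, not a
stain model). Ellipses are rasterized with the centre-in-pixel convention
and hard edges so the label maps are exact.

What the generator does *not* emulate: optical point-spread functions,
real stain variability, textured chromatin, out-of-focus light, or the long
tail of acquisition artefacts in real corpora. Tests passing on synthetic
scenes therefore demonstrate that the implementation is correct and that the
architecture can learn this class of images at desk scale — not that the
reported real-data accuracies transfer.

## Training

`train()` minimizes binary cross-entropy plus (1 − soft Dice) with equal
weights — a standard composite for class-imbalanced segmentation; the
method itself does not prescribe a loss. The optimizer is Adam (lr 1e-3,
batch 8), with an 80/20 train/validation split, early stopping (patience
10), and the best-validation checkpoint returned. Training is seeded end to
end and deterministic. `pretrain_finetune()` runs two phases — a surrogate
corpus (by default generated synthetic scenes) and then the task corpus —
logging both phases separately.

## Desk-scale experiments

Two canned experiments make the end-to-end behaviour reproducible on a
single CPU; their problem sizes are the package's study conditions:

* `synthetic_benchmark()`: 200 fluorescence scenes at 64×64, a reduced
  network (base width 8), 10 epochs; the held-out 20% of scenes are scored
  by mean Dice and mean aggregated Jaccard index.
* `pretrain_comparison()`: for each of 5 seeds, a 10-image corpus of a
  harder second style (smaller, noisier, more clustered nuclei, stronger
  illumination gradient) is learned either by 5 pretraining epochs on 64
  standard-style scenes plus 5 fine-tuning epochs, or by 10 epochs from
  scratch — an equal total budget. Both arms are scored on held-out scenes
  of the hard style. The small fine-tune corpus is the regime in which
  pretraining is expected to matter.

`scripts/acceptance.R` runs both (plus the architecture/preprocessing
arithmetic and the shift-stability measurement) and writes the numbers as
JSON; the test suite asserts the same properties.

## Known limitations

* The head is semantic; instances come from connected components, so
  touching nuclei separated only by a faint boundary can merge — exactly the
  failure mode the aggregated Jaccard index penalizes. A boundary-aware head
  or watershed post-processing would be the natural extension.
* Training is CPU-oriented and deliberately small-scale; reproducing
  GPU-scale results on real corpora is out of scope.
* The architecture leaves several details open (channel schedule, where
  channels double, pyramid-branch semantics, decoder head); this package
  pins each one and documents the choice above, but other readings exist.
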