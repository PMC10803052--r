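---
title: "Cross-gated Conv-MLP U-Nets: model, design choices and verification strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-gated Conv-MLP U-Nets: model, design choices and verification strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlpunet)
```

## The model

`mlpunet` implements a U-shaped segmentation network for binary lesion
masks that interleaves convolutions (local texture, visual structure) with
spatial MLPs (sparse global context) at **every** stage of the
encoder–decoder, rather than only at the bottleneck. Two building blocks
carry the idea.

**Multi-axis, multi-window MLP (MsM).** The input `H x W x C` map is layer
normalised, densely projected, passed through GELU and split into four
channel heads. Two *local* heads partition the plane into non-overlapping
windows of size `b` and `2b` and mix the `b^2` (resp. `4b^2`) positions
inside each window with a shared dense layer along that axis. Two *global*
heads divide the plane into a `b x b` (resp. `2b x 2b`) grid of large
cells and mix, for each shared within-cell offset, the one-pixel-per-cell
set — a dilated pattern with stride `(H/b, W/b)` (resp. `(H/2b, W/2b)`)
that spans the whole map. Each head's mixer is a single dense layer along
its mixing axis followed by GELU and an in-head residual; heads are
re-concatenated, densely projected, and dropout is applied. Because every
mixing axis has fixed length `b^2` or `4b^2`, one set of weights serves
*any* input with `H`, `W` divisible by `2b`: no cropping, no resizing, no
learned positional encoding, and cost linear in the pixel count.

**MLP cross gating (MCG).** Two convolutional streams `u1`, `v1` of equal
shape are each layer normalised, densely projected and GELU-activated
(`u2`, `v2`); a *shared* MsM operator `M` produces a spatial mixture of
each; the streams then gate each other elementwise, `u3 = u2 * M(v2)` and
`v3 = v2 * M(u2)`; each path is projected, dropout-regularised and added
residually to its own input; the block output is the sum of the two paths.
The two paths carry independent weights (exchanging the path weights
mirrors exchanging the inputs — a tested symmetry); `M` is shared because
the formulation applies a single operator to both streams, which also
keeps the parameter budget near its printed target.

**Stages.** Encoder stages (ECM) compute `a = conv(x)`, a downsampled
deeper look `d = conv(pool(a))` and its upsampled return `u =
conv(up(d))`, and cross-gate `a` with `u`; the gated map is the skip
connection and `concat(pool(gated), d)` feeds the next stage, so
downsampling loses as little as possible. Decoder stages (DCM) fuse the
deep map with the skip of the level *below* on one path and pool a
conv-upsampled ("forward-looking") copy of the deep map on the other,
cross-gate the two at half resolution, then fuse the upsampled gate, the
upsampled deep map and the same-level skip into the stage output. The
bottleneck stage (BCM) is a DCM without a same-level skip (its partner is
the deepest encoder feature at the bottleneck resolution). The output
stage (OCM) cross-gates two serial conv blocks and maps to logits with a
1x1 convolution; the loss applies the sigmoid.

## Loss and metrics

Training minimises `0.5 * BCE + Dice`. The BCE is the standard *two-term*
cross-entropy over pixels. (The source formulation prints only the
positive-class term; taken literally that ignores every background pixel
and cannot train a segmenter, so the two-term form is implemented — a
deliberate, logged deviation.) Probabilities are clipped to
`[1e-7, 1 - 1e-7]`; the soft Dice uses an additive smoothing constant of 1
in numerator and denominator. Evaluation reports IoU and F1 on masks
binarised at 0.5, aggregated as per-image means; when both masks are empty
both scores are 1 by convention. These four constants are unstated in the
source and follow common practice; all are recorded in the metrics JSON.

## Parameter and FLOP accounting

`network_plan()` is the single source of truth for channel bookkeeping:
the builder instantiates from it and `count_parameters()` /
`count_flops()` sum over the same table, so the closed-form counts and the
instantiated model cannot drift apart (a test enumerates every parameter
tensor of a built model and compares). FLOPs follow the one
multiply-accumulate = one FLOP convention, summing convolution and dense
(including spatial-mixing) MACs and excluding normalisation and activation
ops; under the same convention the classic 64-base U-Net
(`unet_reference_cost()`) lands within about 2% of its widely printed
cost at 256 x 256, which anchors the convention.

The encoder widths (64/128/256/512, with the downsampled path `d` at the
stage width and stage inputs doubling accordingly) follow the classic
U-Net ladder. The decoder's internal widths are not printed anywhere, so
they were *calibrated*: under the fixed wiring above, the bottleneck
cross-gate width (960), its up-projection width (48), its output width
(64), and the per-level decoder gate/up widths ((8,16,32) and (13,16,64))
were chosen once so that the default configuration reproduces the
published total of 33.25 M parameters and 53.80 GFLOPs at 256 x 256
(obtained: 33,252,747 parameters and 53.83 GFLOPs). The resulting design
concentrates capacity in the bottleneck cross-gate — where parameters are
FLOP-cheap — and keeps the high-resolution decoder gates slim, which is
also why the network undercuts the baseline U-Net's FLOPs despite more
parameters. Where the figures admit two readings (for example whether the
two conv-of-upsampled-deep operations in a decoder stage share one
convolution), the printed cost was used as the tiebreaker; they share.
Non-default configurations fall back to proportional versions of the same
rules.

## The autodiff engine

No automatic-differentiation framework is assumed: the package carries a
small reverse-mode engine (tape of operation nodes, each with a bespoke
vector-Jacobian product). Feature maps are stored internally as
`(H, W, N, C)` arrays so that the matrix view used by per-pixel channel
operations is a zero-copy reshape; convolution is 9 shifted
matrix-multiplications; partitioned mixing is a permutation plus one
matrix-multiplication. GELU uses the sigmoid approximation
`x * sigmoid(1.702 x)`. Every operation's gradient is verified against
central finite differences in the test suite, and an end-to-end test
checks that every parameter tensor of the assembled network receives a
nonzero gradient (no dead branches).

Numerical choices: He-normal weight initialisation (zero biases,
batch-norm affine at identity; the 1x1 output head starts at scale 1e-3,
so the untrained network predicts close to the maximally uncertain p = 0.5
everywhere — giving the step-0 loss a closed form that the tests check —
while gradients still reach every stage in the first backward pass); layer norm `eps = 1e-5`; batch norm
`eps = 1e-5`, momentum 0.1, biased variance for normalisation and
unbiased for the running estimate; max-pool ties broken toward the first
element in scan order; bilinear upsampling with half-pixel centres (so a
pooled constant map upsamples back to the same constant); dropout is
inverted (scaled at train time) and disabled in every oracle test. Inputs
whose size violates the `2^depth * 2b` divisibility constraint are
rejected with the minimal valid padded size in the message; the
*evaluation* path (`evaluate()` / `predict_prob()`) instead reflect-pads,
predicts and crops back, and reports that it did so. Partitions reject
rather than pad — padding would silently break the exact-bijection
round-trip guarantee.

## Training protocol

The published protocol fixes batch size 8, 100 epochs, 7:2:1
train/validation/test splits (re-seeded repetition supported via
`--repeats`) and rotation/hue/brightness/crop augmentation, but not the
optimizer. The package uses Adam, lr 1e-4, no weight decay, cosine decay
over the step budget — a package choice, stated in the run log. Images
are normalised to `[0, 1]` with no dataset-statistic normalisation, so
synthetic and real data are treated identically. Runs are deterministic
given the seed under single-threaded BLAS; multi-threaded BLAS may
reorder floating-point reductions.

## Synthetic data: what it emulates and what it does not

The generator produces lesion-like fixtures: a smooth Gaussian random
field (background anatomy) carrying multiplicative Rayleigh-like noise
(speckle), plus blurred, boundary-perturbed ellipses shifted in contrast
(lesions). Defaults: 1–2 lesions per image, radii 12–30% of the short
side, contrast 0.35, speckle amplitude 0.15, boundary blur 1.5 px —
values chosen once to make lesions clearly present but not trivially
separable, in rough visual analogy to breast-ultrasound data. Every
sample is a pure function of `(seed, index)`, so fixtures are never
shipped, only generated. The generator makes *no* claim of physical
fidelity: it has no acoustic shadowing, no anatomy-correlated lesion
placement, no annotation noise, no class imbalance across images, and its
lesions are always brighter than background. Passing the packaged tests
therefore demonstrates that the architecture, losses, metrics and
training loop are implemented correctly and can fit structured signal —
not that the network reaches any particular accuracy on clinical data.

## Verification strategy and problem sizes

Tests run at deliberately small scale so the full suite completes on one
CPU: gradient checks and partition algebra on maps up to 16 x 16; the
receptive-field oracle compares the numerical Jacobian support of the MsM
block on an 8 x 8 x 4 input against the combinatorial prediction for all
64 pixels; the functional capacity ("overfit") test trains a reduced
configuration (depth 1, base width 8, full-batch Adam at a constant
5e-3 learning rate) on eight 64 x 64 synthetic images for 150
optimization steps and requires training F1 > 0.95; the
reproducibility test runs two seeded end-to-end toy trainings (twelve
32 x 32 images, depth 1) and requires byte-identical metric reports. The
default-scale network is exercised for its shape contract (forward passes
at 256 x 256 and 192 x 256) and its cost figures, not trained in the
suite.

## Known limitations

Pure-R training is orders of magnitude slower than a GPU framework; the
package is a faithful, verifiable reference implementation and a
desk-scale research tool, not a production trainer. Only binary masks are
supported (`num_classes = 1` with sigmoid semantics). The published
benchmark accuracies on external datasets require those datasets and long
GPU training and are out of scope; the package reproduces the
architecture's *cost* figures and its structural and functional
properties instead.
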