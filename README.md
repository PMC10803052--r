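# mlpunet

Medical image segmentation networks that combine convolutions with
spatial MLPs at every stage of a U-shaped encoder–decoder — implemented,
trained and verified entirely in R.

Accurate lesion segmentation (breast ultrasound, dermoscopy, endoscopy)
needs both the local texture sensitivity of convolutions and long-range
context. Pure CNN U-Nets lack explicit global interaction; pure
Transformer/MLP designs need fixed input sizes and lose fine
localisation. `mlpunet` implements a hybrid: every encoder and decoder
stage cross-fuses two convolutional feature streams through an *MLP
cross-gating* block (MCG) whose spatial mixer is a *multi-axis,
multi-window MLP* (MsM).

The MsM splits the channels of an `H x W x C` map into four heads:

- two **local** heads mix the `b^2` / `(2b)^2` positions inside
  non-overlapping windows of size `b` and `2b`;
- two **global** heads divide the map into a `b x b` / `2b x 2b` grid of
  large cells and mix one pixel per cell at each shared offset — a
  dilated, globally sparse receptive field with stride `H/b` (resp.
  `H/2b`).

All mixing axes have fixed length, so one set of weights accepts any
input with `H`, `W` divisible by `2b` — no cropping — at cost linear in
the pixel count. In the cross-gating block two streams `u`, `v` gate each
other elementwise, `u3 = u2 ⊙ M(v2)`, `v3 = v2 ⊙ M(u2)`, with residual
projections and a summed output. Training minimises

    L = 0.5 · BCE(Y, Ŷ) + DiceLoss(Y, Ŷ)

and evaluation reports per-image IoU and F1 (Dice), with
`F1 = 2·IoU / (1 + IoU)`.

The package contains the network (with parameter/FLOP accounting), a
small reverse-mode autodiff engine so training runs on CPU without any
deep-learning framework, the compound loss and mask metrics, a
deterministic synthetic lesion-image generator (so everything is testable
with no downloads), a training/evaluation engine and a CLI.

## Worked example

Generate a small synthetic dataset, train a reduced network for a few
epochs, and evaluate:

```r
library(mlpunet)

ds_dir <- file.path(tempdir(), "lesions")
write_dataset(synthetic_config(n_images = 12, image_size = c(32, 32), seed = 17),
              ds_dir)

rec <- train(net_config(depth = 1, base_channels = 8, in_channels = 1,
                        dropout_rate = 0.1),
             train_config(split = c(0.7, 0.2, 0.1), batch_size = 4,
                          epochs = 25, seed = 19, lr = 5e-3,
                          lr_schedule = "constant"),
             ds_dir)
tail(rec$history, 1)
#>    epoch train_loss  val_loss   val_iou   val_f1
#> 25    25  0.3778095 0.5418141 0.4741925 0.636244

evaluate(rec$model, ds_dir)
#> metrics over 12 image(s), threshold 0.50:
#>   mean IoU 0.6201   mean F1 0.7326
```

Twenty-five epochs on a one-stage toy network lift the overall F1 to
0.73 (the numbers above are what this exact seeded run prints): the
training loss has fallen from its closed-form starting value of about
1.03 (`0.5*log(2)` plus the Dice of a uniform half prediction) and the
masks are clearly being found. The functional-capacity test in the suite
trains a comparable network for 150 Adam steps on eight 64 x 64 images
and requires training F1 > 0.95.

Architecture cost at the default configuration (depth 4, base width 64,
window base b = 2):

```r
count_parameters(net_config()) / 1e6   # 33.25 (millions of parameters)
count_flops(net_config(), c(256, 256)) / 1e9   # 53.83 GFLOPs (1 MAC = 1 FLOP)
model_summary(net_config())            # per-stage breakdown
```

The same numbers are available from the shell:

```sh
Rscript -e 'mlpunet::cli()' count
Rscript -e 'mlpunet::cli()' generate --out data/toy --n 16 --seed 1 --size 64
Rscript -e 'mlpunet::cli()' train --data data/toy --out runs/toy --epochs 5 --batch 4 --seed 1
Rscript -e 'mlpunet::cli()' eval --checkpoint runs/toy/best.rds --data data/toy --out runs/toy
```

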