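Package: mlpunet
Title: Conv-MLP U-Nets with Cross-Gated Multi-Axis MLP Blocks for Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A U-shaped convolution + multilayer-perceptron segmentation
    network for binary lesion masks, built around two blocks: a multi-axis,
    multi-window MLP that mixes features inside local windows and across a
    sparse global grid at two scales, and a cross-gating block in which two
    convolutional feature streams mutually gate each other. Includes a small
    reverse-mode automatic-differentiation engine so the network is trainable
    on CPU, a compound binary cross-entropy + Dice loss, IoU/F1 mask metrics,
    parameter and multiply-accumulate (FLOP) accounting, a deterministic
    synthetic generator of speckle-textured lesion images for testing without
    external data, and a training/evaluation command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
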