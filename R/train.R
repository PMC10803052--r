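# Training and evaluation engine.
#
# The optimizer is Adam (the source publication protocol leaves the
# optimizer unstated; this is a deliberate package choice, logged at run
# start) with an optional cosine learning-rate decay over the step budget.
# Images are normalised to [0, 1] only — no dataset-statistic normalisation,
# keeping synthetic and real data on the same footing. Runs are
# deterministic given the seed under single-threaded BLAS; multi-threaded
# BLAS kernels may reorder floating-point sums (documented caveat).

#' Training configuration
#'
#' @param split train/validation/test ratios; must be non-negative, with a
#'   positive train share, summing to 1.
#' @param batch_size images per optimization step.
#' @param epochs passes over the training split.
#' @param seed master seed for the split, shuffling, dropout and
#'   initialisation.
#' @param lr Adam learning rate.
#' @param lr_schedule `"cosine"` (decay to 0 over the run) or `"constant"`.
#' @param augment an [aug_config()] applied to training images each epoch
#'   (the default is the identity).
#' @param checkpoint_dir directory for the best-validation checkpoint
#'   (`NULL`: keep it in memory only).
#' @param max_steps optional cap on total optimization steps (useful for
#'   smoke tests); `NULL` means `epochs * steps_per_epoch`.
#' @param threshold binarisation threshold for validation metrics.
#' @param verbose print per-epoch progress lines.
#' @return a `train_config` object.
#' @export
train_config <- function(split = c(0.7, 0.2, 0.1), batch_size = 8,
                         epochs = 100, seed = 1, lr = 1e-4,
                         lr_schedule = c("cosine", "constant"),
                         augment = aug_config(), checkpoint_dir = NULL,
                         max_steps = NULL, threshold = 0.5, verbose = FALSE) {
  if (length(split) != 3 || any(split < 0) || split[1] <= 0 ||
      abs(sum(split) - 1) > 1e-6)
    stop("split must be three non-negative ratios summing to 1, with a positive train share")
  if (batch_size < 1) stop("batch_size must be at least 1")
  if (epochs < 0) stop("epochs must be non-negative")
  structure(list(split = split, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr = lr, lr_schedule = match.arg(lr_schedule),
                 augment = augment, checkpoint_dir = checkpoint_dir,
                 max_steps = max_steps, threshold = threshold,
                 verbose = verbose),
            class = "train_config")
}

#' Split samples into train/validation/test
#'
#' Seeded shuffle followed by a contiguous partition. Sizes are the rounded
#' ratios with the remainder assigned to the training split; the three
#' parts are disjoint and cover the input.
#'
#' @param samples a list (of samples, or anything subsettable).
#' @param ratios three positive ratios summing to 1.
#' @param seed integer seed for the shuffle.
#' @return list with `train`, `val`, `test`.
#' @export
split_dataset <- function(samples, ratios = c(0.7, 0.2, 0.1), seed = 1) {
  n <- length(samples)
  if (n < 3) stop("need at least 3 samples to split")
  if (length(ratios) != 3 || any(ratios <= 0) || abs(sum(ratios) - 1) > 1e-6)
    stop("ratios must be three positive values summing to 1")
  perm <- with_seed(seed, sample.int(n))
  n_val <- round(ratios[2] * n)
  n_test <- round(ratios[3] * n)
  n_train <- n - n_val - n_test
  if (n_train < 1) stop("ratios leave the training split empty")
  list(train = samples[perm[seq_len(n_train)]],
       val = samples[perm[n_train + seq_len(n_val)]],
       test = samples[perm[n_train + n_val + seq_len(n_test)]])
}

as_sample_list <- function(data) {
  if (is.character(data)) read_dataset(data)
  else if (is.list(data)) data
  else stop("data must be a dataset directory or a list of samples")
}

stack_batch <- function(samples, in_channels) {
  imgs <- lapply(samples, function(s) {
    img <- s$image
    if (dim(img)[3] != in_channels) {
      if (in_channels == 1) img <- array(rowMeans(matrix(img, ncol = dim(img)[3])),
                                         c(dim(img)[1:2], 1))
      else if (dim(img)[3] == 1) img <- array(img, c(dim(img)[1:2], in_channels))
      else stop("image channels do not match the network input channels")
    }
    img
  })
  d <- dim(imgs[[1]])
  # internal engine layout: (H, W, N, C)
  x <- array(0, c(d[1], d[2], length(imgs), d[3]))
  y <- array(0, c(d[1], d[2], length(imgs), 1))
  for (i in seq_along(imgs)) {
    x[, , i, ] <- imgs[[i]]
    y[, , i, 1] <- samples[[i]]$mask
  }
  list(x = x, y = y)
}

#' Train the network
#'
#' Optimizes the compound 0.5 * BCE + Dice loss with Adam, evaluating on
#' the validation split after every epoch and retaining the checkpoint with
#' the highest validation IoU.
#'
#' @param model_cfg a [net_config()].
#' @param tr_cfg a [train_config()].
#' @param data a dataset directory (see [read_dataset()]) or a list of
#'   `segmentation_sample`s.
#' @return a `run_record`: list with `history` (per-epoch data.frame of
#'   train loss, validation loss/IoU/F1), `best_epoch`, `best_state`
#'   (parameter snapshot at the best validation IoU), `model` (final
#'   weights), `config` and `seed`. With `epochs = 0` the history is empty
#'   and no checkpoint is produced.
#' @export
train <- function(model_cfg, tr_cfg, data) {
  stopifnot(inherits(model_cfg, "net_config"), inherits(tr_cfg, "train_config"))
  samples <- as_sample_list(data)
  n <- length(samples)
  if (n < 1) stop("empty dataset")
  if (tr_cfg$verbose)
    message(sprintf(
      "run: seed %d, %d samples, optimizer adam (lr %g, %s decay; optimizer choice is not part of the published protocol), loss 0.5*BCE(two-term)+Dice",
      tr_cfg$seed, n, tr_cfg$lr, tr_cfg$lr_schedule))
  if (all(tr_cfg$split[2:3] > 0)) {
    sp <- split_dataset(samples, tr_cfg$split, tr_cfg$seed)
  } else {
    n_val <- round(tr_cfg$split[2] * n)
    n_test <- round(tr_cfg$split[3] * n)
    perm <- with_seed(tr_cfg$seed, sample.int(n))
    n_train <- n - n_val - n_test
    sp <- list(train = samples[perm[seq_len(n_train)]],
               val = samples[perm[n_train + seq_len(n_val)]],
               test = samples[perm[n_train + n_val + seq_len(n_test)]])
  }
  if (length(sp$train) == 0) stop("training split is empty")

  set.seed(tr_cfg$seed)
  model <- cm_unet(model_cfg)
  params <- collect_params(model)
  opt <- adam_init(params, lr = tr_cfg$lr)
  steps_per_epoch <- ceiling(length(sp$train) / tr_cfg$batch_size)
  total_steps <- tr_cfg$epochs * steps_per_epoch
  if (!is.null(tr_cfg$max_steps)) total_steps <- min(total_steps, tr_cfg$max_steps)

  history <- list()
  best <- list(iou = -Inf, epoch = NA_integer_, state = NULL)
  identity_aug <- identical(unclass(tr_cfg$augment), unclass(aug_config()))
  step <- 0L
  for (epoch in seq_len(tr_cfg$epochs)) {
    if (step >= total_steps) break
    ord <- sample.int(length(sp$train))
    ep_loss <- 0; ep_batches <- 0L
    for (b0 in seq(1, length(ord), by = tr_cfg$batch_size)) {
      if (step >= total_steps) break
      idx <- ord[b0:min(b0 + tr_cfg$batch_size - 1L, length(ord))]
      batch_samples <- sp$train[idx]
      if (!identity_aug)
        batch_samples <- lapply(batch_samples, augment, cfg = tr_cfg$augment)
      batch <- stack_batch(batch_samples, model_cfg$in_channels)
      ad_tape_start()
      logits <- net_apply(model, ad_const(batch$x), training = TRUE)
      prob <- ad_sigmoid(logits)
      loss <- ad_add(ad_scale(ad_bce(prob, batch$y), 0.5),
                     ad_dice(prob, batch$y))
      if (!is.finite(loss$value))
        stop(sprintf("training diverged: non-finite loss at step %d (epoch %d)",
                     step + 1L, epoch))
      ad_backward(loss)
      ad_tape_stop()
      lr_t <- if (tr_cfg$lr_schedule == "cosine")
        tr_cfg$lr * 0.5 * (1 + cos(pi * step / max(total_steps, 1)))
      else tr_cfg$lr
      adam_step(opt, lr = lr_t)
      ad_zero_grad(params)
      ep_loss <- ep_loss + loss$value
      ep_batches <- ep_batches + 1L
      step <- step + 1L
    }
    val <- eval_split(model, sp$val, model_cfg, tr_cfg$threshold)
    history[[epoch]] <- data.frame(
      epoch = epoch, train_loss = ep_loss / max(ep_batches, 1L),
      val_loss = val$loss, val_iou = val$iou, val_f1 = val$f1)
    if (tr_cfg$verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val IoU %.4f  val F1 %.4f",
                      epoch, ep_loss / max(ep_batches, 1L), val$loss, val$iou, val$f1))
    if (is.na(val$iou)) {       # no validation split: keep the final epoch
      best <- list(iou = -Inf, epoch = epoch, state = model_state(model))
    } else if (val$iou > best$iou) {
      best <- list(iou = val$iou, epoch = epoch, state = model_state(model))
    }
  }
  record <- structure(list(
    history = if (length(history)) do.call(rbind, history) else
      data.frame(epoch = integer(0), train_loss = numeric(0),
                 val_loss = numeric(0), val_iou = numeric(0),
                 val_f1 = numeric(0)),
    best_epoch = best$epoch,
    best_state = best$state,
    model = model,
    splits = lapply(sp, function(s) vapply(s, function(z) z$id, character(1))),
    config = list(model = model_cfg, train = tr_cfg),
    seed = tr_cfg$seed
  ), class = "run_record")
  if (!is.null(tr_cfg$checkpoint_dir) && !is.null(best$state)) {
    dir.create(tr_cfg$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(tr_cfg$checkpoint_dir, "best.rds")
    saveRDS(list(cfg = model_cfg, state = best$state,
                 best_epoch = best$epoch, seed = tr_cfg$seed), path)
    record$checkpoint <- path
  }
  record
}

eval_split <- function(model, samples, model_cfg, threshold) {
  if (length(samples) == 0)
    return(list(loss = NA_real_, iou = NA_real_, f1 = NA_real_))
  losses <- ious <- f1s <- numeric(length(samples))
  for (i in seq_along(samples)) {
    batch <- stack_batch(samples[i], model_cfg$in_channels)
    prob <- stats::plogis(net_apply(model, ad_const(batch$x), FALSE)$value)
    truth <- batch$y
    losses[i] <- combined_loss(truth, prob)
    pm <- (prob >= threshold) * 1
    ious[i] <- iou_score(truth, pm)
    f1s[i] <- f1_score(truth, pm)
  }
  list(loss = mean(losses), iou = mean(ious), f1 = mean(f1s))
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the network configuration, every parameter tensor
#' and the batch-norm running moments; loading rebuilds the model and
#' restores the exact values, so save -> load -> evaluate is bit-identical
#' to evaluating in memory.
#'
#' @param model a `cm_unet` model.
#' @param path file path (`.rds`).
#' @return `load_checkpoint` returns the restored model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "cm_unet"))
  saveRDS(list(cfg = model$cfg, state = model_state(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- cm_unet(ck$cfg)
  restore_model_state(model, ck$state)
  model
}

reflect_pad_hw <- function(a, ph, pw) {
  d <- dim(a)
  if (ph > 0) {
    ri <- c(seq_len(d[1]), seq.int(d[1] - 1, by = -1, length.out = ph))
    a <- a[ri, , , , drop = FALSE]
  }
  if (pw > 0) {
    ci <- c(seq_len(d[2]), seq.int(d[2] - 1, by = -1, length.out = pw))
    a <- a[, ci, , , drop = FALSE]
  }
  a
}

#' Predict a probability map for one image
#'
#' Runs the network in inference mode. Images whose size violates the
#' divisibility constraint are reflect-padded to the nearest valid size and
#' the prediction is cropped back (reported with a message).
#'
#' @param model a `cm_unet`.
#' @param image `H x W x C` array.
#' @return `H x W` matrix of foreground probabilities.
#' @export
predict_prob <- function(model, image) {
  d <- dim(image)
  if (length(d) == 2) dim(image) <- c(d, 1)
  d <- dim(image)
  m <- model$cfg$divisor
  ph <- (m - d[1] %% m) %% m
  pw <- (m - d[2] %% m) %% m
  x <- image
  dim(x) <- c(d, 1)
  x <- to_internal(x)                      # (H, W, 1, C)
  if (ph > 0 || pw > 0) {
    message(sprintf("image %dx%d reflect-padded to %dx%d for prediction",
                    d[1], d[2], d[1] + ph, d[2] + pw))
    x <- reflect_pad_hw(x, ph, pw)
  }
  prob <- stats::plogis(net_apply(model, ad_const(x), FALSE)$value)
  prob[seq_len(d[1]), seq_len(d[2]), 1, 1]
}

#' Evaluate a model (or checkpoint) on a dataset
#'
#' Predicts every image, thresholds, scores per-image IoU and F1 and their
#' means, and optionally writes `metrics.csv` / `metrics.json`.
#'
#' @param model a `cm_unet` model or the path of a checkpoint file.
#' @param data dataset directory or list of `segmentation_sample`s.
#' @param threshold binarisation threshold.
#' @param out_dir optional directory for the CSV/JSON report.
#' @return a `metrics_report` (see [evaluate_masks()]).
#' @export
evaluate <- function(model, data, threshold = 0.5, out_dir = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  stopifnot(inherits(model, "cm_unet"))
  samples <- as_sample_list(data)
  probs <- lapply(samples, function(s) {
    batch <- stack_batch(list(s), model$cfg$in_channels)
    img <- batch$x[, , 1, , drop = FALSE]          # (H, W, 1, C)
    predict_prob(model, array(img, dim(img)[c(1, 2, 4)]))
  })
  truths <- lapply(samples, function(s) s$mask)
  ids <- vapply(samples, function(s) s$id, character(1))
  report <- evaluate_masks(truths, probs, ids, threshold)
  if (!is.null(out_dir)) write_metrics(report, out_dir)
  report
}
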