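# Compound segmentation loss (0.5 * BCE + soft Dice) and binary mask
# metrics (IoU, F1). Conventions, all stated in the metrics JSON summary:
# probabilities are clipped to [1e-7, 1 - 1e-7] inside the BCE; the soft
# Dice uses an additive smoothing constant (default 1); metrics binarise at
# threshold 0.5; when both masks are empty IoU and F1 are 1; aggregate
# scores are arithmetic means of per-image scores.

check_binary <- function(x, what = "mask") {
  if (!all(x %in% c(0, 1)))
    stop(sprintf("%s must be strictly binary (0/1)", what))
  invisible(TRUE)
}

check_pair <- function(truth, pred, prob = FALSE) {
  if (!identical(dim(truth) %||% length(truth), dim(pred) %||% length(pred)))
    stop("truth and prediction shapes disagree")
  check_binary(truth, "truth mask")
  if (prob) {
    if (any(pred < 0 | pred > 1)) stop("predicted probabilities must lie in [0, 1]")
  } else check_binary(pred, "predicted mask")
  invisible(TRUE)
}

#' Binary cross-entropy between a mask and predicted probabilities
#'
#' Standard two-term cross-entropy, averaged over pixels, with
#' probabilities clipped to `[eps, 1 - eps]`.
#'
#' @param truth binary array (0/1).
#' @param pred_prob array of probabilities in `[0, 1]`, same shape.
#' @param eps clipping constant.
#' @return scalar loss.
#' @examples
#' bce_loss(matrix(1, 2, 2), matrix(0.5, 2, 2))  # log(2)
#' @export
bce_loss <- function(truth, pred_prob, eps = 1e-7) {
  check_pair(truth, pred_prob, prob = TRUE)
  p <- pmin(pmax(pred_prob, eps), 1 - eps)
  -mean(truth * log(p) + (1 - truth) * log(1 - p))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(truth * pred) + s) / (sum(truth) + sum(pred) + s)`,
#' computed on soft probabilities so it is differentiable during training;
#' 0 at perfect agreement (up to smoothing), 1 at total disagreement.
#'
#' @param truth binary array (0/1).
#' @param pred_prob probabilities in `[0, 1]`, same shape.
#' @param smooth additive smoothing constant `s`.
#' @return scalar loss in `[0, 1]`.
#' @export
dice_loss <- function(truth, pred_prob, smooth = 1) {
  check_pair(truth, pred_prob, prob = TRUE)
  num <- 2 * sum(truth * pred_prob) + smooth
  den <- sum(truth) + sum(pred_prob) + smooth
  1 - num / den
}

#' Compound training loss
#'
#' Exactly `0.5 * bce_loss(...) + dice_loss(...)`.
#'
#' @inheritParams dice_loss
#' @param eps BCE clipping constant.
#' @return scalar loss, non-negative.
#' @export
combined_loss <- function(truth, pred_prob, smooth = 1, eps = 1e-7) {
  0.5 * bce_loss(truth, pred_prob, eps) + dice_loss(truth, pred_prob, smooth)
}

#' Intersection-over-union of two binary masks
#'
#' `|A intersect B| / |A union B|`; returns 1 when both masks are empty.
#'
#' @param truth,pred_mask binary arrays (0/1) of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
iou_score <- function(truth, pred_mask) {
  check_pair(truth, pred_mask)
  inter <- sum(truth * pred_mask)
  uni <- sum(truth) + sum(pred_mask) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' F1 score (Dice coefficient) of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; returns 1 when both masks are empty.
#' For binary masks this is the harmonic mean of precision and recall and
#' satisfies `F1 = 2 IoU / (1 + IoU)`.
#'
#' @inheritParams iou_score
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(truth, pred_mask) {
  check_pair(truth, pred_mask)
  inter <- sum(truth * pred_mask)
  tot <- sum(truth) + sum(pred_mask)
  if (tot == 0) return(1)
  2 * inter / tot
}

#' Per-image and aggregate mask metrics
#'
#' Thresholds each probability map, scores it against its ground truth and
#' aggregates by the arithmetic mean of per-image scores.
#'
#' @param truths list of binary `H x W` masks.
#' @param probs list of probability maps (same shapes); already-binary
#'   predictions are accepted.
#' @param ids optional character ids, one per image.
#' @param threshold binarisation threshold for the probability maps.
#' @return a `metrics_report`: list with `per_image` (data.frame of id,
#'   iou, f1), `aggregate` (mean_iou, mean_f1), `threshold`, and the
#'   conventions used.
#' @export
evaluate_masks <- function(truths, probs, ids = NULL, threshold = 0.5) {
  stopifnot(length(truths) == length(probs))
  n <- length(truths)
  if (is.null(ids)) ids <- sprintf("img%04d", seq_len(n))
  iou <- f1 <- numeric(n)
  for (i in seq_len(n)) {
    pm <- (probs[[i]] >= threshold) * 1
    iou[i] <- iou_score(truths[[i]], pm)
    f1[i] <- f1_score(truths[[i]], pm)
  }
  structure(list(
    per_image = data.frame(id = ids, iou = iou, f1 = f1,
                           stringsAsFactors = FALSE),
    aggregate = c(mean_iou = if (n) mean(iou) else NA_real_,
                  mean_f1 = if (n) mean(f1) else NA_real_),
    threshold = threshold,
    conventions = list(empty_pair_score = 1, aggregation = "per-image mean")
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics over %d image(s), threshold %.2f:\n",
              nrow(x$per_image), x$threshold))
  cat(sprintf("  mean IoU %.4f   mean F1 %.4f\n",
              x$aggregate[["mean_iou"]], x$aggregate[["mean_f1"]]))
  invisible(x)
}

#' Write a metrics report as CSV + JSON
#'
#' Writes `metrics.csv` (id, iou, f1) and `metrics.json` (means, threshold
#' and scoring conventions) into `dir`.
#'
#' @param report a `metrics_report` from [evaluate_masks()].
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_metrics <- function(report, dir) {
  stopifnot(inherits(report, "metrics_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "metrics.csv")
  js <- file.path(dir, "metrics.json")
  utils::write.csv(report$per_image, csv, row.names = FALSE)
  jsonlite::write_json(list(
    mean_iou = report$aggregate[["mean_iou"]],
    mean_f1 = report$aggregate[["mean_f1"]],
    n_images = nrow(report$per_image),
    threshold = report$threshold,
    conventions = report$conventions
  ), js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
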