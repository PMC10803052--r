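# Multi-axis, multi-window MLP block.
#
# The block mixes spatial information along four parallel channel heads:
# two local heads that mix inside non-overlapping windows of size b and 2b,
# and two global heads that mix across a b x b (resp. 2b x 2b) grid of large
# cells at shared within-cell offsets, i.e. with stride H/b (resp. H/2b).
# All four mixing MLPs act on axes of fixed length (b^2 or 4b^2), so one set
# of weights serves any input whose H and W are divisible by 2b — no cropping
# or resizing is ever needed and the cost is linear in the number of pixels.

#' Configuration of a multi-axis multi-window MLP block
#'
#' @param channels number of channels `C`; must be divisible by 4 (the block
#'   splits channels into four heads).
#' @param b base window size in pixels. The two local heads use windows of
#'   `b` and `2b`; the two global heads use grids of `b` and `2b`. Any input
#'   must have `H` and `W` divisible by `2b`.
#' @param dropout_rate dropout probability applied after the output
#'   projection, in `[0, 1)`.
#' @param hidden_ratio expansion factor of the dense projection applied
#'   before the channel split (the default 1 keeps the width unchanged).
#' @return an object of class `msm_config`.
#' @export
msm_config <- function(channels, b = 2, dropout_rate = 0.1, hidden_ratio = 1) {
  if (channels < 4 || channels %% 4 != 0)
    stop("channels must be a positive multiple of 4 (four heads)")
  if (b < 1 || b != round(b)) stop("b must be a positive integer")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  hidden <- round(channels * hidden_ratio)
  if (hidden < 4 || hidden %% 4 != 0)
    stop("channels * hidden_ratio must be a positive multiple of 4")
  structure(list(channels = as.integer(channels), b = as.integer(b),
                 dropout_rate = dropout_rate, hidden_ratio = hidden_ratio,
                 hidden = as.integer(hidden)),
            class = "msm_config")
}

#' Instantiate a multi-axis multi-window MLP block
#'
#' Creates the learnable weights for the pipeline
#' layer norm -> dense -> GELU -> split into four heads ->
#' per-head spatial MLP mixing (window b, window 2b, grid b, grid 2b, each a
#' single dense layer along its mixing axis followed by GELU and an in-head
#' residual) -> channel concatenation -> dense -> dropout.
#'
#' @param cfg an [msm_config()].
#' @return an `msm_block` object holding the block's parameters.
#' @export
msm_block <- function(cfg) {
  stopifnot(inherits(cfg, "msm_config"))
  C <- cfg$channels; h <- cfg$hidden; b <- cfg$b
  structure(list(
    cfg = cfg,
    ln = new_ln(C),
    pre = new_dense(C, h),
    mix = list(local1 = new_mix(b^2),     # window [b, b]
               local2 = new_mix((2 * b)^2), # window [2b, 2b]
               global1 = new_mix(b^2),    # grid [b, b]
               global2 = new_mix((2 * b)^2)), # grid [2b, 2b]
    post = new_dense(h, C)
  ), class = "msm_block")
}

check_msm_input <- function(d, cfg) {
  if (d[4L] != cfg$channels)
    stop(sprintf("input has %d channels but the block was built for %d",
                 d[4L], cfg$channels))
  m <- 2L * cfg$b
  if (d[1L] %% m != 0)
    stop(sprintf("height %d is not divisible by 2b = %d", d[1L], m))
  if (d[2L] %% m != 0)
    stop(sprintf("width %d is not divisible by 2b = %d", d[2L], m))
}

# node-level forward (shared by the user API and the network)
msm_apply <- function(blk, x, training = FALSE) {
  cfg <- blk$cfg
  d <- dim(x$value)
  check_msm_input(d, cfg)
  H <- d[1L]; W <- d[2L]; b <- cfg$b; hq <- cfg$hidden %/% 4L
  h <- ad_layernorm(x, blk$ln$gamma, blk$ln$beta)
  h <- ad_gelu(ad_dense(h, blk$pre$w, blk$pre$b))
  heads <- list(
    ad_slice_c(h, 1L, hq),
    ad_slice_c(h, hq + 1L, 2L * hq),
    ad_slice_c(h, 2L * hq + 1L, 3L * hq),
    ad_slice_c(h, 3L * hq + 1L, 4L * hq)
  )
  specs <- list(list(type = "block", size = b),
                list(type = "block", size = 2L * b),
                list(type = "grid", size = b),
                list(type = "grid", size = 2L * b))
  mixed <- vector("list", 4L)
  mixers <- blk$mix
  for (k in 1:4) {
    sp <- specs[[k]]
    perm <- mix_perm(H, W, sp$size, sp$type)
    mk <- mixers[[k]]
    z <- ad_mix(heads[[k]], mk$w, mk$b, perm, sp$size^2)
    mixed[[k]] <- ad_add(heads[[k]], ad_gelu(z))   # in-head residual
  }
  out <- ad_concat_c(mixed)
  out <- ad_dense(out, blk$post$w, blk$post$b)
  ad_dropout(out, cfg$dropout_rate, training)
}

#' Apply a multi-axis multi-window MLP block to a feature map
#'
#' Output has the same shape as the input for every `H x W` divisible by
#' `2b`; the block never requires a specific image size. With
#' `training = FALSE` (or `dropout_rate = 0`) the forward pass is
#' deterministic.
#'
#' @param block an [msm_block()].
#' @param x an `H x W x C` array with `C = block$cfg$channels` and `H`, `W`
#'   divisible by `2b`.
#' @param training logical; enables dropout.
#' @return an array of the same dimensions as `x`.
#' @export
msm_forward <- function(block, x, training = FALSE) {
  stopifnot(inherits(block, "msm_block"))
  x4 <- as_fm4(x)
  out <- msm_apply(block, node_in(x4), training)
  array_out(out, x4$batched)
}

#' Predicted receptive field of one output pixel of the MsM block
#'
#' Returns the combinatorial prediction of which input pixels can influence
#' the output at `(row, col)`: the union of the enclosing `b x b` and
#' `2b x 2b` windows (local heads) and the two dilated same-offset sets with
#' strides `(H/b, W/b)` and `(H/2b, W/2b)` (global heads). The numerical
#' Jacobian of [msm_forward()] is supported exactly on this set.
#'
#' @param row,col 1-based pixel position, `1 <= row <= H`, `1 <= col <= W`.
#' @param H,W spatial dimensions, both divisible by `2b`.
#' @param b base window size.
#' @return a two-column integer matrix of (row, col) positions, one per
#'   pixel in the receptive field.
#' @export
msm_receptive_mask <- function(row, col, H, W, b) {
  if (row < 1 || row > H || col < 1 || col > W)
    stop(sprintf("pixel (%d, %d) is outside the %d x %d map", row, col, H, W))
  if (H %% (2 * b) != 0 || W %% (2 * b) != 0)
    stop("H and W must be divisible by 2b")
  mask <- matrix(FALSE, H, W)
  r0 <- row - 1L; c0 <- col - 1L          # 0-based
  for (w in c(b, 2L * b)) {
    # local window containing the pixel
    rs <- (r0 %/% w) * w; cs <- (c0 %/% w) * w
    mask[(rs + 1L):(rs + w), (cs + 1L):(cs + w)] <- TRUE
    # global: same offset within each of the w x w large cells
    ch <- H %/% w; cw <- W %/% w          # cell size
    ro <- r0 %% ch; co <- c0 %% cw        # within-cell offset
    mask[ro + 1L + ch * (0:(w - 1L)), co + 1L + cw * (0:(w - 1L))] <- TRUE
  }
  which(mask, arr.ind = TRUE)[, c(1L, 2L), drop = FALSE]
}
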