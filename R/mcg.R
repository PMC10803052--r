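# MLP cross-gating block.
#
# Two convolutional feature streams u and v, of identical shape, gate each
# other: each stream is layer-normalised, densely projected and passed
# through GELU; a shared multi-axis multi-window MLP M() produces a spatial
# mixture of each stream; each projected stream is then multiplied
# elementwise by the mixture of the *other* stream, residually projected
# back onto its input, and the two paths are summed:
#
#   u2 = GELU(Dense(LN(u1)))          v2 = GELU(Dense(LN(v1)))
#   u3 = u2 * M(v2)                   v3 = v2 * M(u2)
#   u4 = u1 + Drop(Dense(u3))         v4 = v1 + Drop(Dense(v3))
#   out = u4 + v4
#
# All dense layers are per-pixel channel projections, dimension preserving,
# so the output shape equals the input shape. The two paths carry
# independent weights; only M() is shared (a single operator applied to both
# streams).

#' Configuration of an MLP cross-gating block
#'
#' @param channels channel count `C` of the two input streams; must be a
#'   multiple of 4.
#' @param b base window size of the embedded multi-axis MLP.
#' @param dropout_rate dropout probability of the residual projections and
#'   of the embedded MsM block.
#' @param hidden_ratio expansion ratio of the MsM pre-split projection.
#' @return an object of class `mcg_config`.
#' @export
mcg_config <- function(channels, b = 2, dropout_rate = 0.1, hidden_ratio = 1) {
  msm <- msm_config(channels, b = b, dropout_rate = dropout_rate,
                    hidden_ratio = hidden_ratio)
  structure(list(channels = as.integer(channels), msm = msm,
                 dropout_rate = dropout_rate),
            class = "mcg_config")
}

#' Instantiate an MLP cross-gating block
#'
#' @param cfg an [mcg_config()].
#' @return an `mcg_block` object holding the block's parameters.
#' @export
mcg_block <- function(cfg) {
  stopifnot(inherits(cfg, "mcg_config"))
  C <- cfg$channels
  structure(list(
    cfg = cfg,
    ln_u = new_ln(C), in_u = new_dense(C, C),
    ln_v = new_ln(C), in_v = new_dense(C, C),
    msm = msm_block(cfg$msm),
    out_u = new_dense(C, C),
    out_v = new_dense(C, C)
  ), class = "mcg_block")
}

mcg_apply <- function(blk, u1, v1, training = FALSE) {
  du <- dim(u1$value); dv <- dim(v1$value)
  if (!identical(du, dv))
    stop(sprintf("cross-gating inputs differ in shape: (%s) vs (%s)",
                 paste(du, collapse = "x"), paste(dv, collapse = "x")))
  p <- blk$cfg$dropout_rate
  u2 <- ad_gelu(ad_dense(ad_layernorm(u1, blk$ln_u$gamma, blk$ln_u$beta),
                         blk$in_u$w, blk$in_u$b))
  v2 <- ad_gelu(ad_dense(ad_layernorm(v1, blk$ln_v$gamma, blk$ln_v$beta),
                         blk$in_v$w, blk$in_v$b))
  mu <- msm_apply(blk$msm, u2, training)
  mv <- msm_apply(blk$msm, v2, training)
  u3 <- ad_mul(u2, mv)
  v3 <- ad_mul(v2, mu)
  u4 <- ad_add(u1, ad_dropout(ad_dense(u3, blk$out_u$w, blk$out_u$b), p, training))
  v4 <- ad_add(v1, ad_dropout(ad_dense(v3, blk$out_v$w, blk$out_v$b), p, training))
  ad_add(u4, v4)
}

#' Cross-gate two feature maps
#'
#' @param block an [mcg_block()].
#' @param u1,v1 feature maps of identical shape `H x W x C` with
#'   `C = block$cfg$channels` and `H`, `W` divisible by `2b`.
#' @param training logical; enables dropout.
#' @return a feature map of the same shape as the inputs.
#' @examples
#' blk <- mcg_block(mcg_config(8, dropout_rate = 0))
#' u <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
#' v <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
#' dim(mcg_forward(blk, u, v))
#' @export
mcg_forward <- function(block, u1, v1, training = FALSE) {
  stopifnot(inherits(block, "mcg_block"))
  u4 <- as_fm4(u1); v4 <- as_fm4(v1)
  out <- mcg_apply(block, node_in(u4), node_in(v4), training)
  array_out(out, u4$batched)
}

#' Number of learnable scalars in one cross-gating block
#'
#' Closed-form count, independent of the spatial input size; equals the
#' enumeration of the instantiated block's parameter tensors.
#'
#' @param cfg an [mcg_config()] (or an [mcg_block()], whose config is used).
#' @return integer parameter count.
#' @export
mcg_parameter_count <- function(cfg) {
  if (inherits(cfg, "mcg_block")) cfg <- cfg$cfg
  stopifnot(inherits(cfg, "mcg_config"))
  C <- cfg$channels
  h <- cfg$msm$hidden
  b <- cfg$msm$b
  sizes <- c(b^2, (2 * b)^2, b^2, (2 * b)^2)
  msm_p <- 2 * C + (C * h + h) + sum(sizes^2 + sizes) + (h * C + C)
  2 * (2 * C + C * C + C) +      # per-stream LN + input dense
    msm_p +                      # shared MsM
    2 * (C * C + C)              # residual output denses
}
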