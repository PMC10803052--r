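# Layer containers. A layer is a plain list of ad_param nodes plus any
# non-learnable state (batch-norm running moments). Blocks are nested lists
# of layers; collect_params() walks the nesting to enumerate every learnable
# tensor, which is what the optimizer, the checkpointing code and the
# parameter-count cross-checks consume.

he_init <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))

new_conv3 <- function(cin, cout) {
  w <- array(he_init(9 * cin * cout, 9 * cin), c(3L, 3L, cin, cout))
  structure(list(w = ad_param(w), cin = cin, cout = cout), class = "ly_conv3")
}

new_dense <- function(cin, cout) {
  w <- matrix(he_init(cin * cout, cin), cin, cout)
  structure(list(w = ad_param(w), b = ad_param(rep(0, cout)),
                 cin = cin, cout = cout), class = "ly_dense")
}

new_mix <- function(s) {
  w <- matrix(he_init(s * s, s), s, s)
  structure(list(w = ad_param(w), b = ad_param(rep(0, s)), s = s), class = "ly_mix")
}

new_bn <- function(c0) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- rep(0, c0)
  st$running_var <- rep(1, c0)
  structure(list(gamma = ad_param(rep(1, c0)), beta = ad_param(rep(0, c0)),
                 state = st, c0 = c0), class = "ly_bn")
}

new_ln <- function(c0) {
  structure(list(gamma = ad_param(rep(1, c0)), beta = ad_param(rep(0, c0)),
                 c0 = c0), class = "ly_ln")
}

# conv 3x3 (no bias) -> batch norm -> ReLU
new_conv_block <- function(cin, cout) {
  structure(list(conv = new_conv3(cin, cout), bn = new_bn(cout),
                 cin = cin, cout = cout), class = "ly_conv_block")
}

cb_forward <- function(blk, x, training = FALSE) {
  h <- ad_conv3(x, blk$conv$w)
  h <- ad_batchnorm(h, blk$bn$gamma, blk$bn$beta, blk$bn$state, training)
  ad_relu(h)
}

#' Convolutional block: 3x3 convolution, batch norm, ReLU
#'
#' The elementary convolutional unit of the network: a 3x3 convolution
#' (stride 1, zero padding 1, bias-free because batch normalisation follows),
#' batch normalisation over the batch and spatial axes, and a ReLU. Spatial
#' dimensions are preserved.
#'
#' @param block a block created by [conv_block()].
#' @param x feature map, an `H x W x C` array (or `H x W x C x N` batch).
#' @param training logical; use batch statistics and update running moments.
#' @return a feature map of the same height and width with `block$cout`
#'   channels.
#' @examples
#' blk <- conv_block(3, 8)
#' y <- conv_block_forward(blk, array(rnorm(16 * 16 * 3), c(16, 16, 3)))
#' dim(y)
#' @export
conv_block_forward <- function(block, x, training = FALSE) {
  x4 <- as_fm4(x)
  out <- cb_forward(block, node_in(x4), training)
  array_out(out, x4$batched)
}

# boundary conversion: public H x W x C (x N) array -> internal node, and back
node_in <- function(x4) ad_const(to_internal(x4$a))
array_out <- function(node, batched) from_fm4(to_public(node$value), batched)

#' @rdname conv_block_forward
#' @param cin,cout input and output channel counts.
#' @export
conv_block <- function(cin, cout) new_conv_block(cin, cout)

# Promote H x W x C (or H x W) to H x W x C x 1; remember whether a batch
# axis was already present.
as_fm4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  else if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("feature map must have 2, 3 or 4 dimensions")
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  list(a = x, batched = length(d) == 4L)
}

from_fm4 <- function(a, batched) {
  if (!batched) {
    d <- dim(a)
    dim(a) <- d[1:3]
  }
  a
}

# -- parameter bookkeeping ---------------------------------------------------

collect_params <- function(obj) {
  if (inherits(obj, "ad_node")) {
    if (isTRUE(obj$is_param)) return(list(obj)) else return(list())
  }
  if (is.list(obj)) {
    out <- list()
    for (el in obj) out <- c(out, collect_params(el))
    return(out)
  }
  list()
}

n_params <- function(obj) {
  sum(vapply(collect_params(obj), function(p) length(p$value), numeric(1)))
}

# Export / restore parameter values and batch-norm running moments as plain
# lists (used by checkpoints).
collect_bn_states <- function(obj) {
  out <- list()
  if (inherits(obj, "ly_bn")) return(list(obj$state))
  if (is.list(obj)) for (el in obj) out <- c(out, collect_bn_states(el))
  out
}

model_state <- function(model) {
  list(params = lapply(collect_params(model), function(p) p$value),
       bn = lapply(collect_bn_states(model), function(s)
         list(mean = s$running_mean, var = s$running_var)))
}

restore_model_state <- function(model, state) {
  ps <- collect_params(model)
  stopifnot(length(ps) == length(state$params))
  for (i in seq_along(ps)) {
    stopifnot(length(ps[[i]]$value) == length(state$params[[i]]))
    v <- state$params[[i]]
    dim(v) <- dim(ps[[i]]$value)
    ps[[i]]$value <- v
  }
  sts <- collect_bn_states(model)
  stopifnot(length(sts) == length(state$bn))
  for (i in seq_along(sts)) {
    sts[[i]]$running_mean <- state$bn[[i]]$mean
    sts[[i]]$running_var <- state$bn[[i]]$var
  }
  invisible(model)
}

# -- optimizer ---------------------------------------------------------------

adam_init <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$m <- lapply(params, function(p) p$value * 0)  # zeros, same shape class
  st$v <- lapply(params, function(p) p$value * 0)
  st$t <- 0L
  st$lr <- lr; st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(st, lr = NULL) {
  st$t <- st$t + 1L
  lr <- lr %||% st$lr
  b1 <- st$beta1; b2 <- st$beta2
  bc1 <- 1 - b1^st$t
  bc2 <- 1 - b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    g <- p$grad
    if (is.null(g)) next
    st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
    st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    p$value <- p$value - lr * mhat / (sqrt(vhat) + st$eps)
  }
  invisible(st)
}
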