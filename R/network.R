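# The full U-shaped Conv-MLP segmentation network.
#
# Encoder stages (ECM) compute a convolutional feature `a`, a downsampled
# deeper look `d = conv(pool(a))`, an upsampled return `u = conv(up(d))`,
# and cross-gate `a` with `u`; the gated map is the skip connection, and
# `concat(pool(gated), d)` feeds the next stage. The bottleneck (BCM) and
# decoder stages (DCM) mirror this: the deep map is upsampled through a
# conv ("forward-looking" path), pooled back and cross-gated against a
# fusion of the deep map with the skip from the level below; the gated map
# is upsampled and fused (with the same-level skip, where one exists) into
# the stage output. The output stage (OCM) cross-gates two serial conv
# blocks and maps to class logits with a 1x1 convolution.
#
# Channel bookkeeping lives in one place, network_plan(), which both the
# builder and the parameter/FLOP accountants consume, so the closed-form
# costs and the instantiated model can never drift apart.

round4 <- function(x) max(4, 4 * round(x / 4))

#' Network configuration
#'
#' @param depth number of encoder stages (default 4).
#' @param base_channels channels of the first stage (default 64), doubling
#'   at every downsampling; must be a multiple of 4.
#' @param in_channels image channels (3 for RGB, 1 for grayscale).
#' @param num_classes output channels (1 for binary masks, sigmoid
#'   semantics).
#' @param b base window size of every multi-axis MLP block (constant across
#'   stages).
#' @param dropout_rate dropout inside the cross-gating blocks.
#' @param hidden_ratio expansion ratio of the MsM pre-split projection.
#' @return an object of class `net_config`. Any input image must have
#'   height and width divisible by `2^depth * 2b` (reported in
#'   `$divisor`).
#' @export
net_config <- function(depth = 4, base_channels = 64, in_channels = 3,
                       num_classes = 1, b = 2, dropout_rate = 0.1,
                       hidden_ratio = 1) {
  if (depth < 1) stop("depth must be at least 1")
  if (base_channels %% 4 != 0) stop("base_channels must be a multiple of 4")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 b = as.integer(b), dropout_rate = dropout_rate,
                 hidden_ratio = hidden_ratio,
                 divisor = as.integer(2^depth * 2 * b)),
            class = "net_config")
}

# Internal stage widths. The decoder widths of the default configuration
# (depth 4, base 64) are the calibrated plan; other configurations fall back
# to the same proportional rules.
internal_widths <- function(depth, base) {
  Fw <- base * 2^(seq_len(depth) - 1L)
  Dw <- 2L * Fw[depth]
  if (depth == 4L && base == 64L) {
    list(Fw = Fw, Dw = Dw, m = c(8L, 16L, 32L), u = c(13L, 16L, 64L),
         mb = 960L, ub = 48L, B = 64L)
  } else {
    m <- vapply(Fw, function(f) round4(f / 8), numeric(1))
    list(Fw = Fw, Dw = Dw,
         m = if (depth > 1) m[seq_len(depth - 1L)] else integer(0),
         u = if (depth > 1) m[seq_len(depth - 1L)] else integer(0),
         mb = max(Fw[depth], round4(15 * Dw / 16)),
         ub = max(8, round4(Dw / 21)),
         B = max(Fw[1L], round4(Dw / 16)))
  }
}

#' Stage plan of a network configuration
#'
#' Explicit channel bookkeeping for every stage: the encoder widths, the
#' decoder cross-gating and upsampling widths, and the concatenation widths
#' at every fusion. The builder and the parameter/FLOP accounting both read
#' this table, so a calibration edit is a one-line change.
#'
#' @param cfg a [net_config()].
#' @return a data.frame with one row per stage.
#' @export
network_plan <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  iw <- internal_widths(cfg$depth, cfg$base_channels)
  d <- cfg$depth
  enc <- data.frame(
    stage = paste0("ecm", seq_len(d)),
    level = seq_len(d),
    cin = c(cfg$in_channels, 2L * iw$Fw[-d]),
    width = iw$Fw,
    mcg = iw$Fw,
    up = NA_integer_,
    out = 2L * iw$Fw
  )
  bcm <- data.frame(stage = "bcm", level = d + 1L, cin = iw$Dw + iw$Fw[d],
                    width = NA_integer_, mcg = iw$mb, up = iw$ub, out = iw$B)
  if (d > 1) {
    lev <- seq.int(d - 1L, 1L)
    deepw <- c(iw$B, iw$Fw[seq.int(d - 1L, 2L)])
    dcm <- data.frame(
      stage = paste0("dcm", lev),
      level = lev,
      cin = deepw + iw$Fw[lev + 1L],
      width = iw$Fw[lev],
      mcg = iw$m[lev],
      up = iw$u[lev],
      out = iw$Fw[lev]
    )
  } else dcm <- NULL
  ocm <- data.frame(stage = "ocm", level = 1L, cin = iw$Fw[1L],
                    width = iw$Fw[1L], mcg = iw$Fw[1L], up = NA_integer_,
                    out = cfg$num_classes)
  rbind(enc, bcm, dcm, ocm)
}

# One row per learnable layer; the single source of truth for costs.
# `mult` is the number of forward applications per network pass (the shared
# MsM inside a cross-gating block runs on both streams).
layer_table <- function(cfg, input_hw = c(256, 256)) {
  iw <- internal_widths(cfg$depth, cfg$base_channels)
  d <- cfg$depth
  hw <- prod(input_hw) / 4^(0:(d + 1L))  # area at levels 1..depth+2
  rows <- list()
  add <- function(module, type, cin, cout, s, hw, mult = 1) {
    rows[[length(rows) + 1L]] <<- data.frame(
      module = module, type = type, cin = cin, cout = cout, s = s,
      hw = hw, mult = mult)
  }
  add_mcg <- function(module, C, hw) {
    h <- round(C * cfg$hidden_ratio)
    b <- cfg$b
    add(module, "ln", C, C, NA, hw); add(module, "dense", C, C, NA, hw)
    add(module, "ln", C, C, NA, hw); add(module, "dense", C, C, NA, hw)
    add(module, "ln", C, C, NA, hw, 2); add(module, "dense", C, h, NA, hw, 2)
    for (s in c(b^2, 4 * b^2, b^2, 4 * b^2))
      add(module, "mix", h / 4, h / 4, s, hw, 2)
    add(module, "dense", h, C, NA, hw, 2)
    add(module, "dense", C, C, NA, hw); add(module, "dense", C, C, NA, hw)
  }
  cin <- cfg$in_channels
  for (i in seq_len(d)) {
    f <- iw$Fw[i]; mod <- paste0("ecm", i)
    add(mod, "conv3", cin, f, NA, hw[i])
    add(mod, "conv3", f, f, NA, hw[i + 1L])
    add(mod, "conv3", f, f, NA, hw[i])
    add_mcg(mod, f, hw[i])
    cin <- 2L * f
  }
  add("bcm", "conv3", iw$Dw, iw$ub, NA, hw[d])
  add("bcm", "conv3", iw$Dw + iw$Fw[d], iw$mb, NA, hw[d + 1L])
  add("bcm", "conv3", iw$ub, iw$mb, NA, hw[d + 1L])
  add_mcg("bcm", iw$mb, hw[d + 1L])
  add("bcm", "conv3", iw$mb + iw$ub, iw$B, NA, hw[d])
  if (d > 1) {
    deepw <- iw$B
    for (i in seq.int(d - 1L, 1L)) {
      f <- iw$Fw[i]; mod <- paste0("dcm", i)
      add(mod, "conv3", deepw, iw$u[i], NA, hw[i])
      add(mod, "conv3", deepw + iw$Fw[i + 1L], iw$m[i], NA, hw[i + 1L])
      add(mod, "conv3", iw$u[i], iw$m[i], NA, hw[i + 1L])
      add_mcg(mod, iw$m[i], hw[i + 1L])
      add(mod, "conv3", iw$m[i] + iw$u[i] + f, f, NA, hw[i])
      deepw <- f
    }
  }
  f <- iw$Fw[1L]
  add("ocm", "conv3", f, f, NA, hw[1L])
  add("ocm", "conv3", f, f, NA, hw[1L])
  add_mcg("ocm", f, hw[1L])
  add("ocm", "conv1", f, cfg$num_classes, NA, hw[1L])
  tb <- do.call(rbind, rows)
  tb$params <- with(tb, ifelse(type == "conv3", 9 * cin * cout + 2 * cout,
                        ifelse(type %in% c("conv1", "dense"), cin * cout + cout,
                        ifelse(type == "ln", 2 * cout, s^2 + s))))
  tb$macs <- with(tb, mult * hw * ifelse(type == "conv3", 9 * cin * cout,
                       ifelse(type %in% c("conv1", "dense"), cin * cout,
                       ifelse(type == "ln", 0, s * cin))))
  tb
}

#' Count the learnable parameters of the network
#'
#' Closed-form count over the stage plan; independent of the input size.
#' It equals, exactly, the enumeration of every parameter tensor of the
#' instantiated model.
#'
#' @param cfg a [net_config()] (or a built network, whose config is used).
#' @return integer: total learnable scalars.
#' @examples
#' count_parameters(net_config()) / 1e6
#' @export
count_parameters <- function(cfg) {
  if (inherits(cfg, "cm_unet")) cfg <- cfg$cfg
  sum(layer_table(cfg)$params)
}

#' Count the multiply-accumulate cost of one forward pass
#'
#' One multiply-accumulate is counted as one FLOP; convolution and dense
#' (including the spatial-mixing MLP) layers are summed, normalisation and
#' activation operations are excluded. Under this convention the classic
#' 64-base U-Net at 256 x 256 costs about 54.6 GFLOPs
#' (see [unet_reference_cost()]).
#'
#' @param cfg a [net_config()].
#' @param input_hw integer length-2 vector, the input height and width.
#' @return total FLOPs (multiply-accumulates) of one forward pass.
#' @examples
#' count_flops(net_config(), c(256, 256)) / 1e9
#' @export
count_flops <- function(cfg, input_hw = c(256, 256)) {
  if (inherits(cfg, "cm_unet")) cfg <- cfg$cfg
  check_input_size(cfg, input_hw[1], input_hw[2])
  sum(layer_table(cfg, input_hw)$macs)
}

check_input_size <- function(cfg, H, W, stage = NULL) {
  m <- cfg$divisor
  if (H %% m == 0 && W %% m == 0) return(invisible(TRUE))
  padH <- (m - H %% m) %% m
  padW <- (m - W %% m) %% m
  where <- if (is.null(stage)) "input" else paste0("input to ", stage)
  stop(sprintf(paste0(
    "%s of size %d x %d is not divisible by %d (= 2^depth * 2b); ",
    "pad to %d x %d (e.g. reflect-pad by %d rows and %d columns)"),
    where, H, W, m, H + padH, W + padW, padH, padW))
}

#' Per-module cost summary of a configuration
#'
#' @param cfg a [net_config()].
#' @param input_hw input size used for the FLOP column.
#' @return a data.frame with per-module parameter and GFLOP totals plus a
#'   total row.
#' @export
model_summary <- function(cfg, input_hw = c(256, 256)) {
  if (inherits(cfg, "cm_unet")) cfg <- cfg$cfg
  tb <- layer_table(cfg, input_hw)
  agg <- aggregate(cbind(params, macs) ~ module, data = tb, FUN = sum)
  agg <- agg[order(match(agg$module, unique(tb$module))), ]
  total <- data.frame(module = "total", params = sum(tb$params),
                      macs = sum(tb$macs))
  out <- rbind(agg, total)
  out$gflops <- out$macs / 1e9
  rownames(out) <- NULL
  out[, c("module", "params", "gflops")]
}

# -- builders ---------------------------------------------------------------

new_ecm <- function(cin, f, cfg) {
  structure(list(
    a = new_conv_block(cin, f),
    d = new_conv_block(f, f),
    u = new_conv_block(f, f),
    mcg = mcg_block(mcg_config(f, b = cfg$b, dropout_rate = cfg$dropout_rate,
                               hidden_ratio = cfg$hidden_ratio))
  ), class = "ecm_block")
}

new_bcm <- function(deepw, skipw, mb, ub, B, cfg) {
  structure(list(
    up = new_conv_block(deepw, ub),
    p = new_conv_block(deepw + skipw, mb),
    q = new_conv_block(ub, mb),
    mcg = mcg_block(mcg_config(mb, b = cfg$b, dropout_rate = cfg$dropout_rate,
                               hidden_ratio = cfg$hidden_ratio)),
    out = new_conv_block(mb + ub, B)
  ), class = "bcm_block")
}

new_dcm <- function(deepw, f_same, f_below, m, u, cfg) {
  structure(list(
    up = new_conv_block(deepw, u),
    p = new_conv_block(deepw + f_below, m),
    q = new_conv_block(u, m),
    mcg = mcg_block(mcg_config(m, b = cfg$b, dropout_rate = cfg$dropout_rate,
                               hidden_ratio = cfg$hidden_ratio)),
    out = new_conv_block(m + u + f_same, f_same)
  ), class = "dcm_block")
}

new_ocm <- function(f, classes, cfg) {
  head <- new_dense(f, classes)
  # near-zero head: the untrained network starts at p ~ 0.5 everywhere
  # (closed-form step-0 loss) while gradients still reach every stage
  head$w$value <- head$w$value * 0 + stats::rnorm(length(head$w$value), 0, 1e-3)
  structure(list(
    c1 = new_conv_block(f, f),
    c2 = new_conv_block(f, f),
    mcg = mcg_block(mcg_config(f, b = cfg$b, dropout_rate = cfg$dropout_rate,
                               hidden_ratio = cfg$hidden_ratio)),
    head = head
  ), class = "ocm_block")
}

#' Build the Conv-MLP U-Net
#'
#' Instantiates all stages of the network according to the configuration's
#' stage plan.
#'
#' @param cfg a [net_config()].
#' @return a model object of class `cm_unet`.
#' @export
cm_unet <- function(cfg = net_config()) {
  stopifnot(inherits(cfg, "net_config"))
  iw <- internal_widths(cfg$depth, cfg$base_channels)
  d <- cfg$depth
  ecm <- vector("list", d)
  cin <- cfg$in_channels
  for (i in seq_len(d)) {
    ecm[[i]] <- new_ecm(cin, iw$Fw[i], cfg)
    cin <- 2L * iw$Fw[i]
  }
  bcm <- new_bcm(iw$Dw, iw$Fw[d], iw$mb, iw$ub, iw$B, cfg)
  dcm <- list()
  if (d > 1) {
    deepw <- iw$B
    for (i in seq.int(d - 1L, 1L)) {
      dcm[[as.character(i)]] <- new_dcm(deepw, iw$Fw[i], iw$Fw[i + 1L],
                                        iw$m[i], iw$u[i], cfg)
      deepw <- iw$Fw[i]
    }
  }
  ocm <- new_ocm(iw$Fw[1L], cfg$num_classes, cfg)
  structure(list(cfg = cfg, ecm = ecm, bcm = bcm, dcm = dcm, ocm = ocm),
            class = "cm_unet")
}

# -- stage forwards (node level) --------------------------------------------

ecm_apply <- function(blk, x, training = FALSE) {
  a <- cb_forward(blk$a, x, training)
  dn <- cb_forward(blk$d, ad_maxpool2(a), training)
  u <- cb_forward(blk$u, ad_upsample2(dn), training)
  m <- mcg_apply(blk$mcg, a, u, training)
  list(skip = m, down = ad_concat_c(list(ad_maxpool2(m), dn)), d = dn)
}

bcm_apply <- function(blk, deep, skip_below, training = FALSE) {
  upd <- cb_forward(blk$up, ad_upsample2(deep), training)
  p <- cb_forward(blk$p, ad_concat_c(list(deep, skip_below)), training)
  q <- cb_forward(blk$q, ad_maxpool2(upd), training)
  m <- mcg_apply(blk$mcg, p, q, training)
  cb_forward(blk$out, ad_concat_c(list(ad_upsample2(m), upd)), training)
}

dcm_apply <- function(blk, deep, skip_same, skip_below, training = FALSE) {
  dd <- dim(deep$value); ds <- dim(skip_same$value); db <- dim(skip_below$value)
  if (dd[1L] * 2L != ds[1L] || dd[2L] * 2L != ds[2L])
    stop("decoder stage: deep map must be at half the resolution of the same-level skip")
  if (!identical(dd[1:2], db[1:2]))
    stop("decoder stage: deep map and below-level skip must share a resolution")
  upd <- cb_forward(blk$up, ad_upsample2(deep), training)
  p <- cb_forward(blk$p, ad_concat_c(list(deep, skip_below)), training)
  q <- cb_forward(blk$q, ad_maxpool2(upd), training)
  m <- mcg_apply(blk$mcg, p, q, training)
  cb_forward(blk$out, ad_concat_c(list(ad_upsample2(m), upd, skip_same)),
             training)
}

ocm_apply <- function(blk, x, training = FALSE) {
  c1 <- cb_forward(blk$c1, x, training)
  c2 <- cb_forward(blk$c2, c1, training)
  m <- mcg_apply(blk$mcg, c1, c2, training)
  ad_dense(m, blk$head$w, blk$head$b)   # 1x1 conv to logits, no activation
}

net_apply <- function(model, x, training = FALSE) {
  d <- model$cfg$depth
  skips <- vector("list", d)
  h <- x
  last_d <- NULL
  for (i in seq_len(d)) {
    st <- ecm_apply(model$ecm[[i]], h, training)
    skips[[i]] <- st$skip
    h <- st$down
    last_d <- st$d
  }
  h <- bcm_apply(model$bcm, h, last_d, training)
  if (d > 1) {
    for (i in seq.int(d - 1L, 1L)) {
      h <- dcm_apply(model$dcm[[as.character(i)]], h, skips[[i]],
                     skips[[i + 1L]], training)
    }
  }
  ocm_apply(model$ocm, h, training)
}

#' Forward pass of the network
#'
#' @param model a [cm_unet()].
#' @param image an `H x W x C` array (or `H x W x C x N` batch) with `C`
#'   equal to the configured input channels; `H` and `W` must be divisible
#'   by `2^depth * 2b`, otherwise an error states the minimal valid padded
#'   size.
#' @param training logical; enables dropout and batch-statistics mode.
#' @return logits of dim `H x W x num_classes` (no activation; apply
#'   [stats::plogis] or the loss's sigmoid).
#' @export
net_forward <- function(model, image, training = FALSE) {
  stopifnot(inherits(model, "cm_unet"))
  x4 <- as_fm4(image)
  dd <- dim(x4$a)
  check_input_size(model$cfg, dd[1L], dd[2L])
  if (dd[3L] != model$cfg$in_channels)
    stop(sprintf("image has %d channels, network expects %d", dd[3L],
                 model$cfg$in_channels))
  out <- net_apply(model, node_in(x4), training)
  array_out(out, x4$batched)
}

#' Stage forwards on plain arrays
#'
#' Convenience wrappers running one encoder, bottleneck, decoder or output
#' stage on plain arrays. Mainly useful for inspecting shapes and wiring;
#' [net_forward()] runs the assembled network.
#'
#' @param block a stage built by [cm_unet()] (elements of `$ecm`, `$bcm`,
#'   `$dcm`, `$ocm`).
#' @param x,deep,skip_same,skip_below feature maps (`H x W x C` arrays).
#' @param training logical.
#' @return `ecm_forward`: a list with `skip` (the cross-gated map, the skip
#'   connection) and `down` (half-resolution input to the next stage);
#'   the others: a feature map.
#' @export
ecm_forward <- function(block, x, training = FALSE) {
  x4 <- as_fm4(x)
  st <- ecm_apply(block, node_in(x4), training)
  list(skip = array_out(st$skip, x4$batched),
       down = array_out(st$down, x4$batched))
}

#' @rdname ecm_forward
#' @export
bcm_forward <- function(block, deep, skip_below, training = FALSE) {
  d4 <- as_fm4(deep); s4 <- as_fm4(skip_below)
  out <- bcm_apply(block, node_in(d4), node_in(s4), training)
  array_out(out, d4$batched)
}

#' @rdname ecm_forward
#' @export
dcm_forward <- function(block, deep, skip_same, skip_below, training = FALSE) {
  d4 <- as_fm4(deep); ss <- as_fm4(skip_same); sb <- as_fm4(skip_below)
  out <- dcm_apply(block, node_in(d4), node_in(ss), node_in(sb), training)
  array_out(out, d4$batched)
}

#' @rdname ecm_forward
#' @export
ocm_forward <- function(block, x, training = FALSE) {
  x4 <- as_fm4(x)
  out <- ocm_apply(block, node_in(x4), training)
  array_out(out, x4$batched)
}

# -- reference U-Net cost (FLOP-convention calibrator) -----------------------

#' Cost of the classic U-Net under this package's counting convention
#'
#' Parameter and multiply-accumulate count of the classic 64-base U-Net
#' (double 3x3 conv + batch norm per stage, 2x2 max pooling, 2x2
#' transposed-convolution upsampling, 1x1 output head) — the baseline whose
#' printed cost anchors the one-MAC-one-FLOP convention used by
#' [count_flops()].
#'
#' @param input_hw input height and width.
#' @param in_channels,num_classes image channels and output classes.
#' @return list with `params` and `gflops`.
#' @export
unet_reference_cost <- function(input_hw = c(256, 256), in_channels = 3,
                                num_classes = 1) {
  widths <- c(64, 128, 256, 512, 1024)
  hw <- prod(input_hw) / 4^(0:4)
  P <- 0; M <- 0
  dc <- function(ci, co, a) {  # double conv with BN
    P <<- P + 9 * ci * co + 2 * co + 9 * co * co + 2 * co
    M <<- M + (9 * ci * co + 9 * co * co) * a
  }
  cin <- in_channels
  for (i in 1:5) { dc(cin, widths[i], hw[i]); cin <- widths[i] }
  for (i in 4:1) {
    ci <- widths[i + 1]; co <- widths[i]
    P <- P + 4 * ci * co + co          # 2x2 transposed conv, with bias
    M <- M + 4 * ci * co * hw[i]
    dc(2 * co, co, hw[i])
  }
  P <- P + widths[1] * num_classes + num_classes
  M <- M + widths[1] * num_classes * hw[1]
  list(params = P, gflops = M / 1e9)
}
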