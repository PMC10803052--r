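# Reverse-mode automatic differentiation over dense arrays.
#
# Inside the engine, feature maps are stored as 4-D arrays with dim
# c(H, W, N, C) — rows, columns, batch, channels. With channels last and R's
# column-major layout, the (H*W*N, C) matrix view used by every per-pixel
# channel operation (dense projections, layer/batch norm) is a zero-copy
# `dim<-`, which is what makes the engine fast enough for CPU training. The
# public API (layers.R and the module wrappers) presents the conventional
# H x W x C (x N) order and converts at the boundary.
#
# Every operation builds an `ad_node` holding the forward value, the parent
# nodes and a vector-Jacobian-product closure; nodes are recorded on a tape
# in creation order, so a single reverse sweep implements backpropagation.
# Only the operations the network needs exist, each with a bespoke vjp so
# that large intermediates never materialise. Gradients are not computed
# into nodes that cannot need them (constant inputs).

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL

ad_tape_start <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  .ad$tape <- tp
  invisible(tp)
}

ad_tape_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

ad_record <- function(node) {
  tp <- .ad$tape
  if (is.null(tp)) return(invisible(node))
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[tp$n]] <- node
  invisible(node)
}

ad_node <- function(value, parents = list(), vjp = NULL) {
  if (is.null(.ad$tape)) {
    # inference: no backward pass can happen, so do not retain the graph
    # (the vjp closures capture large forward intermediates)
    parents <- list()
    vjp <- NULL
  }
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$vjp <- vjp
  n$is_param <- FALSE
  n$needs_grad <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$needs_grad, logical(1)))
  class(n) <- "ad_node"
  if (length(parents) > 0L) ad_record(n)
  n
}

ad_const <- function(x) ad_node(x)

ad_param <- function(x) {
  n <- ad_node(x)
  n$is_param <- TRUE
  n$needs_grad <- TRUE
  n
}

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# Reverse sweep. `loss` must be a scalar node created while the tape was live.
ad_backward <- function(loss) {
  tp <- .ad$tape
  if (is.null(tp)) stop("no active tape; call ad_tape_start() before the forward pass")
  loss$grad <- 1
  for (i in seq.int(tp$n, 1L)) {
    nd <- tp$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$vjp)) next
    gs <- nd$vjp(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# -- reshape helpers (free under the internal H, W, N, C layout) -------------

fm_to_mat <- function(a) {
  d <- dim(a)
  dim(a) <- c(d[1L] * d[2L] * d[3L], d[4L])
  a
}

mat_to_fm <- function(m, d4) {
  dim(m) <- d4
  m
}

# public H x W x C x N  <->  internal H x W x N x C
to_internal <- function(a) aperm(a, c(1L, 2L, 4L, 3L))
to_public <- function(a) aperm(a, c(1L, 2L, 4L, 3L))

# -- elementwise -------------------------------------------------------------

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_scale <- function(a, s) {
  ad_node(a$value * s, list(a), function(g) list(g * s))
}

ad_relu <- function(a) {
  av <- a$value
  pos <- av > 0
  ad_node(av * pos, list(a), function(g) list(g * pos))
}

# GELU via the sigmoid approximation x * sigmoid(1.702 x) (accurate to ~1e-2
# and substantially cheaper than the erf form on CPU).
ad_gelu <- function(a) {
  av <- a$value
  s <- 1 / (1 + exp(-1.702 * av))
  ad_node(av * s, list(a), function(g)
    list(g * (s + 1.702 * av * s * (1 - s))))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$value))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

# Inverted dropout; identity when not training or rate == 0. Draws from the
# R RNG, so seeding the session seeds the masks.
ad_dropout <- function(a, rate, training) {
  if (!training || rate <= 0) return(a)
  av <- a$value
  keep <- array(stats::runif(length(av)) >= rate, dim = dim(av))
  sc <- 1 / (1 - rate)
  ad_node(av * keep * sc, list(a), function(g) list(g * keep * sc))
}

ad_mean <- function(a) {
  n <- length(a$value)
  d <- dim(a$value)
  ad_node(mean(a$value), list(a), function(g) list(array(g / n, dim = d)))
}

ad_sum <- function(a) {
  d <- dim(a$value)
  ad_node(sum(a$value), list(a), function(g) list(array(g, dim = d)))
}

# -- channel plumbing (channels are the 4th internal axis) -------------------

ad_concat_c <- function(xs) {
  vs <- lapply(xs, function(x) x$value)
  d1 <- dim(vs[[1L]])
  cs <- vapply(vs, function(v) dim(v)[4L], numeric(1))
  out <- array(0, c(d1[1L], d1[2L], d1[3L], sum(cs)))
  off <- 0L
  for (v in vs) {
    ci <- dim(v)[4L]
    out[, , , off + seq_len(ci)] <- v
    off <- off + ci
  }
  offs <- cumsum(c(0L, cs))
  ad_node(out, xs, function(g) {
    lapply(seq_along(xs), function(j) {
      g[, , , (offs[j] + 1L):offs[j + 1L], drop = FALSE]
    })
  })
}

ad_slice_c <- function(x, from, to) {
  xv <- x$value
  d <- dim(xv)
  out <- xv[, , , from:to, drop = FALSE]
  ad_node(out, list(x), function(g) {
    dx <- array(0, d)
    dx[, , , from:to] <- g
    list(dx)
  })
}

# -- dense / conv / norm layers ---------------------------------------------

# Per-pixel channel projection: weights (Cin x Cout), bias length Cout.
ad_dense <- function(x, w, b) {
  xv <- x$value
  d <- dim(xv)
  wv <- w$value
  xm <- fm_to_mat(xv)
  out <- xm %*% wv
  bv <- b$value
  out <- out + rep(bv, each = nrow(out))
  Co <- ncol(wv)
  ad_node(mat_to_fm(out, c(d[1:3], Co)), list(x, w, b), function(g) {
    gm <- fm_to_mat(g)
    list(if (x$needs_grad) mat_to_fm(gm %*% t(wv), d) else NULL,
         crossprod(xm, gm),
         colSums(gm))
  })
}

# 3x3 convolution, stride 1, zero padding 1, no bias (batch norm follows).
# Weight dim c(3, 3, Cin, Cout).
ad_conv3 <- function(x, w) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; N <- d[3L]; Ci <- d[4L]
  wv <- w$value
  Co <- dim(wv)[4L]
  xp <- array(0, c(H + 2L, W + 2L, N, Ci))
  xp[2:(H + 1L), 2:(W + 1L), , ] <- xv
  Wm <- vector("list", 9L)
  acc <- matrix(0, H * W * N, Co)
  for (a in 0:2) for (b in 0:2) {
    k <- a * 3L + b + 1L
    Wm[[k]] <- matrix(wv[a + 1L, b + 1L, , ], Ci, Co)
    xs <- xp[(1L + a):(H + a), (1L + b):(W + b), , , drop = FALSE]
    acc <- acc + fm_to_mat(xs) %*% Wm[[k]]
  }
  ad_node(mat_to_fm(acc, c(H, W, N, Co)), list(x, w), function(g) {
    gm <- fm_to_mat(g)
    dw <- array(0, c(3L, 3L, Ci, Co))
    dxp <- if (x$needs_grad) array(0, c(H + 2L, W + 2L, N, Ci)) else NULL
    for (a in 0:2) for (b in 0:2) {
      k <- a * 3L + b + 1L
      xs <- xp[(1L + a):(H + a), (1L + b):(W + b), , , drop = FALSE]
      dw[a + 1L, b + 1L, , ] <- crossprod(fm_to_mat(xs), gm)
      if (!is.null(dxp)) {
        dxs <- mat_to_fm(gm %*% t(Wm[[k]]), c(H, W, N, Ci))
        dxp[(1L + a):(H + a), (1L + b):(W + b), , ] <-
          dxp[(1L + a):(H + a), (1L + b):(W + b), , , drop = FALSE] + dxs
      }
    }
    list(if (!is.null(dxp)) dxp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE] else NULL,
         dw)
  })
}

# Layer normalisation across channels at each pixel, with affine terms.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  d <- dim(xv)
  gm_v <- gamma$value
  xm <- fm_to_mat(xv)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  n <- nrow(xm)
  y <- xh * rep(gm_v, each = n) + rep(beta$value, each = n)
  ad_node(mat_to_fm(y, d), list(x, gamma, beta), function(g) {
    gmat <- fm_to_mat(g)
    dyh <- gmat * rep(gm_v, each = n)
    dx <- inv * (dyh - rowMeans(dyh) - xh * rowMeans(dyh * xh))
    list(mat_to_fm(dx, d),
         colSums(gmat * xh),
         colSums(gmat))
  })
}

# Batch normalisation per channel over (H, W, N). `state` is an environment
# carrying running_mean / running_var, updated as a side effect in training.
ad_batchnorm <- function(x, gamma, beta, state, training, eps = 1e-5, momentum = 0.1) {
  xv <- x$value
  d <- dim(xv)
  gm_v <- gamma$value
  xm <- fm_to_mat(xv)
  n <- nrow(xm)
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = n)
    v <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    vu <- if (n > 1L) v * n / (n - 1L) else v
    state$running_var <- (1 - momentum) * state$running_var + momentum * vu
  } else {
    mu <- state$running_mean
    xc <- xm - rep(mu, each = n)
    v <- state$running_var
  }
  inv <- 1 / sqrt(v + eps)
  xh <- xc * rep(inv, each = n)
  y <- xh * rep(gm_v, each = n) + rep(beta$value, each = n)
  ad_node(mat_to_fm(y, d), list(x, gamma, beta), function(g) {
    gmat <- fm_to_mat(g)
    dyh <- gmat * rep(gm_v, each = n)
    if (training) {
      dx <- dyh - rep(colMeans(dyh), each = n) -
        xh * rep(colMeans(dyh * xh), each = n)
      dx <- dx * rep(inv, each = n)
    } else {
      dx <- dyh * rep(inv, each = n)
    }
    list(mat_to_fm(dx, d),
         colSums(gmat * xh),
         colSums(gmat))
  })
}

# -- spatial resampling ------------------------------------------------------

# 2x2 max pooling (stride 2). Requires even H and W. The trailing two axes
# are opaque (any meaning), only the first two are spatial.
ad_maxpool2 <- function(x) {
  xv <- x$value
  d <- dim(xv)
  H <- d[1L]; W <- d[2L]; d3 <- d[3L]; d4 <- d[4L]
  h2 <- H %/% 2L; w2 <- W %/% 2L
  A <- xv
  dim(A) <- c(2L, h2, W, d3, d4)
  A <- aperm(A, c(1L, 3L, 2L, 4L, 5L))        # (2, W, h2, d3, d4)
  dim(A) <- c(2L, 2L, w2, h2, d3, d4)
  s <- lapply(1:4, function(k) {
    i <- (k - 1L) %% 2L + 1L; j <- (k - 1L) %/% 2L + 1L
    v <- A[i, j, , , , , drop = FALSE]
    dim(v) <- c(w2, h2, d3, d4)
    v
  })
  y <- pmax(s[[1L]], s[[2L]], s[[3L]], s[[4L]])
  m1 <- s[[1L]] == y
  m2 <- (s[[2L]] == y) & !m1
  m3 <- (s[[3L]] == y) & !(m1 | m2)
  m4 <- !(m1 | m2 | m3)
  out <- aperm(y, c(2L, 1L, 3L, 4L))          # (h2, w2, d3, d4)
  ad_node(out, list(x), function(g) {
    gp <- aperm(g, c(2L, 1L, 3L, 4L))
    dA <- array(0, c(2L, 2L, w2, h2, d3, d4))
    masks <- list(m1, m2, m3, m4)
    for (k in 1:4) {
      i <- (k - 1L) %% 2L + 1L; j <- (k - 1L) %/% 2L + 1L
      dA[i, j, , , , ] <- gp * masks[[k]]
    }
    dA <- aperm(dA, c(1L, 4L, 2L, 3L, 5L, 6L))  # (2, h2, 2, w2, d3, d4)
    dim(dA) <- c(H, W, d3, d4)
    list(dA)
  })
}

# Cached 1-D bilinear upsampling matrices (factor 2, half-pixel centres).
.ad$up_cache <- new.env(parent = emptyenv())

up2_matrix <- function(n) {
  key <- as.character(n)
  hit <- .ad$up_cache[[key]]
  if (!is.null(hit)) return(hit)
  A <- matrix(0, 2L * n, n)
  for (i in seq_len(2L * n)) {
    s <- (i - 0.5) / 2 - 0.5          # source coordinate, 0-based
    s <- min(max(s, 0), n - 1)
    j0 <- floor(s)
    w <- s - j0
    A[i, j0 + 1L] <- A[i, j0 + 1L] + (1 - w)
    if (w > 0) A[i, j0 + 2L] <- A[i, j0 + 2L] + w
  }
  .ad$up_cache[[key]] <- A
  A
}

# apply matrix M (m x H) along the first axis of a 4-D array
apply_rows <- function(a, M) {
  d <- dim(a)
  dim(a) <- c(d[1L], prod(d[-1L]))
  out <- M %*% a
  dim(out) <- c(nrow(M), d[-1L])
  out
}

# apply matrix M (m x W) along the second axis
apply_cols <- function(a, M) {
  d <- dim(a)
  ap <- aperm(a, c(2L, 1L, 3L, 4L))
  dim(ap) <- c(d[2L], d[1L] * d[3L] * d[4L])
  out <- M %*% ap
  dim(out) <- c(nrow(M), d[1L], d[3L], d[4L])
  aperm(out, c(2L, 1L, 3L, 4L))
}

# Bilinear x2 upsampling, channel preserving.
ad_upsample2 <- function(x) {
  xv <- x$value
  d <- dim(xv)
  Ah <- up2_matrix(d[1L])
  Aw <- up2_matrix(d[2L])
  out <- apply_cols(apply_rows(xv, Ah), Aw)
  ad_node(out, list(x), function(g) {
    list(apply_rows(apply_cols(g, t(Aw)), t(Ah)))
  })
}

# -- spatial MLP mixing ------------------------------------------------------

# Linear map along a grouped-pixel axis. `perm` reorders the H*W pixels so
# that each consecutive run of `s` pixels forms one mixing group; `w` is the
# (s x s) mixing matrix shared across groups, channels and batch, `b` its bias.
ad_mix <- function(x, w, b, perm, s) {
  xv <- x$value
  d <- dim(xv)
  HW <- d[1L] * d[2L]
  CN <- d[3L] * d[4L]
  wv <- w$value
  xm <- xv
  dim(xm) <- c(HW, CN)
  xp <- xm[perm, , drop = FALSE]
  dim(xp) <- c(s, (HW %/% s) * CN)
  y <- wv %*% xp + as.vector(b$value)
  dim(y) <- c(HW, CN)
  ym <- matrix(0, HW, CN)
  ym[perm, ] <- y
  dim(ym) <- d
  ad_node(ym, list(x, w, b), function(g) {
    gmm <- g
    dim(gmm) <- c(HW, CN)
    gp <- gmm[perm, , drop = FALSE]
    dim(gp) <- c(s, (HW %/% s) * CN)
    dW <- tcrossprod(gp, xp)
    db <- rowSums(gp)
    dxp <- crossprod(wv, gp)
    dim(dxp) <- c(HW, CN)
    dxm <- matrix(0, HW, CN)
    dxm[perm, ] <- dxp
    dim(dxm) <- d
    list(dxm, dW, db)
  })
}

# -- losses ------------------------------------------------------------------

# Two-term binary cross-entropy on probabilities against a {0,1} target,
# mean over all entries; probabilities are clipped to [eps, 1 - eps] and the
# gradient is zero in the clipped region.
ad_bce <- function(p, truth, eps = 1e-7) {
  pv <- p$value
  tv <- ad_value(truth)
  inside <- pv >= eps & pv <= 1 - eps
  pc <- pmin(pmax(pv, eps), 1 - eps)
  n <- length(pv)
  lv <- -mean(tv * log(pc) + (1 - tv) * log(1 - pc))
  ad_node(lv, list(p), function(g) {
    list(g * inside * (-(tv / pc) + (1 - tv) / (1 - pc)) / n)
  })
}

# Soft Dice loss with additive smoothing on probabilities.
ad_dice <- function(p, truth, smooth = 1) {
  pv <- p$value
  tv <- ad_value(truth)
  num <- 2 * sum(tv * pv) + smooth
  den <- sum(tv) + sum(pv) + smooth
  ad_node(1 - num / den, list(p), function(g) {
    list(g * (-(2 * tv * den - num) / den^2))
  })
}
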