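# Window ("block") and grid partitions of a feature map.
#
# A block partition tiles the H x W plane into non-overlapping w x w windows;
# mixing inside a window gives dense local interaction. A grid partition
# divides the plane into a g x g arrangement of large (H/g) x (W/g) cells;
# gathering one pixel per cell at a shared within-cell offset gives a dilated,
# globally sparse interaction with stride (H/g, W/g). Both are pure
# rearrangements (exact bijections on pixel values).

check_div <- function(H, W, w, what = "window") {
  if (H %% w != 0)
    stop(sprintf("height %d is not divisible by %s size %d", H, what, w))
  if (W %% w != 0)
    stop(sprintf("width %d is not divisible by %s size %d", W, what, w))
}

as_fm3 <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("feature map must be an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L)
  else if (length(d) != 3L) stop("feature map must be H x W or H x W x C")
  x
}

# Flat (column-major) pixel indices of the H x W plane, ordered so that for
# window shape (wh, ww) the index matrix is (n_windows x positions): windows
# enumerated row-major over the window grid, positions row-major (left to
# right, then next row) inside each window.
window_index <- function(H, W, wh, ww) {
  nh <- H %/% wh
  nw <- W %/% ww
  win <- integer(nh * nw * wh * ww)
  k <- 0L
  idx <- matrix(0L, nh * nw, wh * ww)
  for (i in seq_len(nh)) for (j in seq_len(nw)) {
    k <- k + 1L
    r0 <- (i - 1L) * wh
    c0 <- (j - 1L) * ww
    p <- 0L
    for (r in seq_len(wh)) for (cc in seq_len(ww)) {
      p <- p + 1L
      idx[k, p] <- (r0 + r) + (c0 + cc - 1L) * H
    }
  }
  idx
}

#' Partition a feature map into non-overlapping square windows
#'
#' Tiles the `H x W` plane into `(H/w) * (W/w)` contiguous `w x w` windows.
#' Window `(i, j)` holds the patch at rows `[i*w, (i+1)*w)` and columns
#' `[j*w, (j+1)*w)` (0-based), stored row-major within the window. The
#' operation is a pure rearrangement; [block_unpartition()] is its exact
#' inverse.
#'
#' @param x an `H x W x C` array (an `H x W` matrix is treated as `C = 1`).
#' @param w window edge length; must divide both `H` and `W`.
#' @return an array of dim `(n_windows, w * w, C)`.
#' @examples
#' x <- array(0:15, c(4, 4, 1))  # column-major fill
#' t <- block_partition(x, 2)
#' dim(t)
#' @seealso [grid_partition()] for the dilated global counterpart.
#' @export
block_partition <- function(x, w) {
  x <- as_fm3(x)
  d <- dim(x)
  check_div(d[1L], d[2L], w)
  idx <- window_index(d[1L], d[2L], w, w)
  gather_plane(x, idx)
}

gather_plane <- function(x, idx) {
  d <- dim(x)
  xm <- x
  dim(xm) <- c(d[1L] * d[2L], d[3L])
  t0 <- xm[as.vector(idx), , drop = FALSE]
  dim(t0) <- c(nrow(idx), ncol(idx), d[3L])
  t0
}

scatter_plane <- function(t0, idx, H, W) {
  d <- dim(t0)
  C <- d[3L]
  dim(t0) <- c(d[1L] * d[2L], C)
  xm <- matrix(0, H * W, C)
  xm[as.vector(idx), ] <- t0
  dim(xm) <- c(H, W, C)
  xm
}

#' Undo a block partition
#'
#' Exact inverse of [block_partition()].
#'
#' @param t an array of dim `(n_windows, w * w, C)`.
#' @param H,W the spatial dimensions of the original map.
#' @param w the window edge length used for partitioning.
#' @return the reconstructed `H x W x C` array.
#' @export
block_unpartition <- function(t, H, W, w) {
  d <- dim(t)
  if (length(d) != 3L) stop("windowed tensor must be 3-dimensional")
  check_div(H, W, w)
  if (d[1L] != (H %/% w) * (W %/% w) || d[2L] != w * w)
    stop(sprintf(
      "windowed tensor of dim (%d, %d, %d) is inconsistent with H = %d, W = %d, w = %d",
      d[1L], d[2L], d[3L], H, W, w))
  idx <- window_index(H, W, w, w)
  scatter_plane(t, idx, H, W)
}

#' Partition a feature map into a g x g grid of large cells
#'
#' Divides the `H x W` plane into a fixed `g x g` arrangement of cells of
#' size `(H/g) x (W/g)`. The first axis enumerates the `g * g` cells
#' (row-major over the grid), the second the positions within a cell
#' (row-major). Mixing along the first axis therefore couples, for each
#' shared within-cell offset, one pixel per cell — a dilated pattern with
#' stride `(H/g, W/g)` across the whole map. On square inputs this layout
#' coincides with `block_partition(x, H/g)`.
#'
#' @param x an `H x W x C` array.
#' @param g grid size; `g` must divide both `H` and `W`.
#' @return an array of dim `(g * g, (H/g) * (W/g), C)`.
#' @seealso [block_partition()], [grid_unpartition()]
#' @export
grid_partition <- function(x, g) {
  x <- as_fm3(x)
  d <- dim(x)
  check_div(d[1L], d[2L], g, what = "grid")
  idx <- window_index(d[1L], d[2L], d[1L] %/% g, d[2L] %/% g)
  gather_plane(x, idx)
}

#' Undo a grid partition
#'
#' Exact inverse of [grid_partition()].
#'
#' @param t an array of dim `(g * g, (H/g) * (W/g), C)`.
#' @param H,W the spatial dimensions of the original map.
#' @param g the grid size used for partitioning.
#' @return the reconstructed `H x W x C` array.
#' @export
grid_unpartition <- function(t, H, W, g) {
  d <- dim(t)
  if (length(d) != 3L) stop("gridded tensor must be 3-dimensional")
  check_div(H, W, g, what = "grid")
  if (d[1L] != g * g || d[2L] != (H %/% g) * (W %/% g))
    stop(sprintf(
      "gridded tensor of dim (%d, %d, %d) is inconsistent with H = %d, W = %d, g = %d",
      d[1L], d[2L], d[3L], H, W, g))
  idx <- window_index(H, W, H %/% g, W %/% g)
  scatter_plane(t, idx, H, W)
}

# -- mixing permutations -----------------------------------------------------
#
# For the MLP mixing ops the H*W pixels are reordered so that every
# consecutive run of `s` pixels is one mixing group:
#  * local ("block") mixing at window size w: groups are the w x w windows,
#    s = w^2, within-window positions fastest;
#  * global ("grid") mixing at grid size g: groups are the same-offset sets,
#    s = g^2, the g^2 cells fastest.

.perm_cache <- new.env(parent = emptyenv())

mix_perm <- function(H, W, size, type = c("block", "grid")) {
  type <- match.arg(type)
  key <- paste(H, W, size, type, sep = "_")
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (type == "block") {
    idx <- window_index(H, W, size, size)
    # groups (rows of idx) = windows; want within-window position fastest
    perm <- as.vector(t(idx))
  } else {
    idx <- window_index(H, W, H %/% size, W %/% size)
    # rows = cells, columns = offsets; want cell index fastest
    perm <- as.vector(idx)
  }
  .perm_cache[[key]] <- perm
  perm
}
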