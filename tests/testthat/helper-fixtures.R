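# Shared helpers: tiny deterministic fixtures built in code.

tiny_net <- function(depth = 2, base = 8, in_channels = 3, dropout = 0) {
  net_config(depth = depth, base_channels = base, in_channels = in_channels,
             dropout_rate = dropout)
}

# a 4x4x1 map holding 0..15 in row-major reading order
rowmajor_4x4 <- function() {
  x <- array(0, c(4, 4, 1))
  for (r in 1:4) for (cc in 1:4) x[r, cc, 1] <- (r - 1) * 4 + (cc - 1)
  x
}

rand_fm <- function(H, W, C, seed = 1) {
  set.seed(seed)
  array(rnorm(H * W * C), c(H, W, C))
}

mask_centroid <- function(w) {
  tot <- sum(w)
  c(sum(row(w) * w), sum(col(w) * w)) / tot
}
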