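## Minimal differentiable convolution engine.
##
## Feature extraction has to be differentiable with respect to the input
## image so the style-transfer inner loop can descend on pixels. There is no
## automatic-differentiation framework among this package's dependencies, so
## the three layer types the supported backbones need (3x3 'same' stride-1
## convolution, ReLU, 2x2 max-pooling) carry hand-derived backward passes.
## Convolutions are executed as im2col + matrix multiply so the heavy work
## lands in BLAS.
##
## Tensor layout: activations are arrays of dim (H, W, C); convolution
## weights are arrays of dim (kh, kw, c_in, c_out), biases length c_out.

pad_zero <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- x
  out
}

## Patch matrix of a zero-padded tensor: row = output position (column-major
## over H x W), column = (di, dj, c) with di fastest, matching how
## matrix(weight) flattens a (kh, kw, c_in, c_out) array.
im2col <- function(xp, h, w, kh, kw) {
  cc <- dim(xp)[3]
  cols <- matrix(0, h * w, kh * kw * cc)
  k <- 1L
  for (c in seq_len(cc)) {
    for (dj in 0:(kw - 1L)) {
      for (di in 0:(kh - 1L)) {
        cols[, k] <- xp[di + seq_len(h), dj + seq_len(w), c]
        k <- k + 1L
      }
    }
  }
  cols
}

conv_forward <- function(x, weight, bias) {
  d <- dim(x)
  kh <- dim(weight)[1]
  kw <- dim(weight)[2]
  p <- (kh - 1L) %/% 2L
  cols <- im2col(pad_zero(x, p), d[1], d[2], kh, kw)
  wmat <- matrix(weight, nrow = kh * kw * dim(weight)[3])
  y <- cols %*% wmat
  y <- sweep(y, 2L, bias, "+")
  array(y, c(d[1], d[2], dim(weight)[4]))
}

## Gradient w.r.t. the input of a 'same' stride-1 convolution: convolve the
## upstream gradient with the spatially flipped, channel-transposed kernel.
conv_backward_input <- function(dy, weight) {
  kh <- dim(weight)[1]
  kw <- dim(weight)[2]
  wb <- aperm(weight[rev(seq_len(kh)), rev(seq_len(kw)), , , drop = FALSE],
              c(1L, 2L, 4L, 3L))
  conv_forward(dy, wb, rep(0, dim(wb)[4]))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

## dL/d(pre-activation) given dL/d(post-activation); post > 0 iff pre > 0.
relu_backward <- function(dpost, post) {
  dpost * (post > 0)
}

maxpool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L) {
    stop_rnst("max-pooling requires even spatial dimensions, got ",
              d[1], "x", d[2], class = "rnst_shape_error")
  }
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  views <- list(
    x[io, jo, , drop = FALSE],
    x[io + 1L, jo, , drop = FALSE],
    x[io, jo + 1L, , drop = FALSE],
    x[io + 1L, jo + 1L, , drop = FALSE]
  )
  y <- views[[1]]
  idx <- array(1L, dim(y))
  for (k in 2:4) {
    m <- views[[k]] > y     # strict: ties resolved to the earliest view
    y[m] <- views[[k]][m]
    idx[m] <- k
  }
  list(out = y, idx = idx, in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  io <- seq(1L, d[1], by = 2L)
  jo <- seq(1L, d[2], by = 2L)
  offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    m <- cache$idx == k
    if (!any(m)) next
    sub <- array(0, dim(dy))
    sub[m] <- dy[m]
    ii <- io + offs[[k]][1]
    jj <- jo + offs[[k]][2]
    dx[ii, jj, ] <- dx[ii, jj, , drop = FALSE] + sub
  }
  dx
}
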