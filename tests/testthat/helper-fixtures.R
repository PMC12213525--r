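## Shared fixtures: everything is generated in code, nothing on disk.

tiny_backbone <- function(seed = 1) build_backbone("tiny-random", seed = seed)

rand_image <- function(n, seed = 1) {
  with_local_seed(seed, matrix(stats::runif(n * n), n, n))
}

## seeded evaluation that restores the caller's RNG stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

## the reduced desk-scale schedule used by the phantom studies
small_schedule <- function(Niter = 3L) {
  rnst_config(N0 = 20L, Nstep = 10L, Nstyle = 2L, Nline = 3L, Niter = Niter,
              mu = 0.1, lam = 0.3)
}

## independent brute-force oracles -----------------------------------------

gram_oracle <- function(f) {
  n <- nrow(f)
  g <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      for (k in seq_len(ncol(f))) g[i, j] <- g[i, j] + f[i, k] * f[j, k]
    }
  }
  g
}

content_loss_oracle <- function(fx, fc, norm) {
  tot <- 0
  for (i in seq_len(nrow(fx))) {
    for (j in seq_len(ncol(fx))) {
      d <- fx[i, j] - fc[i, j]
      tot <- tot + if (norm == "l2") 0.5 * d^2 else 0.5 * abs(d)
    }
  }
  tot
}

style_loss_layer_oracle <- function(gx, gs, n_l, m_l, norm) {
  tot <- 0
  for (i in seq_len(nrow(gx))) {
    for (j in seq_len(ncol(gx))) {
      d <- gx[i, j] - gs[i, j]
      tot <- tot + if (norm == "l2") d^2 else abs(d)
    }
  }
  tot / (4 * n_l^2 * m_l^2)
}

## windowed SSIM recomputed per window with stats::var/cov (unbiased), the
## reference the fast integral-image implementation must match
ssim_oracle <- function(x, y, w = 7L, k1 = 0.01, k2 = 0.03, L = 1) {
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  vals <- c()
  for (i in seq_len(nrow(x) - w + 1L)) {
    for (j in seq_len(ncol(x) - w + 1L)) {
      px <- as.vector(x[i:(i + w - 1L), j:(j + w - 1L)])
      py <- as.vector(y[i:(i + w - 1L), j:(j + w - 1L)])
      mx <- mean(px); my <- mean(py)
      vals <- c(vals,
                ((2 * mx * my + c1) * (2 * stats::cov(px, py) + c2)) /
                  ((mx^2 + my^2 + c1) * (stats::var(px) + stats::var(py) + c2)))
    }
  }
  mean(vals)
}
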