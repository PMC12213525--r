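#' Block-matching 3-D collaborative filtering denoiser
#'
#' Self-contained implementation of the hard-thresholding stage of the
#' classical block-matching and 3-D filtering (BM3D) scheme: for every
#' reference block on a coarse grid, the most similar blocks inside a local
#' search window are stacked into a 3-D group; the group is taken to a
#' separable orthonormal transform domain (2-D DCT over the block, 1-D DCT
#' along the stack), hard-thresholded at `2.7 * sigma`, inverted, and the
#' filtered blocks are aggregated back with inverse-sparsity weights.
#'
#' @param image numeric matrix in `[0, 1]`, at least `block` pixels on each
#'   side.
#' @param sigma assumed noise standard deviation on the `[0, 1]` scale.
#' @param block block side length (default 8).
#' @param step reference-block grid stride (default 3).
#' @param search_radius half-width of the block-matching search window in
#'   pixels (default 12).
#' @param max_group maximum number of blocks per group (default 16).
#' @return The denoised image (same shape; not clamped — [denoise()] clamps).
#' @export
bm3d <- function(image, sigma = 20 / 255, block = 8L, step = 3L,
                 search_radius = 12L, max_group = 16L) {
  check_image(image)
  check_scalar(sigma, "sigma", 0, strict = TRUE)
  h <- nrow(image); w <- ncol(image)
  if (h < block || w < block) {
    stop_rnst("image must be at least ", block, "x", block,
              class = "rnst_shape_error")
  }
  nb_i <- h - block + 1L
  nb_j <- w - block + 1L

  ## all blocks, column-major over top-left positions, as rows of length
  ## block^2; one matmul takes every block to the 2-D DCT domain
  nb <- nb_i * nb_j
  blocks <- matrix(0, nb, block * block)
  p <- 1L
  for (dj in 0:(block - 1L)) {
    for (di in 0:(block - 1L)) {
      blocks[, p] <- image[di + seq_len(nb_i), dj + seq_len(nb_j)]
      p <- p + 1L
    }
  }
  t2 <- dct_matrix(block)
  k2 <- t2 %x% t2                 # vec(T B T') = (T (x) T) vec(B)
  dblocks <- blocks %*% t(k2)

  ref_i <- unique(c(seq(1L, nb_i, by = step), nb_i))
  ref_j <- unique(c(seq(1L, nb_j, by = step), nb_j))
  thr <- 2.7 * sigma
  dct1 <- lapply(seq_len(max_group), dct_matrix)

  n_inst <- 0L
  est <- vector("list", length(ref_i) * length(ref_j))
  wts <- numeric(length(est))
  rows_of <- vector("list", length(est))
  g <- 0L
  for (rj in ref_j) {
    cj <- max(1L, rj - search_radius):min(nb_j, rj + search_radius)
    off_j <- (cj - 1L) * nb_i
    for (ri in ref_i) {
      ci <- max(1L, ri - search_radius):min(nb_i, ri + search_radius)
      cand <- as.vector(outer(ci, off_j, "+"))
      ref_row <- (rj - 1L) * nb_i + ri
      d2 <- rowSums((dblocks[cand, , drop = FALSE] -
                       matrix(dblocks[ref_row, ], length(cand),
                              ncol(dblocks), byrow = TRUE))^2)
      k <- min(max_group, length(cand))
      ## the reference block always leads its own group (guarantees full
      ## pixel coverage even when all distances tie)
      sel <- unique(c(ref_row, cand[order(d2)]))[seq_len(k)]
      grp <- dct1[[k]] %*% dblocks[sel, , drop = FALSE]
      keep <- abs(grp) >= thr
      grp[!keep] <- 0
      n_kept <- max(1L, sum(keep))
      g <- g + 1L
      est[[g]] <- (t(dct1[[k]]) %*% grp) %*% k2   # back to pixel domain
      wts[g] <- 1 / n_kept
      rows_of[[g]] <- sel
      n_inst <- n_inst + k
    }
  }

  ## overlap-add aggregation with per-group weights
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  all_rows <- unlist(rows_of[seq_len(g)])
  all_w <- rep(wts[seq_len(g)],
               vapply(rows_of[seq_len(g)], length, 1L))
  all_est <- do.call(rbind, est[seq_len(g)])
  pos_i <- (all_rows - 1L) %% nb_i + 1L
  pos_j <- (all_rows - 1L) %/% nb_i + 1L
  p <- 1L
  for (dj in 0:(block - 1L)) {
    for (di in 0:(block - 1L)) {
      lin <- (pos_j + dj - 1L) * h + (pos_i + di)
      acc_n <- rowsum(all_w * all_est[, p], lin)
      acc_d <- rowsum(all_w, lin)
      ii <- as.integer(rownames(acc_n))
      num[ii] <- num[ii] + acc_n[, 1L]
      den[ii] <- den[ii] + acc_d[, 1L]
      p <- p + 1L
    }
  }
  num / den
}

## Orthonormal DCT-II matrix of order n.
dct_matrix <- function(n) {
  if (n == 1L) return(matrix(1, 1L, 1L))
  i <- matrix(0:(n - 1L), n, n)
  j <- t(i)
  m <- sqrt(2 / n) * cos(pi * i * (2 * j + 1) / (2 * n))
  m[1L, ] <- sqrt(1 / n)
  m
}
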