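#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10( max(x_ref)^2 / MSE(x_hat, x_ref) )` in decibels,
#' with the peak taken over the reference image (set `peak` to override,
#' e.g. `peak = 1` for a fixed dynamic range). Identical images give `Inf`.
#'
#' @param x_hat reconstructed image.
#' @param x_ref reference image, same shape.
#' @param peak optional fixed peak value; default `max(x_ref)`.
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0.1, 4, 4), matrix(0.2, 4, 4))  # 10*log10(0.2^2/0.01)
#' @export
psnr <- function(x_hat, x_ref, peak = NULL) {
  check_image(x_hat, "x_hat", require_range = FALSE)
  check_image(x_ref, "x_ref", require_range = FALSE)
  check_same_shape(x_hat, x_ref)
  mse <- mean((x_hat - x_ref)^2)
  if (mse == 0) return(Inf)
  if (is.null(peak)) peak <- max(x_ref)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index
#'
#' Mean SSIM over all fully-interior sliding windows ("valid" mode): for
#' each `window x window` patch,
#' `SSIM = (2 mu_x mu_y + c1)(2 cov_xy + c2) /
#'         ((mu_x^2 + mu_y^2 + c1)(var_x + var_y + c2))`
#' with `c1 = (k1 L)^2`, `c2 = (k2 L)^2`. Windows are unweighted (uniform)
#' by default; variances and covariance use the unbiased `n - 1`
#' normalization. A Gaussian-weighted mode (`gaussian = TRUE`, sd 1.5) is
#' available.
#'
#' @param x_hat,x_ref images of the same shape, both dimensions `>= window`.
#' @param window odd window side (default 7).
#' @param k1,k2 stabilization constants (defaults 0.01, 0.03).
#' @param dynamic_range dynamic range `L` of the pixel values (default 1
#'   for `[0,1]` images; use 255 for 8-bit).
#' @param gaussian use an 11-point Gaussian-weighted window instead of the
#'   uniform one.
#' @return SSIM in `[-1, 1]`; exactly 1 for identical images.
#' @export
ssim <- function(x_hat, x_ref, window = 7L, k1 = 0.01, k2 = 0.03,
                 dynamic_range = 1, gaussian = FALSE) {
  check_image(x_hat, "x_hat", require_range = FALSE)
  check_image(x_ref, "x_ref", require_range = FALSE)
  check_same_shape(x_hat, x_ref)
  if (min(dim(x_ref)) < window) {
    stop_rnst("image smaller than the ", window, "x", window, " SSIM window",
              class = "rnst_validation_error")
  }
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  if (gaussian) {
    r <- (window - 1L) %/% 2L
    k1d <- stats::dnorm(-r:r, sd = 1.5)
    wk <- outer(k1d, k1d)
    wk <- wk / sum(wk)
    wsum <- function(z) filter2_valid(z, wk)
    mu_x <- wsum(x_hat); mu_y <- wsum(x_ref)
    vx <- wsum(x_hat^2) - mu_x^2
    vy <- wsum(x_ref^2) - mu_y^2
    cxy <- wsum(x_hat * x_ref) - mu_x * mu_y
  } else {
    n <- window^2
    s <- function(z) box_sum_valid(z, window)
    sx <- s(x_hat); sy <- s(x_ref)
    mu_x <- sx / n; mu_y <- sy / n
    vx <- (s(x_hat^2) - sx^2 / n) / (n - 1)
    vy <- (s(x_ref^2) - sy^2 / n) / (n - 1)
    cxy <- (s(x_hat * x_ref) - sx * sy / n) / (n - 1)
  }
  map <- ((2 * mu_x * mu_y + c1) * (2 * cxy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (vx + vy + c2))
  mean(map)
}

## Sliding-window sums over all valid positions via an integral image.
box_sum_valid <- function(x, w) {
  n1 <- nrow(x); n2 <- ncol(x)
  s <- rbind(0, apply(x, 2L, cumsum))
  s <- cbind(0, t(apply(s, 1L, cumsum)))
  io <- seq_len(n1 - w + 1L)
  jo <- seq_len(n2 - w + 1L)
  s[io + w, jo + w, drop = FALSE] - s[io, jo + w, drop = FALSE] -
    s[io + w, jo, drop = FALSE] + s[io, jo, drop = FALSE]
}

## Valid-mode correlation with an arbitrary kernel (small kernels only).
filter2_valid <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  n1 <- nrow(x) - kh + 1L
  n2 <- ncol(x) - kw + 1L
  out <- matrix(0, n1, n2)
  for (dj in 0:(kw - 1L)) {
    for (di in 0:(kh - 1L)) {
      out <- out + k[di + 1L, dj + 1L] *
        x[di + seq_len(n1), dj + seq_len(n2)]
    }
  }
  out
}

#' Image-quality report
#'
#' Convenience wrapper computing both [psnr()] and [ssim()] with the
#' evaluation defaults (7x7 uniform window, `k1 = 0.01`, `k2 = 0.03`).
#'
#' @inheritParams ssim
#' @return A list of class `metrics_report` with `psnr_db`, `ssim`, and the
#'   SSIM settings used.
#' @export
metrics_report <- function(x_hat, x_ref, window = 7L, k1 = 0.01, k2 = 0.03,
                           dynamic_range = 1) {
  structure(list(
    psnr_db = psnr(x_hat, x_ref),
    ssim = ssim(x_hat, x_ref, window, k1, k2, dynamic_range),
    window = window, k1 = k1, k2 = k2, dynamic_range = dynamic_range
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("PSNR: %.2f dB | SSIM: %.4f (window %dx%d, k1=%g, k2=%g, L=%g)\n",
              x$psnr_db, x$ssim, x$window, x$window, x$k1, x$k2,
              x$dynamic_range))
  invisible(x)
}
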