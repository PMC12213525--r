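#' Denoiser specification
#'
#' The reconstruction algorithm's regularizer is built from a pluggable,
#' stateless denoising engine `D`: the update pulls the iterate toward
#' `D(x)` with weight `lambda` (regularization-by-denoising). Supported
#' engines:
#'
#' * `"bm3d"`: collaborative filtering of matched block stacks in a 3-D
#'   transform domain (hard-thresholding stage; see [bm3d()]); `sigma` is
#'   the assumed noise standard deviation on the `[0,1]` scale.
#' * `"gaussian"`: separable Gaussian smoothing, reflect-padded; `kernel`
#'   is the standard deviation in pixels (default 0.5: light smoothing that
#'   trades noise suppression against edge blur on structure-rich images).
#' * `"median"`: square median filter, reflect-padded; `kernel` is the odd
#'   window width (default 3).
#' * `"identity"`: returns the input unchanged.
#'
#' @param name one of `"bm3d"`, `"gaussian"`, `"median"`, `"identity"`.
#' @param sigma assumed noise sd for `"bm3d"` (default `20/255`).
#' @param kernel width parameter for `"gaussian"` / `"median"`.
#' @return An object of class `denoiser_spec`.
#' @export
denoiser_spec <- function(name = c("bm3d", "gaussian", "median", "identity"),
                          sigma = 20 / 255, kernel = NULL) {
  choices <- c("bm3d", "gaussian", "median", "identity")
  if (identical(name, choices)) name <- "bm3d"
  if (!is.character(name) || length(name) != 1L || !name %in% choices) {
    stop_rnst("unknown denoiser '", paste(name, collapse = ","),
              "'; supported: ", paste(choices, collapse = ", "),
              class = "rnst_config_error")
  }
  if (name == "bm3d") check_scalar(sigma, "sigma", 0, strict = TRUE)
  if (is.null(kernel)) kernel <- switch(name, gaussian = 0.5, median = 3L, NULL)
  if (name == "median") {
    if (kernel < 1 || kernel %% 2 != 1) {
      stop_rnst("median kernel must be odd and >= 1",
                class = "rnst_config_error")
    }
  }
  if (name == "gaussian") check_scalar(kernel, "kernel", 0, strict = TRUE)
  structure(list(name = name, sigma = sigma, kernel = kernel),
            class = "denoiser_spec")
}

#' Apply a denoiser to an image
#'
#' Stateless and deterministic: the same image and spec always give the
#' bit-identical output. Output has the same shape and is clamped to
#' `[0, 1]`.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param spec a [denoiser_spec()].
#' @return The denoised image.
#' @export
denoise <- function(image, spec = denoiser_spec()) {
  stopifnot(inherits(spec, "denoiser_spec"))
  check_image(image)
  out <- switch(spec$name,
    identity = return(image),
    gaussian = gaussian_blur(image, spec$kernel),
    median = median_filter(image, as.integer(spec$kernel)),
    bm3d = bm3d(image, spec$sigma)
  )
  clamp01(out)
}

reflect_pad <- function(x, r) {
  n1 <- nrow(x); n2 <- ncol(x)
  if (r >= n1 || r >= n2) {
    stop_rnst("image too small for filter radius ", r,
              class = "rnst_shape_error")
  }
  ri <- c(rev(seq_len(r) + 1L), seq_len(n1), n1 - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(n2), n2 - seq_len(r))
  x[ri, ci, drop = FALSE]
}

## Separable Gaussian smoothing with reflect boundary (avoids the dark-frame
## bias a zero boundary would feed into the reconstruction residual).
gaussian_blur <- function(x, sd) {
  r <- max(1L, ceiling(3 * sd))
  k <- stats::dnorm(-r:r, sd = sd)
  k <- k / sum(k)
  xp <- reflect_pad(x, r)
  ## convolve rows then columns via banded crossprods
  n1 <- nrow(x); n2 <- ncol(x)
  a <- matrix(0, n1, nrow(xp))
  for (i in seq_len(n1)) a[i, i:(i + 2L * r)] <- k
  b <- matrix(0, ncol(xp), n2)
  for (j in seq_len(n2)) b[j:(j + 2L * r), j] <- k
  a %*% xp %*% b
}

median_filter <- function(x, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(x)
  xp <- reflect_pad(x, r)
  n1 <- nrow(x); n2 <- ncol(x)
  patches <- matrix(0, n1 * n2, k * k)
  p <- 1L
  for (dj in 0:(k - 1L)) {
    for (di in 0:(k - 1L)) {
      patches[, p] <- xp[di + seq_len(n1), dj + seq_len(n2)]
      p <- p + 1L
    }
  }
  matrix(apply(patches, 1L, stats::median), n1, n2)
}
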