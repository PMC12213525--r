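#' Phantom specification
#'
#' Parameters of the synthetic paired low-field/high-field study images.
#' A "high-field" phantom is a brain-like composition of a head ellipse and
#' nested internal ellipses at the given tissue intensities on a dark
#' background; its "low-field" counterpart applies a strictly monotone
#' contrast remap `gain * x^gamma` (emulating the field-dependent contrast
#' shift) followed by seeded additive white Gaussian noise of standard
#' deviation `noise_sigma` and clamping. The defaults reproduce the study
#' corruption level `sigma = 20/255` (about 0.08 on the `[0,1]` scale) with
#' a moderate contrast shift (`gain = 0.9`, `gamma = 1.3`).
#'
#' @param size square image side in pixels (default 64; `>= 32`).
#' @param n_ellipses total number of ellipses including the head outline
#'   (`>= 1`).
#' @param tissue_levels intensities in `[0, 1]`; the first is the head
#'   level, the rest are cycled over internal structures.
#' @param gain,gamma monotone low-field contrast remap `gain * x^gamma`.
#' @param noise_sigma AWGN standard deviation on the `[0,1]` scale.
#' @param seed integer controlling geometry and noise; generation is fully
#'   deterministic given the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 64L, n_ellipses = 6L,
                         tissue_levels = c(0.65, 0.30, 0.45, 0.80, 0.55),
                         gain = 0.9, gamma = 1.3,
                         noise_sigma = 20 / 255, seed = 1L) {
  if (size < 32) stop_rnst("size must be >= 32", class = "rnst_config_error")
  if (n_ellipses < 1) {
    stop_rnst("n_ellipses must be >= 1", class = "rnst_config_error")
  }
  if (any(tissue_levels < 0 | tissue_levels > 1)) {
    stop_rnst("tissue_levels must lie in [0, 1]", class = "rnst_config_error")
  }
  if (noise_sigma < 0) {
    stop_rnst("noise_sigma must be >= 0", class = "rnst_validation_error")
  }
  check_scalar(gain, "gain", 0, strict = TRUE)
  check_scalar(gamma, "gamma", 0, strict = TRUE)
  structure(list(size = as.integer(size), n_ellipses = as.integer(n_ellipses),
                 tissue_levels = tissue_levels, gain = gain, gamma = gamma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

## Ellipse table (center, semi-axes, angle, level) for a spec; the first row
## is the head outline, later rows are internal structures constrained to
## fall inside the head (redrawn up to 20 times, then an error).
phantom_ellipses <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  s <- spec$size
  lv <- spec$tissue_levels
  with_seed(spec$seed, {
    head <- c(cx = s / 2 + stats::runif(1, -0.02, 0.02) * s,
              cy = s / 2 + stats::runif(1, -0.02, 0.02) * s,
              a = stats::runif(1, 0.33, 0.38) * s,
              b = stats::runif(1, 0.38, 0.44) * s,
              theta = stats::runif(1, -0.15, 0.15),
              level = lv[1])
    rows <- list(head)
    if (spec$n_ellipses > 1L) {
      for (k in 2:spec$n_ellipses) {
        lev <- if (length(lv) > 1) lv[-1][(k - 2L) %% (length(lv) - 1L) + 1L]
               else lv[1]
        ok <- FALSE
        for (try in 1:20) {
          e <- c(cx = head["cx"] + stats::runif(1, -0.18, 0.18) * s,
                 cy = head["cy"] + stats::runif(1, -0.18, 0.18) * s,
                 a = stats::runif(1, 0.05, 0.18) * s,
                 b = stats::runif(1, 0.05, 0.18) * s,
                 theta = stats::runif(1, -pi, pi),
                 level = lev)
          names(e) <- names(head)
          ## accept if the ellipse's bounding radius stays inside the head
          r <- max(e["a"], e["b"])
          u <- (e["cx"] - head["cx"]) / (head["a"] - r)
          v <- (e["cy"] - head["cy"]) / (head["b"] - r)
          if (head["a"] > r && head["b"] > r && u^2 + v^2 <= 1) {
            ok <- TRUE
            break
          }
        }
        if (!ok) {
          stop_rnst("could not place internal ellipse ", k,
                    " after 20 attempts", class = "rnst_config_error")
        }
        rows[[k]] <- e
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a high-field-like phantom image
#'
#' Rasterizes the seeded ellipse composition of `spec` (see
#' [phantom_spec()]); deterministic per seed. Later ellipses paint over
#' earlier ones, and internal structures are clipped to the head.
#'
#' @param spec a [phantom_spec()].
#' @return A `size x size` image matrix in `[0, 1]`.
#' @examples
#' img <- make_phantom(phantom_spec(size = 64, seed = 3))
#' range(img)
#' @export
make_phantom <- function(spec) {
  ell <- phantom_ellipses(spec)
  s <- spec$size
  gx <- matrix(rep(seq_len(s) - 0.5, s), s, s)          # row coordinate
  gy <- matrix(rep(seq_len(s) - 0.5, each = s), s, s)   # column coordinate
  img <- matrix(0, s, s)
  head_mask <- NULL
  for (r in seq_len(nrow(ell))) {
    e <- ell[r, ]
    dx <- gx - e["cx"]; dy <- gy - e["cy"]
    ct <- cos(e["theta"]); st <- sin(e["theta"])
    m <- ((dx * ct + dy * st) / e["a"])^2 +
      ((-dx * st + dy * ct) / e["b"])^2 <= 1
    if (r == 1L) head_mask <- m else m <- m & head_mask
    img[m] <- e["level"]
  }
  img
}

#' Degrade a high-field image to a low-field-like acquisition
#'
#' Applies the monotone contrast remap `gain * x^gamma`, adds seeded
#' additive white Gaussian noise of sd `noise_sigma`, and clamps to
#' `[0, 1]`. The noise stream is derived from `spec$seed` but independent
#' of the geometry stream, so the same anatomy can be re-noised by changing
#' the seed.
#'
#' @param image image matrix in `[0, 1]`.
#' @param spec a [phantom_spec()] supplying `gain`, `gamma`, `noise_sigma`,
#'   `seed`.
#' @return The degraded image.
#' @export
degrade_to_lowfield <- function(image, spec) {
  check_image(image)
  stopifnot(inherits(spec, "phantom_spec"))
  out <- spec$gain * image^spec$gamma
  if (spec$noise_sigma > 0) {
    noise <- with_seed(spec$seed + 77003L,
                       stats::rnorm(length(out), sd = spec$noise_sigma))
    out <- out + matrix(noise, nrow(out), ncol(out))
  }
  clamp01(out)
}

#' Generate a content/guidance/reference phantom triple
#'
#' Emulates the field-transfer study setup: `clean_reference` is the
#' high-field phantom for `spec$seed`; `content` is its low-field
#' degradation (the reconstruction input); `guidance` is a clean high-field
#' phantom supplying the style. In `"frozen"` mode (default) the guidance
#' uses `seed + 1`, i.e. different anatomy with the same contrast
#' characteristics — the condition where guidance content and input content
#' do not match. In `"matched"` mode the guidance shares the input's seed
#' (same anatomy).
#'
#' @param spec a [phantom_spec()].
#' @param mode `"frozen"` or `"matched"` guidance.
#' @return A list with elements `content`, `guidance`, `clean_reference`,
#'   and `mode`.
#' @export
make_pair <- function(spec, mode = c("frozen", "matched")) {
  mode <- match.arg(mode)
  clean <- make_phantom(spec)
  content <- degrade_to_lowfield(clean, spec)
  guidance <- if (mode == "frozen") {
    sp2 <- spec
    sp2$seed <- spec$seed + 1L
    make_phantom(sp2)
  } else {
    clean
  }
  list(content = content, guidance = guidance, clean_reference = clean,
       mode = mode)
}
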