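#' Build a frozen feature-extraction backbone
#'
#' The style-transfer engine reads features from a frozen convolutional
#' network. Four backbones are supported:
#'
#' * `"tiny-random"`: a small 4-layer stack of 3x3 stride-1 convolutions
#'   (8 maps each, ReLU, zero biases) whose weights are drawn
#'   deterministically from `seed`. It needs no downloaded weights, so it is
#'   the backbone every offline test and phantom study runs on. Style taps:
#'   all four layers; content tap: layer 2.
#' * `"vgg16"`: style taps at the first eight convolutional layers
#'   (`conv1_1` ... `conv4_1`, post-ReLU), content tap at the fourth
#'   (`conv2_2`). Extraction requires pretrained weights supplied via
#'   `weights` (see Details); none are bundled.
#' * `"resnet50"` / `"resnet152"`: style taps at the initial 7x7 convolution
#'   and residual stages 1-3; content taps at the 7x7 convolution and stages
#'   1 and 3. Tap metadata only: extraction raises an error directing you to
#'   `tiny-random` because no offline weight source exists for these graphs.
#'
#' All taps are post-nonlinearity activations. Weights are never updated by
#' any operation in this package; `backbone_checksum()` lets tests assert
#' that.
#'
#' @details For `"vgg16"`, `weights` is the path to an RDS file holding a
#'   named list (names `conv1_1`, `conv1_2`, ...) of
#'   `list(weight = <kh x kw x c_in x c_out array>, bias = <numeric c_out>)`.
#'   Grayscale slices are replicated to three channels and normalized with
#'   the ImageNet constants before entering pretrained stems; `tiny-random`
#'   consumes the \[0,1\] image directly.
#'
#' @param name one of `"vgg16"`, `"resnet50"`, `"resnet152"`, `"tiny-random"`.
#' @param seed integer; required for (and only for) `"tiny-random"`.
#' @param weights optional path to a weights RDS file (`"vgg16"` only).
#' @param style_taps,content_taps optional character vectors overriding the
#'   default tap layers.
#' @return An object of class `feature_backbone`.
#' @examples
#' b <- build_backbone("tiny-random", seed = 7)
#' length(b$style_taps)   # 4
#' @export
build_backbone <- function(name, seed = NULL, weights = NULL,
                           style_taps = NULL, content_taps = NULL) {
  if (!is.character(name) || length(name) != 1L) {
    stop_rnst("backbone name must be a single string",
              class = "rnst_config_error")
  }
  b <- switch(name,
    "tiny-random" = {
      if (is.null(seed)) {
        stop_rnst("tiny-random backbone requires a seed",
                  class = "rnst_config_error")
      }
      backbone_tiny_random(as.integer(seed))
    },
    "vgg16" = backbone_vgg16(weights),
    "resnet50" = backbone_resnet(name, n_total_layers = 50L),
    "resnet152" = backbone_resnet(name, n_total_layers = 152L),
    stop_rnst("unknown backbone '", name, "'; supported: vgg16, resnet50, ",
              "resnet152, tiny-random", class = "rnst_config_error")
  )
  if (!identical(name, "tiny-random") && !is.null(seed)) {
    stop_rnst("seed is only meaningful for the tiny-random backbone",
              class = "rnst_config_error")
  }
  layer_ids <- vapply(b$layers, `[[`, "", "id")
  if (is.null(layer_ids) || length(layer_ids) == 0L) layer_ids <- b$tap_ids
  if (!is.null(style_taps)) b$style_taps <- style_taps
  if (!is.null(content_taps)) b$content_taps <- content_taps
  known <- if (length(b$layers)) layer_ids else b$tap_ids
  bad <- setdiff(c(b$style_taps, b$content_taps), known)
  if (length(bad)) {
    stop_rnst("unknown tap layer(s): ", paste(bad, collapse = ", "),
              class = "rnst_config_error")
  }
  if (length(b$style_taps) == 0L || length(b$content_taps) == 0L) {
    stop_rnst("style_taps and content_taps must be non-empty",
              class = "rnst_config_error")
  }
  b$frozen <- TRUE
  class(b) <- "feature_backbone"
  b
}

conv_layer <- function(id, c_in, c_out, k = 3L) {
  list(id = id, type = "conv", c_in = c_in, c_out = c_out, k = k,
       weight = NULL, bias = NULL)
}

pool_layer <- function(id) list(id = id, type = "pool")

backbone_tiny_random <- function(seed) {
  channels <- c(8L, 8L, 8L, 8L)
  c_in <- 1L
  layers <- list()
  with_seed(seed, {
    for (i in seq_along(channels)) {
      l <- conv_layer(paste0("conv", i), c_in, channels[i])
      ## He-scaled draws keep activation magnitudes of order the input's
      l$weight <- array(stats::rnorm(9L * c_in * channels[i],
                                     sd = sqrt(2 / (9 * c_in))),
                        c(3L, 3L, c_in, channels[i]))
      l$bias <- rep(0, channels[i])
      layers[[i]] <- l
      c_in <- channels[i]
    }
  })
  list(name = "tiny-random", seed = seed, layers = layers,
       style_taps = paste0("conv", 1:4), content_taps = "conv2",
       input_channels = 1L, normalize = NULL, min_size = 16L,
       executable = TRUE)
}

vgg16_plan <- function() {
  ## (id, c_out) for the convolutional trunk; pools between blocks
  list(
    conv_layer("conv1_1", 3L, 64L), conv_layer("conv1_2", 64L, 64L),
    pool_layer("pool1"),
    conv_layer("conv2_1", 64L, 128L), conv_layer("conv2_2", 128L, 128L),
    pool_layer("pool2"),
    conv_layer("conv3_1", 128L, 256L), conv_layer("conv3_2", 256L, 256L),
    conv_layer("conv3_3", 256L, 256L),
    pool_layer("pool3"),
    conv_layer("conv4_1", 256L, 512L), conv_layer("conv4_2", 512L, 512L),
    conv_layer("conv4_3", 512L, 512L),
    pool_layer("pool4"),
    conv_layer("conv5_1", 512L, 512L), conv_layer("conv5_2", 512L, 512L),
    conv_layer("conv5_3", 512L, 512L)
  )
}

backbone_vgg16 <- function(weights_path) {
  layers <- vgg16_plan()
  have_weights <- FALSE
  if (!is.null(weights_path)) {
    if (!file.exists(weights_path)) {
      stop_rnst("weights file not found: ", weights_path,
                class = "rnst_config_error")
    }
    wl <- readRDS(weights_path)
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type != "conv") next
      if (is.null(wl[[l$id]])) {
        stop_rnst("weights file lacks layer '", l$id, "'",
                  class = "rnst_config_error")
      }
      w <- wl[[l$id]]$weight
      b <- wl[[l$id]]$bias
      if (!identical(dim(w), c(l$k, l$k, l$c_in, l$c_out)) ||
          length(b) != l$c_out) {
        stop_rnst("layer '", l$id, "' weights have wrong shape; expected ",
                  l$k, "x", l$k, "x", l$c_in, "x", l$c_out,
                  class = "rnst_config_error")
      }
      layers[[i]]$weight <- w
      layers[[i]]$bias <- as.numeric(b)
    }
    have_weights <- TRUE
  }
  list(name = "vgg16", seed = NULL, layers = layers,
       style_taps = c("conv1_1", "conv1_2", "conv2_1", "conv2_2",
                      "conv3_1", "conv3_2", "conv3_3", "conv4_1"),
       content_taps = "conv2_2",
       input_channels = 3L,
       normalize = list(mean = c(0.485, 0.456, 0.406),
                        sd = c(0.229, 0.224, 0.225)),
       min_size = 32L, executable = have_weights)
}

backbone_resnet <- function(name, n_total_layers) {
  ## Tap metadata per the residual-network reading: style from the 7x7 stem
  ## convolution and bottleneck stages 1-3, content from the stem and
  ## stages 1 and 3. No offline weight source exists for these graphs, so
  ## extraction is not executable; build succeeds so configurations can be
  ## inspected and presets resolved.
  list(name = name, seed = NULL, layers = list(),
       tap_ids = c("conv1", "stage1", "stage2", "stage3"),
       style_taps = c("conv1", "stage1", "stage2", "stage3"),
       content_taps = c("conv1", "stage1", "stage3"),
       input_channels = 3L,
       normalize = list(mean = c(0.485, 0.456, 0.406),
                        sd = c(0.229, 0.224, 0.225)),
       min_size = 32L, executable = FALSE, depth = n_total_layers)
}

#' Checksum of a backbone's parameters
#'
#' A cheap numeric signature (sum, sum of squares, parameter count) of all
#' weights and biases. Extraction and style-transfer runs must leave it
#' unchanged: the backbone is frozen.
#'
#' @param backbone a `feature_backbone`.
#' @return Named numeric vector `c(sum =, sumsq =, n =)`.
#' @export
backbone_checksum <- function(backbone) {
  stopifnot(inherits(backbone, "feature_backbone"))
  s <- 0; s2 <- 0; n <- 0
  for (l in backbone$layers) {
    if (!identical(l$type, "conv") || is.null(l$weight)) next
    v <- c(as.numeric(l$weight), l$bias)
    s <- s + sum(v); s2 <- s2 + sum(v^2); n <- n + length(v)
  }
  c(sum = s, sumsq = s2, n = n)
}

#' @export
print.feature_backbone <- function(x, ...) {
  cat("<feature_backbone>", x$name,
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")") else "",
      "\n  style taps:  ", paste(x$style_taps, collapse = ", "),
      "\n  content taps:", paste(x$content_taps, collapse = ", "),
      "\n  executable:  ", x$executable,
      " | min input: ", x$min_size, "x", x$min_size, "\n")
  invisible(x)
}
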