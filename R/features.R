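## Forward/backward execution of a backbone and the public feature surface.

prep_input <- function(image, backbone, require_range = TRUE) {
  check_image(image, require_range = require_range)
  d <- dim(image)
  if (min(d) < backbone$min_size) {
    stop_rnst("image ", d[1], "x", d[2], " is smaller than the '",
              backbone$name, "' backbone's minimum input size ",
              backbone$min_size, "x", backbone$min_size,
              class = "rnst_shape_error")
  }
  if (backbone$input_channels == 1L) {
    array(image, c(d, 1L))
  } else {
    ## replicate the gray channel, then apply the backbone's native
    ## training normalization so pretrained features stay in calibration
    x <- array(image, c(d, 3L))
    for (c in 1:3) {
      x[, , c] <- (x[, , c] - backbone$normalize$mean[c]) /
        backbone$normalize$sd[c]
    }
    x
  }
}

grad_unprep <- function(dx, backbone) {
  if (backbone$input_channels == 1L) {
    matrix(dx[, , 1L], dim(dx)[1], dim(dx)[2])
  } else {
    g <- matrix(0, dim(dx)[1], dim(dx)[2])
    for (c in 1:3) g <- g + dx[, , c] / backbone$normalize$sd[c]
    g
  }
}

check_executable <- function(backbone) {
  if (!isTRUE(backbone$executable)) {
    stop_rnst("pretrained weights for '", backbone$name, "' are not ",
              "available offline; supply a weights file (vgg16) or use ",
              "build_backbone(\"tiny-random\", seed = ...)",
              class = "rnst_config_error")
  }
}

## Forward pass caching every post-activation the backward pass needs.
## `upto`: index of the deepest layer that must be evaluated.
backbone_forward <- function(image, backbone, upto = length(backbone$layers),
                             require_range = TRUE) {
  check_executable(backbone)
  x <- prep_input(image, backbone, require_range)
  acts <- vector("list", upto)
  caches <- vector("list", upto)
  cur <- x
  for (i in seq_len(upto)) {
    l <- backbone$layers[[i]]
    if (l$type == "conv") {
      cur <- relu(conv_forward(cur, l$weight, l$bias))
    } else {
      pc <- maxpool_forward(cur)
      cur <- pc$out
      caches[[i]] <- pc
    }
    acts[[i]] <- cur
  }
  names(acts) <- vapply(backbone$layers[seq_len(upto)], `[[`, "", "id")
  list(input = x, acts = acts, caches = caches, upto = upto)
}

deepest_layer_index <- function(backbone, taps) {
  ids <- vapply(backbone$layers, `[[`, "", "id")
  max(match(taps, ids))
}

## dL/d(input image) from per-tap gradients dL/d(activation).
backbone_backward <- function(fw, backbone, tap_grads) {
  ids <- vapply(backbone$layers[seq_len(fw$upto)], `[[`, "", "id")
  start <- max(match(names(tap_grads), ids))
  d <- array(0, dim(fw$acts[[start]]))
  for (i in seq(start, 1L)) {
    l <- backbone$layers[[i]]
    tg <- tap_grads[[l$id]]
    if (!is.null(tg)) d <- d + tg
    if (l$type == "conv") {
      d <- relu_backward(d, fw$acts[[i]])
      d <- conv_backward_input(d, l$weight)
    } else {
      d <- maxpool_backward(d, fw$caches[[i]])
    }
  }
  grad_unprep(d, backbone)
}

## Flatten an (H, W, C) activation into the N_l x M_l feature matrix
## (row i = feature map i over the M_l = H*W spatial positions).
act_to_fmat <- function(a) {
  d <- dim(a)
  f <- t(matrix(a, d[1] * d[2], d[3]))
  attr(f, "spatial_dim") <- d[1:2]
  f
}

fmat_grad_to_act <- function(df, d3) {
  array(t(df), d3)
}

#' Extract multi-layer feature matrices from a frozen backbone
#'
#' Runs the image through the backbone and returns, for each requested tap
#' layer, the feature matrix `F` of shape `N_l x M_l` (`N_l` feature maps,
#' each flattened over the `M_l` spatial positions). Extraction is
#' deterministic and leaves the backbone untouched.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param backbone a [build_backbone()] object.
#' @param which `"style"` or `"content"`: which tap set to extract.
#' @return A named list of feature matrices (class `feature_map_set`); each
#'   element carries its layer's spatial dimensions as an attribute.
#' @examples
#' b <- build_backbone("tiny-random", seed = 1)
#' fs <- extract_features(matrix(0.5, 32, 32), b, "style")
#' dim(fs$conv1)   # 8 x 1024
#' @export
extract_features <- function(image, backbone, which = c("style", "content")) {
  which <- match.arg(which)
  stopifnot(inherits(backbone, "feature_backbone"))
  taps <- if (which == "style") backbone$style_taps else backbone$content_taps
  fw <- backbone_forward(image, backbone,
                         upto = deepest_layer_index(backbone, taps))
  out <- lapply(fw$acts[taps], act_to_fmat)
  structure(out, class = "feature_map_set", which = which)
}
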