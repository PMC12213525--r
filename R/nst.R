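#' Neural style transfer configuration
#'
#' Holds the loss weights and inner-optimization settings of the style
#' transfer engine. The total loss is
#' `alpha * L_content + beta * L_style`, where the content loss compares
#' feature maps at the backbone's content taps and the style loss compares
#' Gram matrices at its style taps. Only the ratio `alpha/beta` matters for
#' the descent direction; the backbone presets use the ratios 1e-6 (vgg16)
#' and 1e-4 (resnet) with `beta = 1`, see [default_nst_config()].
#'
#' @param alpha content-loss weight, `>= 0`.
#' @param beta style-loss weight, `>= 0` (not both zero).
#' @param norm `"l1"` (default) or `"l2"`: both the content and style losses
#'   use absolute instead of squared differences in `"l1"` mode, keeping the
#'   same prefactors. The subgradient of `|.|` at 0 is taken as 0.
#' @param layer_weights optional per-style-layer weights `w_l >= 0`
#'   (default: uniform `1/n_style_taps`).
#' @param inner_steps number of pixel-space descent steps `N` of the inner
#'   optimizer.
#' @param optimizer `"ngd"` (RMS-normalized stateless gradient descent,
#'   default), `"gd"` (plain fixed step), or `"adam"`.
#' @param step_size descent step in intensity units per inner step for
#'   `"ngd"` (default 0.02, i.e. 2% of the dynamic range), raw step for the
#'   others.
#' @param clamp clamp pixels to `[0, 1]` after every inner step (default on).
#' @return An object of class `nst_config`.
#' @export
nst_config <- function(alpha = 1e-4, beta = 1, norm = c("l1", "l2"),
                       layer_weights = NULL, inner_steps = 100L,
                       optimizer = c("ngd", "gd", "adam"),
                       step_size = 0.02, clamp = TRUE) {
  norm <- match.arg(norm)
  optimizer <- match.arg(optimizer)
  check_scalar(alpha, "alpha", 0)
  check_scalar(beta, "beta", 0)
  if (alpha == 0 && beta == 0) {
    stop_rnst("alpha and beta cannot both be zero",
              class = "rnst_config_error")
  }
  if (!is.null(layer_weights)) {
    if (any(layer_weights < 0) || sum(layer_weights) <= 0) {
      stop_rnst("layer_weights must be >= 0 with positive sum",
                class = "rnst_config_error")
    }
  }
  if (!is.numeric(inner_steps) || inner_steps < 1) {
    stop_rnst("inner_steps must be >= 1", class = "rnst_config_error")
  }
  check_scalar(step_size, "step_size", 0, strict = TRUE)
  structure(list(alpha = alpha, beta = beta, norm = norm,
                 layer_weights = layer_weights,
                 inner_steps = as.integer(inner_steps),
                 optimizer = optimizer, step_size = step_size,
                 clamp = isTRUE(clamp)),
            class = "nst_config")
}

#' Default style-transfer configuration for a backbone
#'
#' Applies the per-backbone content/style weight ratios: `alpha/beta = 1e-6`
#' for vgg16 and `1e-4` for the resnets (with `beta = 1`). For tiny-random
#' the ratio is `1e-9`, chosen so that the L1 content and style gradient
#' magnitudes are commensurate given that backbone's small map count
#' (`N_l = 8`) and the `1/(4 N_l^2 M_l^2)` style prefactor (see the methods
#' vignette for the derivation).
#'
#' @param backbone a [build_backbone()] object.
#' @param ... overrides passed on to [nst_config()].
#' @return An `nst_config`.
#' @export
default_nst_config <- function(backbone, ...) {
  ratio <- switch(backbone$name,
                  "vgg16" = 1e-6,
                  "resnet50" = , "resnet152" = 1e-4,
                  "tiny-random" = 1e-9)
  args <- list(...)
  if (is.null(args$alpha)) args$alpha <- ratio
  if (is.null(args$beta)) args$beta <- 1
  do.call(nst_config, args)
}

#' Gram matrix of a layer's feature maps
#'
#' `G[i, j] = sum_k F[i, k] * F[j, k]`: the inner products between feature
#' maps, whose entries encode the feature co-activation statistics ("style")
#' of the layer. Always symmetric positive semi-definite.
#'
#' @param f an `N_l x M_l` feature matrix (one row per feature map).
#' @return The `N_l x N_l` Gram matrix.
#' @export
gram_matrix <- function(f) {
  if (!is.matrix(f) || !is.numeric(f) || nrow(f) < 1L || ncol(f) < 1L) {
    stop_rnst("feature matrix must be a non-empty numeric matrix",
              class = "rnst_validation_error")
  }
  if (any(!is.finite(f))) {
    stop_rnst("feature matrix contains non-finite values",
              class = "rnst_validation_error")
  }
  tcrossprod(f)
}

as_fmat_list <- function(f) {
  if (is.matrix(f)) list(layer = f) else unclass(f)
}

#' Content loss between two feature representations
#'
#' `1/2 * sum((F - F_c)^2)` (`norm = "l2"`) or `1/2 * sum(|F - F_c|)`
#' (`"l1"`), summed over all supplied content-tap layers.
#'
#' @param f_x,f_c feature sets from [extract_features()] (or single feature
#'   matrices) with matching layers and shapes.
#' @param norm `"l2"` or `"l1"`.
#' @return Nonnegative scalar.
#' @export
content_loss <- function(f_x, f_c, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  f_x <- as_fmat_list(f_x); f_c <- as_fmat_list(f_c)
  if (!identical(names(f_x), names(f_c))) {
    stop_rnst("feature sets have different layers",
              class = "rnst_validation_error")
  }
  tot <- 0
  for (l in seq_along(f_x)) {
    check_same_shape(f_x[[l]], f_c[[l]], "feature matrices")
    d <- f_x[[l]] - f_c[[l]]
    tot <- tot + if (norm == "l2") 0.5 * sum(d^2) else 0.5 * sum(abs(d))
  }
  tot
}

#' Single-layer style loss between two Gram matrices
#'
#' `1/(4 N_l^2 M_l^2) * sum((G - G_s)^2)` in `"l2"` mode; absolute
#' differences with the same prefactor in `"l1"` mode.
#'
#' @param g_x,g_s `N_l x N_l` Gram matrices.
#' @param n_l number of feature maps of the layer.
#' @param m_l number of spatial positions of the layer.
#' @param norm `"l2"` or `"l1"`.
#' @return Nonnegative scalar.
#' @export
style_loss_layer <- function(g_x, g_s, n_l, m_l, norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  check_same_shape(g_x, g_s, "Gram matrices")
  d <- g_x - g_s
  pre <- 1 / (4 * n_l^2 * m_l^2)
  if (norm == "l2") pre * sum(d^2) else pre * sum(abs(d))
}

resolve_layer_weights <- function(w, n) {
  if (is.null(w)) rep(1 / n, n)
  else if (length(w) != n) {
    stop_rnst("layer_weights has length ", length(w), " but there are ", n,
              " style taps", class = "rnst_config_error")
  } else w
}

#' Multi-layer style loss
#'
#' Weighted sum over style-tap layers of [style_loss_layer()] applied to the
#' Gram matrices of the two feature sets.
#'
#' @param features_x,features_s style feature sets from [extract_features()].
#' @param layer_weights per-layer weights `w_l` (default uniform `1/L`).
#' @param norm `"l2"` or `"l1"`.
#' @return Nonnegative scalar.
#' @export
style_loss <- function(features_x, features_s, layer_weights = NULL,
                       norm = c("l2", "l1")) {
  norm <- match.arg(norm)
  f_x <- as_fmat_list(features_x); f_s <- as_fmat_list(features_s)
  if (!identical(names(f_x), names(f_s))) {
    stop_rnst("feature sets have different layers",
              class = "rnst_validation_error")
  }
  w <- resolve_layer_weights(layer_weights, length(f_x))
  tot <- 0
  for (l in seq_along(f_x)) {
    tot <- tot + w[l] * style_loss_layer(
      gram_matrix(f_x[[l]]), gram_matrix(f_s[[l]]),
      nrow(f_x[[l]]), ncol(f_x[[l]]), norm
    )
  }
  tot
}

## ---- internal optimization context --------------------------------------
##
## Precomputes the fixed targets of a style-transfer problem (style Grams of
## the guidance image, content features of the anchor) so the inner loop and
## the line-search evaluator never re-extract them.

nst_context <- function(backbone, style_image, content_image = NULL,
                        config = default_nst_config(backbone)) {
  taps <- union(backbone$style_taps, backbone$content_taps)
  upto <- deepest_layer_index(backbone, taps)
  fw_s <- backbone_forward(style_image, backbone,
                           upto = deepest_layer_index(backbone,
                                                      backbone$style_taps))
  g_s <- list(); nl <- list(); ml <- list()
  for (id in backbone$style_taps) {
    f <- act_to_fmat(fw_s$acts[[id]])
    g_s[[id]] <- tcrossprod(f)
    nl[[id]] <- nrow(f); ml[[id]] <- ncol(f)
  }
  ctx <- list(backbone = backbone, config = config, upto = upto,
              g_s = g_s, n_l = nl, m_l = ml,
              w_l = resolve_layer_weights(config$layer_weights,
                                          length(backbone$style_taps)),
              f_c = NULL)
  if (!is.null(content_image)) ctx <- set_content_anchor(ctx, content_image)
  ctx
}

set_content_anchor <- function(ctx, content_image) {
  b <- ctx$backbone
  fw_c <- backbone_forward(content_image, b,
                           upto = deepest_layer_index(b, b$content_taps))
  ctx$f_c <- lapply(fw_c$acts[b$content_taps], act_to_fmat)
  ctx
}

## Loss (and optionally its pixel gradient) of image x under the context.
nst_loss_grad <- function(x, ctx, grad = TRUE) {
  b <- ctx$backbone
  cfg <- ctx$config
  ## unclamped inner iterates may leave [0,1]; only finiteness is required
  ## here — the public extraction surface stays strict
  fw <- backbone_forward(x, b, upto = ctx$upto, require_range = FALSE)
  tap_grads <- list()
  l_content <- 0
  for (id in b$content_taps) {
    f <- act_to_fmat(fw$acts[[id]])
    d <- f - ctx$f_c[[id]]
    if (cfg$norm == "l2") {
      l_content <- l_content + 0.5 * sum(d^2)
      df <- d
    } else {
      l_content <- l_content + 0.5 * sum(abs(d))
      df <- 0.5 * sign(d)
    }
    if (grad && cfg$alpha > 0) {
      tap_grads[[id]] <- fmat_grad_to_act(cfg$alpha * df,
                                          dim(fw$acts[[id]]))
    }
  }
  l_style <- 0
  for (i in seq_along(b$style_taps)) {
    id <- b$style_taps[i]
    f <- act_to_fmat(fw$acts[[id]])
    g <- tcrossprod(f)
    dg <- g - ctx$g_s[[id]]
    pre <- ctx$w_l[i] / (4 * ctx$n_l[[id]]^2 * ctx$m_l[[id]]^2)
    if (cfg$norm == "l2") {
      l_style <- l_style + pre * sum(dg^2)
      dG <- 2 * pre * dg
    } else {
      l_style <- l_style + pre * sum(abs(dg))
      dG <- pre * sign(dg)
    }
    if (grad && cfg$beta > 0) {
      ## G = F F^T with symmetric dL/dG  =>  dL/dF = 2 * (dL/dG) F
      df <- cfg$beta * 2 * (dG %*% f)
      prev <- tap_grads[[id]]
      a <- fmat_grad_to_act(df, dim(fw$acts[[id]]))
      tap_grads[[id]] <- if (is.null(prev)) a else prev + a
    }
  }
  loss <- cfg$alpha * l_content + cfg$beta * l_style
  out <- list(loss = loss, content = l_content, style = l_style)
  if (grad) {
    out$grad <- if (length(tap_grads)) {
      backbone_backward(fw, b, tap_grads)
    } else {
      matrix(0, nrow(x), ncol(x))
    }
  }
  out
}

## Stateless/stateful descent on pixels; the engine behind run_nst and the
## candidate generator.
nst_descend <- function(x, ctx, steps) {
  cfg <- ctx$config
  m <- NULL; v <- NULL
  for (it in seq_len(steps)) {
    lg <- nst_loss_grad(x, ctx)
    if (!is.finite(lg$loss)) {
      stop_rnst("non-finite style-transfer loss at inner step ", it,
                class = "rnst_numeric_error")
    }
    g <- lg$grad
    step <- switch(cfg$optimizer,
      gd = cfg$step_size * g,
      ngd = {
        r <- sqrt(mean(g^2))
        if (r > 0) cfg$step_size * g / r else g * 0
      },
      adam = {
        if (is.null(m)) { m <- g * 0; v <- g * 0 }
        m <- 0.9 * m + 0.1 * g
        v <- 0.999 * v + 0.001 * g^2
        mh <- m / (1 - 0.9^it)
        vh <- v / (1 - 0.999^it)
        cfg$step_size * mh / (sqrt(vh) + 1e-8)
      })
    x <- x - step
    if (cfg$clamp) x <- clamp01(x)
  }
  x
}

#' Total style-transfer loss of an image
#'
#' `alpha * L_content(x, x_c) + beta * L_style(x, x_s)` with features
#' extracted at the backbone's configured taps.
#'
#' @param x,x_c,x_s input, content, and style images (matrices in `[0,1]`).
#' @param backbone a [build_backbone()] object.
#' @param config an [nst_config()].
#' @return Scalar loss.
#' @export
total_loss <- function(x, x_c, x_s, backbone,
                       config = default_nst_config(backbone)) {
  ctx <- nst_context(backbone, x_s, x_c, config)
  nst_loss_grad(x, ctx, grad = FALSE)$loss
}

#' Run the inner style-transfer optimization
#'
#' Starting from the content image, performs `config$inner_steps` descent
#' steps on the pixels minimizing [total_loss()] against the fixed content
#' anchor (the starting image) and style guidance. This is the map
#' `T_N(x, x_guid)` that the outer reconstruction algorithm calls at several
#' depths `N`. Deterministic given inputs and configuration; with the
#' default stateless optimizer, `T_N` composed with `T_M` equals
#' `T_(N+M)`.
#'
#' @param content content image (also the initialization).
#' @param style style guidance image.
#' @param backbone a [build_backbone()] object.
#' @param config an [nst_config()]; `inner_steps` sets `N`.
#' @return The stylized image (matrix in `[0,1]` when clamping is on).
#' @export
run_nst <- function(content, style, backbone,
                    config = default_nst_config(backbone)) {
  check_image(content, "content")
  check_image(style, "style")
  ctx <- nst_context(backbone, style, content, config)
  nst_descend(content, ctx, config$inner_steps)
}
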