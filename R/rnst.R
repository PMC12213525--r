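#' Outer reconstruction configuration
#'
#' Hyperparameters of the line-search reconstruction loop. Each outer
#' iteration (i) denoises the current iterate, (ii) generates `Nstyle`
#' style-transferred candidates at depths `N0, N0 + Nstep, ...`, (iii) forms
#' an update for every (depth, step-size) combination with step sizes
#' `mu_i = i * mu`, `i = 1..Nline`, (iv) scores every update with the
#' one-step style-transfer loss, and keeps the best. The printed defaults
#' are `N0 = 500`, `Nstep = 100`, `Nstyle = 3`, `Nline = 5`; see
#' [rnst_preset()] for the per-study `Niter`/`mu`/`lambda` combinations.
#'
#' @param N0 initial style-transfer depth (`>= 1`).
#' @param Nstep depth increment per candidate (`>= 0`).
#' @param Nstyle number of depth candidates (`>= 1`).
#' @param Nline number of line-search step sizes (`>= 1`).
#' @param Niter outer iterations (`>= 1`).
#' @param mu base step size (`> 0`); candidate step sizes are `i * mu`.
#' @param lam denoising weight `lambda >= 0` on the `x - D(x)` residual.
#' @param alpha,beta evaluation-loss weights; default to the style-transfer
#'   engine's `alpha`/`beta` when `NULL`.
#' @param include_identity_candidate also score the unchanged iterate; keeps
#'   the winning evaluation loss non-increasing across iterations (default
#'   on; the identity loses ties).
#' @param denoise_every_iteration denoise the current iterate each outer
#'   iteration (default) rather than the initial input once.
#' @param refresh_candidates_every_iteration regenerate the style-transfer
#'   candidates from the current iterate each outer iteration (default)
#'   rather than freezing the first candidate list.
#' @return An object of class `rnst_config`.
#' @export
rnst_config <- function(N0 = 500L, Nstep = 100L, Nstyle = 3L, Nline = 5L,
                        Niter = 10L, mu = 0.1, lam = 0.3,
                        alpha = NULL, beta = NULL,
                        include_identity_candidate = TRUE,
                        denoise_every_iteration = TRUE,
                        refresh_candidates_every_iteration = TRUE) {
  for (nm in c("N0", "Nstyle", "Nline", "Niter")) {
    v <- get(nm)
    if (!is.numeric(v) || v < 1) {
      stop_rnst(nm, " must be >= 1", class = "rnst_config_error")
    }
  }
  if (Nstep < 0) stop_rnst("Nstep must be >= 0", class = "rnst_config_error")
  check_scalar(mu, "mu", 0, strict = TRUE)
  check_scalar(lam, "lam", 0)
  structure(list(N0 = as.integer(N0), Nstep = as.integer(Nstep),
                 Nstyle = as.integer(Nstyle), Nline = as.integer(Nline),
                 Niter = as.integer(Niter), mu = mu, lam = lam,
                 alpha = alpha, beta = beta,
                 include_identity_candidate = isTRUE(include_identity_candidate),
                 denoise_every_iteration = isTRUE(denoise_every_iteration),
                 refresh_candidates_every_iteration =
                   isTRUE(refresh_candidates_every_iteration)),
            class = "rnst_config")
}

#' Generate the style-transfer candidate directions
#'
#' Candidate `k` (`k = 0 .. Nstyle-1`) is the style transfer of `x` at
#' depth `N0 + k * Nstep`, i.e. `run_nst` with
#' `inner_steps = N0 + k * Nstep`, in depth order.
#'
#' @param x current iterate.
#' @param x_guid style guidance image.
#' @param backbone a [build_backbone()] object.
#' @param nst_cfg an [nst_config()].
#' @param rnst_cfg an [rnst_config()] supplying `N0`, `Nstep`, `Nstyle`.
#' @return List of `Nstyle` images, with the depths as attribute `"depths"`.
#' @export
build_candidate_directions <- function(x, x_guid, backbone, nst_cfg,
                                       rnst_cfg) {
  depths <- rnst_cfg$N0 + (seq_len(rnst_cfg$Nstyle) - 1L) * rnst_cfg$Nstep
  ctx <- nst_context(backbone, x_guid, x, nst_cfg)
  out <- vector("list", length(depths))
  ## with a stateless inner optimizer T_{N+M} = T_M o T_N, so each deeper
  ## candidate continues from the previous instead of restarting
  stateless <- nst_cfg$optimizer %in% c("gd", "ngd")
  cur <- x
  done <- 0L
  for (k in seq_along(depths)) {
    if (stateless) {
      cur <- nst_descend(cur, ctx, depths[k] - done)
      done <- depths[k]
      out[[k]] <- cur
    } else {
      out[[k]] <- nst_descend(x, ctx, depths[k])
    }
  }
  attr(out, "depths") <- depths
  out
}

#' Form a candidate update (gradient-direction step)
#'
#' `x_new = clamp( x - mu_tilde * ((x - x_t) + lam * (x - x_d)) )`:
#' a step along the combined style-transfer and denoising residuals.
#'
#' @param x current iterate.
#' @param x_t a style-transferred candidate direction.
#' @param x_d the denoised image.
#' @param mu_tilde step size `>= 0`.
#' @param lam denoising weight `>= 0`.
#' @return The updated image, clamped to `[0, 1]`.
#' @examples
#' candidate_update(matrix(0.5), matrix(0.7), matrix(0.6), 0.5, 0.3)  # 0.615
#' @export
candidate_update <- function(x, x_t, x_d, mu_tilde, lam) {
  check_same_shape(x, x_t)
  check_same_shape(x, x_d)
  check_scalar(mu_tilde, "mu_tilde", 0)
  check_scalar(lam, "lam", 0)
  clamp01(x - mu_tilde * ((x - x_t) + lam * (x - x_d)))
}

#' Score a candidate with the one-step style-transfer loss
#'
#' Applies a single inner style-transfer step to the candidate,
#' `x' = T_1(x_tilde, x_guid)`, then returns
#' `alpha * L_content(x', x_in) + beta * L_style(x', x_guid)`. The content
#' anchor is the original input `x_in`, not the current iterate.
#'
#' @param x_tilde candidate image.
#' @param x_in the original reconstruction input.
#' @param x_guid style guidance image.
#' @param backbone a [build_backbone()] object.
#' @param alpha,beta evaluation-loss weights.
#' @param norm `"l1"` or `"l2"`.
#' @param nst_cfg optional [nst_config()] controlling the single inner step
#'   (optimizer/step size); weights/norm are taken from the arguments.
#' @return Scalar evaluation loss.
#' @export
evaluate_candidate <- function(x_tilde, x_in, x_guid, backbone,
                               alpha, beta, norm = c("l1", "l2"),
                               nst_cfg = NULL) {
  norm <- match.arg(norm)
  if (is.null(nst_cfg)) nst_cfg <- default_nst_config(backbone)
  cfg <- nst_cfg
  cfg$alpha <- alpha; cfg$beta <- beta; cfg$norm <- norm
  ctx <- nst_context(backbone, x_guid, config = cfg)
  eval_ctx <- set_content_anchor(ctx, x_in)
  evaluate_candidate_ctx(x_tilde, eval_ctx)
}

## same, against a prebuilt context (style Grams of x_guid, content anchor
## x_in) — the hot path of the line search
evaluate_candidate_ctx <- function(x_tilde, eval_ctx) {
  step_ctx <- eval_ctx
  step_ctx <- set_content_anchor(step_ctx, x_tilde)
  x1 <- nst_descend(x_tilde, step_ctx, 1L)
  nst_loss_grad(x1, eval_ctx, grad = FALSE)$loss
}

## ---- the outer loop ------------------------------------------------------

rnst_eval_weights <- function(nst_cfg, rnst_cfg) {
  list(alpha = if (is.null(rnst_cfg$alpha)) nst_cfg$alpha else rnst_cfg$alpha,
       beta = if (is.null(rnst_cfg$beta)) nst_cfg$beta else rnst_cfg$beta)
}

#' One outer reconstruction iteration
#'
#' Denoises, generates candidate directions, forms every (depth, step-size)
#' update, scores each with the one-step evaluation loss, and returns the
#' best candidate together with the full score record. Ties are broken
#' toward the smallest (depth index, step index); the identity candidate
#' (if enabled) loses ties.
#'
#' @param x current iterate.
#' @param x_in original input (content anchor of the evaluation loss).
#' @param x_guid style guidance.
#' @param backbone a [build_backbone()] object.
#' @param denoiser a [denoiser_spec()].
#' @param nst_cfg an [nst_config()].
#' @param rnst_cfg an [rnst_config()].
#' @param state optional internal state carried across iterations (cached
#'   contexts, frozen candidates, once-denoised input).
#' @return A list with `x` (the winner), `record` (indices and losses), and
#'   `state`.
#' @export
rnst_iterate <- function(x, x_in, x_guid, backbone, denoiser, nst_cfg,
                         rnst_cfg, state = NULL) {
  if (is.null(state)) {
    eval_ctx <- nst_context(backbone, x_guid, config = nst_cfg)
    w <- rnst_eval_weights(nst_cfg, rnst_cfg)
    eval_ctx$config$alpha <- w$alpha
    eval_ctx$config$beta <- w$beta
    eval_ctx <- set_content_anchor(eval_ctx, x_in)
    state <- list(eval_ctx = eval_ctx, candidates = NULL, x_d_in = NULL)
  }

  x_d <- if (rnst_cfg$denoise_every_iteration) {
    denoise(x, denoiser)
  } else {
    if (is.null(state$x_d_in)) state$x_d_in <- denoise(x_in, denoiser)
    state$x_d_in
  }

  if (rnst_cfg$refresh_candidates_every_iteration || is.null(state$candidates)) {
    cands <- build_candidate_directions(x, x_guid, backbone, nst_cfg,
                                        rnst_cfg)
    if (!rnst_cfg$refresh_candidates_every_iteration) state$candidates <- cands
  } else {
    cands <- state$candidates
  }

  losses <- matrix(NA_real_, rnst_cfg$Nstyle, rnst_cfg$Nline)
  best <- NULL
  best_loss <- Inf
  best_idx <- c(NA_integer_, NA_integer_)
  for (k in seq_len(rnst_cfg$Nstyle)) {
    for (i in seq_len(rnst_cfg$Nline)) {
      xt <- candidate_update(x, cands[[k]], x_d, i * rnst_cfg$mu,
                             rnst_cfg$lam)
      l <- evaluate_candidate_ctx(xt, state$eval_ctx)
      losses[k, i] <- l
      if (is.finite(l) && l < best_loss) {
        best <- xt; best_loss <- l; best_idx <- c(k, i)
      }
    }
  }
  identity_loss <- NA_real_
  if (rnst_cfg$include_identity_candidate) {
    identity_loss <- evaluate_candidate_ctx(x, state$eval_ctx)
    if (is.finite(identity_loss) && identity_loss < best_loss) {
      best <- x; best_loss <- identity_loss; best_idx <- c(NA_integer_,
                                                           NA_integer_)
    }
  }
  if (is.null(best)) {
    cond <- errorCondition(
      "all candidate evaluation losses are non-finite",
      losses = losses, class = c("rnst_numeric_error", "rnst_error"))
    stop(cond)
  }
  record <- list(depth_index = best_idx[1], step_index = best_idx[2],
                 winner_loss = best_loss, candidate_losses = losses,
                 identity_loss = identity_loss)
  list(x = best, record = record, state = state)
}

#' Field-transfer reconstruction by style transfer with denoising
#'
#' Runs the full iterative reconstruction: `Niter` outer iterations of
#' [rnst_iterate()], threading the winning candidate forward while the
#' original input stays fixed as the content anchor of the evaluation loss.
#' Fully deterministic given inputs and configurations.
#'
#' @param x_in noisy lower-field input image (matrix in `[0,1]`).
#' @param x_guid higher-field style guidance image.
#' @param backbone a [build_backbone()] object.
#' @param denoiser a [denoiser_spec()] (default bm3d at sigma 20/255).
#' @param nst_cfg an [nst_config()] (default [default_nst_config()] of the
#'   backbone).
#' @param rnst_cfg an [rnst_config()].
#' @param reference optional clean reference image; when supplied the trace
#'   records per-iteration PSNR/SSIM against it.
#' @param keep_iterates store the iterate entering each outer iteration in
#'   the trace (used by replay checks).
#' @return An object of class `rnst_result`: `final_image`, `trace` (one
#'   record per outer iteration), and `config_echo`.
#' @examples
#' \donttest{
#' b <- build_backbone("tiny-random", seed = 1)
#' pair <- make_pair(phantom_spec(size = 64, seed = 2))
#' res <- run_rnst(pair$content, pair$guidance, b,
#'                 denoiser_spec("gaussian"),
#'                 rnst_cfg = rnst_config(N0 = 20, Nstep = 10, Nstyle = 2,
#'                                        Nline = 3, Niter = 3))
#' psnr(res$final_image, pair$clean_reference)
#' }
#' @export
run_rnst <- function(x_in, x_guid, backbone,
                     denoiser = denoiser_spec(),
                     nst_cfg = default_nst_config(backbone),
                     rnst_cfg = rnst_config(),
                     reference = NULL, keep_iterates = FALSE) {
  check_image(x_in, "x_in")
  check_image(x_guid, "x_guid")
  x <- x_in
  trace <- vector("list", rnst_cfg$Niter)
  state <- NULL
  for (it in seq_len(rnst_cfg$Niter)) {
    if (keep_iterates) x_before <- x
    step <- rnst_iterate(x, x_in, x_guid, backbone, denoiser, nst_cfg,
                         rnst_cfg, state)
    x <- step$x
    state <- step$state
    rec <- step$record
    rec$iteration <- it
    if (keep_iterates) rec$x_before <- x_before
    if (!is.null(reference)) {
      rec$psnr <- psnr(x, reference)
      rec$ssim <- ssim(x, reference)
    }
    trace[[it]] <- rec
  }
  structure(list(final_image = x, trace = trace,
                 config_echo = list(nst = nst_cfg, rnst = rnst_cfg,
                                    denoiser = denoiser,
                                    backbone = backbone$name,
                                    backbone_seed = backbone$seed)),
            class = "rnst_result")
}

#' @export
print.rnst_result <- function(x, ...) {
  n <- length(x$trace)
  wl <- vapply(x$trace, `[[`, 0, "winner_loss")
  cat("<rnst_result> ", nrow(x$final_image), "x", ncol(x$final_image),
      " image, ", n, " outer iteration(s)\n", sep = "")
  cat("  winner evaluation loss: ",
      paste(signif(wl, 4), collapse = " -> "), "\n", sep = "")
  if (!is.null(x$trace[[n]]$psnr)) {
    cat(sprintf("  final PSNR %.2f dB, SSIM %.4f vs reference\n",
                x$trace[[n]]$psnr, x$trace[[n]]$ssim))
  }
  invisible(x)
}

#' Named hyperparameter presets
#'
#' Printed per-study settings: all share `N0 = 500`, `Nstep = 100`,
#' `Nstyle = 3`, `Nline = 5` and a bm3d denoiser at sigma `20/255`.
#'
#' * `nacc-vgg16`: vgg16, `Niter = 30`, `mu = 0.1`, `lambda = 0.3`.
#' * `nacc-resnet`: resnet50, `Niter = 10`, `mu = 0.1`, `lambda = 0.3`.
#' * `tse-vgg16`: vgg16, `Niter = 10`, `mu = 0.13`, `lambda = 0.2`.
#' * `tse-vgg16-noisy`: vgg16, `Niter = 50`, `mu = 0.15`, `lambda = 0.3`.
#' * `tse-resnet`: resnet50, `Niter = 30`, `mu = 0.12`, `lambda = 0.2`.
#'
#' @param name preset name.
#' @return List with `backbone_name`, `nst` ([nst_config()]), `rnst`
#'   ([rnst_config()]), `denoiser` ([denoiser_spec()]).
#' @export
rnst_preset <- function(name = c("nacc-vgg16", "nacc-resnet", "tse-vgg16",
                                 "tse-vgg16-noisy", "tse-resnet")) {
  name <- match.arg(name)
  p <- switch(name,
    "nacc-vgg16" = list(bb = "vgg16", Niter = 30L, mu = 0.10, lam = 0.3),
    "nacc-resnet" = list(bb = "resnet50", Niter = 10L, mu = 0.10, lam = 0.3),
    "tse-vgg16" = list(bb = "vgg16", Niter = 10L, mu = 0.13, lam = 0.2),
    "tse-vgg16-noisy" = list(bb = "vgg16", Niter = 50L, mu = 0.15, lam = 0.3),
    "tse-resnet" = list(bb = "resnet50", Niter = 30L, mu = 0.12, lam = 0.2)
  )
  ratio <- if (p$bb == "vgg16") 1e-6 else 1e-4
  list(backbone_name = p$bb,
       nst = nst_config(alpha = ratio, beta = 1),
       rnst = rnst_config(N0 = 500L, Nstep = 100L, Nstyle = 3L, Nline = 5L,
                          Niter = p$Niter, mu = p$mu, lam = p$lam),
       denoiser = denoiser_spec("bm3d", sigma = 20 / 255))
}
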