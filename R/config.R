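#' Load a run configuration from a YAML file
#'
#' Resolves the nested keys of a run configuration into the package's
#' objects. Recognized sections and keys:
#'
#' * `backbone`: `name`, `seed`, `weights`, `style_taps`, `content_taps`
#' * `nst`: `alpha`, `beta`, `norm`, `layer_weights`, and `inner` with
#'   `optimizer`, `step_size`, `steps`, `clamp`
#' * `rnst`: `N0`, `Nstep`, `Nstyle`, `Nline`, `Niter`, `mu`, `lambda`
#'   (or `lam`), `include_identity_candidate`, `denoise_every_iteration`,
#'   `refresh_candidates_every_iteration`
#' * `denoiser`: `name`, `sigma`, `kernel`
#' * `preset`: a [rnst_preset()] name supplying defaults that explicit
#'   sections then override
#'
#' @param path path to a YAML file.
#' @return A list with `backbone` (a `feature_backbone`), `nst_cfg`,
#'   `rnst_cfg`, and `denoiser`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop_rnst("config file not found: ", path, class = "rnst_config_error")
  }
  y <- yaml::read_yaml(path)
  base <- if (!is.null(y$preset)) rnst_preset(y$preset) else NULL

  bb <- y$backbone
  backbone_name <- bb$name %||% base$backbone_name %||% "tiny-random"
  backbone <- build_backbone(
    backbone_name,
    seed = if (identical(backbone_name, "tiny-random")) bb$seed %||% 1L,
    weights = bb$weights,
    style_taps = unlist(bb$style_taps),
    content_taps = unlist(bb$content_taps)
  )

  nst_cfg <- base$nst %||% default_nst_config(backbone)
  n <- y$nst
  if (!is.null(n)) {
    for (k in c("alpha", "beta", "norm", "layer_weights")) {
      if (!is.null(n[[k]])) nst_cfg[[k]] <- n[[k]]
    }
    if (!is.null(n$inner)) {
      if (!is.null(n$inner$optimizer)) nst_cfg$optimizer <- n$inner$optimizer
      if (!is.null(n$inner$step_size)) nst_cfg$step_size <- n$inner$step_size
      if (!is.null(n$inner$steps)) nst_cfg$inner_steps <- n$inner$steps
      if (!is.null(n$inner$clamp)) nst_cfg$clamp <- isTRUE(n$inner$clamp)
    }
    nst_cfg <- do.call(nst_config, unclass(nst_cfg))   # re-validate
  }

  rnst_cfg <- base$rnst %||% rnst_config()
  r <- y$rnst
  if (!is.null(r)) {
    if (!is.null(r[["lambda"]]) && is.null(r[["lam"]])) {
      r[["lam"]] <- r[["lambda"]]
    }
    for (k in intersect(names(r), names(formals(rnst_config)))) {
      rnst_cfg[[k]] <- r[[k]]
    }
    rnst_cfg <- do.call(rnst_config, unclass(rnst_cfg))
  }

  den <- base$denoiser %||% denoiser_spec()
  d <- y$denoiser
  if (!is.null(d)) {
    den <- denoiser_spec(d$name %||% den$name,
                         sigma = d$sigma %||% den$sigma %||% 20 / 255,
                         kernel = d$kernel %||% den$kernel)
  }

  list(backbone = backbone, nst_cfg = nst_cfg, rnst_cfg = rnst_cfg,
       denoiser = den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
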