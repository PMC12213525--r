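#' Normalize raw intensities to the unit interval
#'
#' `"minmax"` maps the observed `[min, max]` to `[0, 1]`; `"percentile"`
#' (the default used when loading scans) maps the `[p_low, p_high]`
#' percentile range to `[0, 1]` and clips, which is robust to the extreme
#' outlier voxels MRI volumes routinely contain.
#'
#' @param image numeric matrix of raw intensities.
#' @param method `"percentile"` or `"minmax"`.
#' @param p_low,p_high percentile bounds (defaults 0.5 and 99.5).
#' @return Matrix in `[0, 1]`.
#' @examples
#' normalize_intensity(matrix(c(0, 5, 10, 10), 2), "minmax")
#' @export
normalize_intensity <- function(image, method = c("percentile", "minmax"),
                                p_low = 0.5, p_high = 99.5) {
  method <- match.arg(method)
  check_image(image, require_range = FALSE)
  if (method == "minmax") {
    lo <- min(image); hi <- max(image)
    if (hi <= lo) {
      stop_rnst("constant image cannot be min-max normalized; use ",
                "method = \"percentile\" with explicit bounds",
                class = "rnst_validation_error")
    }
  } else {
    q <- stats::quantile(image, c(p_low, p_high) / 100, names = FALSE)
    lo <- q[1]; hi <- q[2]
    if (hi <= lo) {
      stop_rnst("degenerate percentile range [", p_low, ", ", p_high, "]",
                class = "rnst_validation_error")
    }
  }
  clamp01((image - lo) / (hi - lo))
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop_rnst("unsupported raster format '.", ext, "'",
              class = "rnst_config_error")
  )
  if (length(dim(img)) == 3L) {
    ## collapse color / drop alpha: average the color channels
    img <- apply(img[, , seq_len(min(3L, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  img
}

is_nifti_path <- function(path) {
  grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
}

#' Load a 2-D slice from a NIfTI volume or raster file
#'
#' NIfTI volumes are reoriented to RAS using their stored orientation
#' metadata, then sliced: `"axial"` fixes the superior axis, `"coronal"`
#' the anterior axis, `"sagittal"` the left-right axis. 2-D rasters
#' (PNG/TIFF) are returned whole (`slice_index` ignored). The slice is
#' normalized to `[0, 1]` with [normalize_intensity()].
#'
#' @param path path to a `.nii`/`.nii.gz` volume or a PNG/TIFF raster.
#' @param slice_index 1-based slice index along the chosen axis.
#' @param axis `"axial"`, `"coronal"`, or `"sagittal"`.
#' @param normalize normalization method passed to [normalize_intensity()],
#'   or `"none"` for data already in `[0, 1]`.
#' @param p_low,p_high percentile bounds for `normalize = "percentile"`.
#' @return A 2-D image matrix in `[0, 1]`.
#' @export
load_slice <- function(path, slice_index = 1L,
                       axis = c("axial", "coronal", "sagittal"),
                       normalize = c("percentile", "minmax", "none"),
                       p_low = 0.5, p_high = 99.5) {
  axis <- match.arg(axis)
  normalize <- match.arg(normalize)
  if (!file.exists(path)) {
    stop_rnst("file not found: ", path, class = "rnst_config_error")
  }
  if (is_nifti_path(path)) {
    vol <- RNifti::readNifti(path)
    nd <- length(dim(vol))
    if (nd > 3L) {
      stop_rnst("4-D volume: pre-select a 3-D volume before slicing",
                class = "rnst_validation_error")
    }
    if (nd != 3L) {
      stop_rnst("expected a 3-D NIfTI volume, got ", nd, "-D",
                class = "rnst_validation_error")
    }
    hdr <- RNifti::niftiHeader(vol)
    if (hdr$qform_code > 0 || hdr$sform_code > 0) {
      ## resolve axes through the stored orientation, never raw array order
      RNifti::orientation(vol) <- "RAS"
    }
    ax <- switch(axis, sagittal = 1L, coronal = 2L, axial = 3L)
    n <- dim(vol)[ax]
    if (!is.numeric(slice_index) || slice_index < 1L || slice_index > n) {
      stop_rnst("slice_index ", slice_index, " out of range [1, ", n, "]",
                class = "rnst_validation_error")
    }
    img <- switch(axis,
      sagittal = vol[slice_index, , ],
      coronal = vol[, slice_index, ],
      axial = vol[, , slice_index])
    img <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else {
    img <- read_raster(path)
  }
  if (normalize == "none") {
    check_image(img)
    img
  } else {
    normalize_intensity(img, normalize, p_low, p_high)
  }
}

#' Save an image to disk
#'
#' TIFF output is written at 16 bits per sample, so a `[0, 1]` raster
#' round-trips within `1/65535`; PNG output is 8-bit (the PNG bindings do
#' not expose higher depths).
#'
#' @param image matrix in `[0, 1]`.
#' @param path output path ending in `.tiff`/`.tif` or `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(image, path) {
  check_image(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 16L),
    png = png::writePNG(image, path),
    stop_rnst("unsupported output format '.", ext, "'",
              class = "rnst_config_error")
  )
  invisible(path)
}

## ---- run driver + manifest ----------------------------------------------

rnst_version <- function() {
  as.character(utils::packageVersion("rnst"))
}

#' Run a reconstruction from image files
#'
#' Thin driver over [run_rnst()]: loads the content and guidance slices,
#' runs the reconstruction, and (optionally) writes the reconstructed image
#' (16-bit TIFF), a JSON trace, and a JSON run manifest to `out_dir`. The
#' manifest records every resolved setting, so
#' [run_from_manifest()] reproduces the output bit-identically from the
#' same inputs.
#'
#' @param content,guidance file paths (NIfTI/PNG/TIFF).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param content_slice,guidance_slice slice indices for volume inputs.
#' @param axis slice axis for volume inputs.
#' @param backbone_name,backbone_seed backbone selection (default
#'   tiny-random, seed 1).
#' @param weights optional vgg16 weights file.
#' @param style_taps,content_taps optional tap-layer overrides forwarded to
#'   [build_backbone()].
#' @param denoiser a [denoiser_spec()].
#' @param nst_cfg an [nst_config()] or `NULL` for the backbone default.
#' @param rnst_cfg an [rnst_config()].
#' @param normalize intensity normalization method for loaded slices.
#' @return The [run_rnst()] result, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
rnst_run <- function(content, guidance, out_dir = NULL,
                     content_slice = 1L, guidance_slice = 1L,
                     axis = "axial",
                     backbone_name = "tiny-random", backbone_seed = 1L,
                     weights = NULL, style_taps = NULL, content_taps = NULL,
                     denoiser = denoiser_spec(),
                     nst_cfg = NULL,
                     rnst_cfg = rnst_config(),
                     normalize = "percentile") {
  backbone <- build_backbone(backbone_name,
                             seed = if (backbone_name == "tiny-random")
                               backbone_seed else NULL,
                             weights = weights,
                             style_taps = style_taps,
                             content_taps = content_taps)
  if (is.null(nst_cfg)) nst_cfg <- default_nst_config(backbone)
  x_in <- load_slice(content, content_slice, axis, normalize)
  x_guid <- load_slice(guidance, guidance_slice, axis, normalize)
  res <- run_rnst(x_in, x_guid, backbone, denoiser, nst_cfg, rnst_cfg)
  manifest <- list(
    software = list(package = "rnst", version = rnst_version()),
    inputs = list(content = normalizePath(content),
                  guidance = normalizePath(guidance),
                  content_slice = content_slice,
                  guidance_slice = guidance_slice,
                  axis = axis, normalize = normalize),
    backbone = list(name = backbone_name, seed = backbone_seed,
                    weights = weights, style_taps = style_taps,
                    content_taps = content_taps),
    denoiser = unclass(denoiser),
    nst = unclass(nst_cfg),
    rnst = unclass(rnst_cfg)
  )
  attr(res, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    save_image(res$final_image, file.path(out_dir, "reconstruction.tiff"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    trace <- lapply(res$trace, function(r) {
      list(iteration = r$iteration, depth_index = r$depth_index,
           step_index = r$step_index, winner_loss = r$winner_loss,
           candidate_losses = r$candidate_losses,
           identity_loss = r$identity_loss)
    })
    jsonlite::write_json(trace, file.path(out_dir, "trace.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  res
}

#' Replay a reconstruction from its manifest
#'
#' Re-runs [rnst_run()] with the exact settings recorded in a
#' `manifest.json`; with unchanged input files the result is bit-identical.
#'
#' @param manifest_path path to a manifest JSON written by [rnst_run()].
#' @param out_dir optional output directory for the replayed run.
#' @return The [run_rnst()] result.
#' @export
run_from_manifest <- function(manifest_path, out_dir = NULL) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  den <- denoiser_spec(m$denoiser$name,
                       sigma = if (is.null(m$denoiser$sigma)) 20 / 255
                               else m$denoiser$sigma,
                       kernel = m$denoiser$kernel)
  pick <- function(lst, keys) {
    out <- lst[intersect(keys, names(lst))]
    out[!vapply(out, is.null, TRUE)]
  }
  nst <- do.call(nst_config, pick(m$nst, c("alpha", "beta", "norm",
                                           "layer_weights", "inner_steps",
                                           "optimizer", "step_size",
                                           "clamp")))
  rn <- do.call(rnst_config, pick(m$rnst, names(formals(rnst_config))))
  rnst_run(m$inputs$content, m$inputs$guidance, out_dir = out_dir,
           content_slice = m$inputs$content_slice,
           guidance_slice = m$inputs$guidance_slice,
           axis = m$inputs$axis,
           backbone_name = m$backbone$name,
           backbone_seed = m$backbone$seed,
           weights = m$backbone$weights,
           style_taps = unlist(m$backbone$style_taps),
           content_taps = unlist(m$backbone$content_taps),
           denoiser = den, nst_cfg = nst, rnst_cfg = rn,
           normalize = m$inputs$normalize)
}
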