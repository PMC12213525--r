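Package: rnst
Title: Field-Transfer MRI Reconstruction by Neural Style Transfer Regularization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative enhancement of noisy lower-field magnetic resonance
    images toward higher-field appearance without paired training data. A
    neural style transfer engine matches feature-map correlations (Gram
    matrices) of a higher-field guidance slice while a denoiser supplies a
    regularization-by-denoising residual; at each outer iteration candidate
    updates generated at several style-transfer depths and line-search step
    sizes are scored by a one-step style transfer loss and the best is kept.
    Includes a differentiable convolutional feature extractor with a seeded
    offline test backbone, a collaborative-filtering (block-matching 3D)
    denoiser, ellipse phantoms with low-field degradation, PSNR/SSIM metrics,
    and NIfTI/PNG/TIFF slice input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
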