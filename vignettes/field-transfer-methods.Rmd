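---
title: "Field-transfer reconstruction by style-transfer regularization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-transfer reconstruction by style-transfer regularization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The reconstruction problem

A lower-field MR acquisition of anatomy `x_h` can be viewed as
`x = H x_h + e`: an unknown degradation `H` (contrast change from
field-dependent relaxation behaviour) plus noise `e`. `H` is not modelled
here — it is essentially impossible to write down across scanners — and
that is the point of the method: the *style* of a higher-field scan, i.e.
the co-activation statistics of convolutional features summarized by Gram
matrices, stands in for the unavailable forward model. A guidance slice
from the target field supplies those statistics; a denoiser supplies the
noise prior in the spirit of regularization-by-denoising (RED), whose
regularizer `rho(x) = 1/2 x'(x - D(x))` penalizes the residual between an
image and its denoised self.

Each outer iteration combines the two pulls in one explicit gradient-style
update,

```
x_new = x - mu_i * ( (x - x_t) + lambda * (x - x_d) ),
```

where `x_t` is a style-transferred version of the iterate and
`x_d = D(x)`. Because the objective is non-convex and partly defined
through an optimizer (`x_t` itself is the output of `T_N`), the step is
chosen by *search* rather than analysis: candidates at several transfer
depths `N0 + k*Nstep` and several step sizes `i*mu` are all formed, and a
one-step evaluation loss — content anchored at the original input,
style matched to the guidance — picks the winner. An Armijo-type adaptive
step rule would be a natural alternative; the fixed grid `mu_i = i*mu` is
used deliberately for simplicity and reproducibility.

## Assumptions

* Single 2-D grayscale slices in `[0, 1]`; volumes are reconstructed
  slice-wise.
* The guidance encodes the *style* of the target field; it does not need to
  be registered to, or even depict, the same anatomy (the "frozen
  guidance" condition).
* The degradation is a monotone contrast change plus roughly white noise.
  Structured artifacts (motion, bias fields, aliasing) are outside the
  model.

## Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `N0`, `Nstep`, `Nstyle` | 500, 100, 3 | inner-step depths of the candidate transfers |
| `Nline`, `mu` | 5, 0.1 | step-size grid `i*mu`, dimensionless fraction of the residual |
| `lambda` | 0.3 | weight of the denoising residual |
| `Niter` | preset-dependent (10–50) | outer iterations |
| `alpha/beta` | 1e-6 (vgg16), 1e-4 (resnet), 1e-9 (tiny-random) | content/style weight ratio |
| `nst.norm` | `l1` | absolute-difference variant of both losses (sharper reconstructions) |
| denoiser `sigma` | 20/255 | assumed noise sd on `[0,1]` (bm3d) |

`rnst_preset()` bundles the per-study combinations (`nacc-vgg16`,
`nacc-resnet`, `tse-vgg16`, `tse-vgg16-noisy`, `tse-resnet`).

### The `alpha/beta` ratio for the offline backbone

Only the ratio of the two loss weights matters. For the tiny-random
backbone the ratio was set from a gradient-balance argument, fixed once:
under the L1 losses the per-pixel content gradient has magnitude
`alpha/2` per feature entry, while the style gradient scales like
`beta * 2 N_l mean|F| / (4 N_l^2 M_l^2)` with `N_l = 8` maps and
`M_l = 64^2` positions, i.e. about `1e-9 * beta`. Setting
`alpha/beta = 1e-9` makes the two pulls commensurate; a direct numerical
check of the two gradient RMS values on a phantom pair reproduces the
ratio within 15%.

## The inner optimizer

The inner transfer `T_N` is a stateless descent on pixels, initialized at
the content image (the reconstruction-preserving choice; noise
initialization would discard the content before the anchor can act). The
default update normalizes the gradient by its RMS and moves `step_size =
0.02` intensity units per step. Two properties motivated this over a raw
fixed step:

* the loss weights are only fixed as a *ratio*, so raw gradient magnitude
  is arbitrary across backbones; a normalized step has meaningful units
  (2% of the dynamic range) everywhere;
* it is stateless, so `T_{N+M} = T_M ∘ T_N` holds exactly and the depth
  schedule `N0 + k*Nstep` composes predictably — the candidate generator
  exploits this by continuing deeper candidates from shallower ones.

Plain gradient descent (`optimizer = "gd"`) and an adaptive-moment variant
(`"adam"`, stateful, breaks composition) are available. Pixels are clamped
to `[0, 1]` after every step by default: images are physical intensities,
and unbounded drift destabilizes the Gram statistics.

## Numerical and procedural choices

* **Taps** are post-nonlinearity activations (the conventional reading;
  pre-activation taps are not exposed). "First eight layers" of the vgg16
  trunk means the first eight convolutional layers; the content tap is the
  fourth.
* **Grayscale into pretrained stems**: the single channel is replicated to
  three and normalized with the backbone's training constants; the
  tiny-random backbone consumes the `[0,1]` image directly.
* **L1 variant** applies to both the content and the style loss, keeping
  each prefactor; the subgradient of `|.|` at zero is taken as 0, which
  makes a perfectly matched image an exact fixed point of `T_N`.
* **Tie-breaking** in the line search is deterministic: smallest depth
  index, then smallest step index; the optional identity candidate loses
  ties. With the identity candidate on (default), the winning evaluation
  loss is provably non-increasing across outer iterations, since the
  previous winner re-enters the comparison unchanged.
* **Denoising target**: `D` is applied to the *current iterate* each outer
  iteration (RED evaluates its residual at the iterate); a once-only
  "denoise the input" mode remains behind
  `denoise_every_iteration = FALSE`.
* **Candidate refresh**: the candidate list is regenerated from the
  current iterate every outer iteration (the online update that
  compensates for feature mismatch of general-purpose backbones); a
  cheaper frozen-candidate mode exists behind a flag.
* **Degenerate inputs**: constant images are rejected by min–max
  normalization (use percentile bounds); images smaller than a backbone's
  declared minimum are rejected rather than padded; non-finite pixels are
  rejected everywhere. Off-range intermediates are tolerated only inside
  the unclamped inner loop.
* **Denoiser defaults**: the bm3d implementation is the hard-thresholding
  stage of block-matching 3-D collaborative filtering (8×8 blocks, stride
  3, search radius 12, groups of 16, threshold `2.7 sigma`, inverse-sparsity
  aggregation). The gaussian fallback uses reflect padding (a zero
  boundary would bias the reconstruction residual at edges) with a light
  default bandwidth of 0.5 px: on structure-rich images heavier smoothing
  loses more in edge bias than it gains in noise suppression.
* **SSIM** uses an unweighted 7×7 window over fully-interior positions
  ("valid" mode — padded variants shift the score slightly), unbiased
  `n-1` variance normalization, `k1 = 0.01`, `k2 = 0.03`, `L = 1`; a
  Gaussian-weighted window is available behind a flag. PSNR takes its peak
  over the reference image, with an override for a fixed dynamic range.
* **16-bit output** is written as TIFF; the PNG bindings available to the
  package write 8-bit only.

## What the phantoms emulate — and what they do not

`make_pair()` produces a clean "high-field" ellipse phantom, its
"low-field" degradation (monotone contrast remap `gain * x^gamma`, default
`0.9 * x^1.3`, then AWGN at `sigma = 20/255`), and a clean guidance
phantom — different anatomy in the default frozen mode, the same anatomy in
matched mode. This reproduces the two degradations the field-transfer
setting names (noise increase and contrast shift) and the
guidance-mismatch condition, deterministically per seed.

They are *not* physically realistic MR simulations: no Bloch dynamics,
coil sensitivities, Rician noise, partial-volume effects, or k-space
sampling. Passing phantom studies therefore demonstrates the machinery —
losses, search, denoising, metrics, determinism — and the qualitative
noise/contrast recovery, not clinical image quality on real scans.

## Problem sizes used by the test and acceptance studies

Phantom studies run at 64×64 with the desk-scale schedule `N0 = 20`,
`Nstep = 10`, `Nstyle = 2`, `Nline = 3`, `Niter = 3` and the offline
backbone; the full printed schedule (`N0 = 500`, `Nstep = 100`,
`Nstyle = 3`, `Nline = 5`) is exercised for one outer iteration at
128×128. These sizes were chosen so that the complete study suite runs
comfortably on a single CPU while still exercising every code path at the
printed hyperparameter values.

## Known limitations

* No pretrained weights ship with the package; the vgg16 path needs a
  user-supplied weights file, and the resnet graphs are tap metadata only.
* The reconstruction operates per slice; no through-plane consistency is
  enforced.
* The evaluation loss reuses the transfer loss's `alpha`/`beta`; if the
  style term dominates by construction, candidate selection is mostly
  style-driven and the content anchor acts only as a weak tie-breaker.
* BM3D here is the first (hard-thresholding) stage only; a Wiener second
  stage would add a fraction of a dB.
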