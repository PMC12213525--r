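test_that("the candidate update follows its algebra exactly", {
  x <- rand_image(16, seed = 1)
  xt <- rand_image(16, seed = 2)
  xd <- rand_image(16, seed = 3)
  expect_identical(candidate_update(x, xt, xd, 0, 0.3), x)
  expect_identical(candidate_update(x, xt, xd, 1, 0), xt)
  out <- candidate_update(matrix(0.5), matrix(0.7), matrix(0.6), 0.5, 0.3)
  expect_equal(out[1, 1], 0.615, tolerance = 1e-12)
  expect_error(candidate_update(x, xt[1:8, 1:8], xd, 0.1, 0.1),
               class = "rnst_validation_error")
})

test_that("candidate directions are the style transfers at scheduled depths", {
  b <- tiny_backbone()
  pair <- make_pair(phantom_spec(size = 32, seed = 4))
  nst_cfg <- default_nst_config(b)
  rc <- rnst_config(N0 = 3, Nstep = 2, Nstyle = 3, Nline = 1, Niter = 1)
  cands <- build_candidate_directions(pair$content, pair$guidance, b,
                                      nst_cfg, rc)
  expect_length(cands, 3L)
  expect_identical(attr(cands, "depths"), c(3L, 5L, 7L))
  ## each chained candidate equals a direct run at its depth
  for (k in 1:3) {
    cfg_k <- nst_cfg
    cfg_k$inner_steps <- c(3L, 5L, 7L)[k]
    expect_equal(cands[[k]], run_nst(pair$content, pair$guidance, b, cfg_k),
                 tolerance = 1e-13)
  }
  ## degenerate single-candidate list
  rc1 <- rnst_config(N0 = 3, Nstep = 0, Nstyle = 1, Nline = 1, Niter = 1)
  expect_length(build_candidate_directions(pair$content, pair$guidance, b,
                                           nst_cfg, rc1), 1L)
})

test_that("self-guidance makes every candidate the input itself", {
  b <- tiny_backbone()
  x <- make_phantom(phantom_spec(size = 32, seed = 5))
  rc <- rnst_config(N0 = 5, Nstep = 5, Nstyle = 2, Nline = 1, Niter = 1)
  cands <- build_candidate_directions(x, x, b, default_nst_config(b), rc)
  for (cand in cands) expect_equal(cand, x, tolerance = 1e-12)
})

test_that("the one-step evaluation loss isolates its terms", {
  b <- tiny_backbone()
  x <- make_phantom(phantom_spec(size = 32, seed = 6))
  expect_lt(evaluate_candidate(x, x, x, b, alpha = 1e-9, beta = 1), 1e-15)
  noisy <- degrade_to_lowfield(x, phantom_spec(size = 32, seed = 6))
  ## beta = 0: reduces to the content term of the one-step image vs x_in
  l <- evaluate_candidate(noisy, x, x, b, alpha = 1, beta = 0)
  cfg <- default_nst_config(b)
  cfg$alpha <- 1; cfg$beta <- 0
  ctx <- rnst:::nst_context(b, x, x, cfg)
  step_ctx <- rnst:::set_content_anchor(ctx, noisy)
  x1 <- rnst:::nst_descend(noisy, step_ctx, 1L)
  expect_equal(l, content_loss(extract_features(x1, b, "content"),
                               extract_features(x, b, "content"), "l1"),
               tolerance = 1e-10)
})

test_that("a clean candidate outscores its noisy version", {
  spec <- phantom_spec(size = 48, seed = 7)
  clean <- make_phantom(spec)
  noisy <- degrade_to_lowfield(clean, spec)
  guid <- make_phantom(phantom_spec(size = 48, seed = 8))
  b <- tiny_backbone()
  l_clean <- evaluate_candidate(clean, noisy, guid, b, 1e-9, 1)
  l_noisy <- evaluate_candidate(noisy, noisy, guid, b, 1e-9, 1)
  expect_lt(l_clean, l_noisy)
})

test_that("one iteration selects the exact minimum of the scored set", {
  b <- tiny_backbone()
  pair <- make_pair(phantom_spec(size = 32, seed = 9))
  rc <- small_schedule(1L)
  den <- denoiser_spec("gaussian")
  nst_cfg <- default_nst_config(b)
  step <- rnst_iterate(pair$content, pair$content, pair$guidance, b, den,
                       nst_cfg, rc)
  rec <- step$record
  expect_identical(dim(rec$candidate_losses), c(rc$Nstyle, rc$Nline))
  expect_true(all(rec$winner_loss <= rec$candidate_losses))
  expect_lte(rec$winner_loss, rec$identity_loss)
  ## independent exhaustive re-scoring
  xd <- denoise(pair$content, den)
  cands <- build_candidate_directions(pair$content, pair$guidance, b,
                                      nst_cfg, rc)
  w <- rnst:::rnst_eval_weights(nst_cfg, rc)
  for (k in seq_len(rc$Nstyle)) {
    for (i in seq_len(rc$Nline)) {
      xt <- candidate_update(pair$content, cands[[k]], xd, i * rc$mu, rc$lam)
      expect_equal(rec$candidate_losses[k, i],
                   evaluate_candidate(xt, pair$content, pair$guidance, b,
                                      w$alpha, w$beta, nst_cfg$norm),
                   tolerance = 1e-12)
    }
  }
  kk <- rec$depth_index; ii <- rec$step_index
  if (!is.na(kk)) {
    expect_equal(rec$winner_loss, rec$candidate_losses[kk, ii])
    expect_equal(rec$winner_loss, min(rec$candidate_losses, rec$identity_loss))
  }
})

test_that("degenerate 1x1 searches score exactly one direction", {
  b <- tiny_backbone()
  pair <- make_pair(phantom_spec(size = 32, seed = 10))
  rc <- rnst_config(N0 = 5, Nstep = 0, Nstyle = 1, Nline = 1, Niter = 1,
                    include_identity_candidate = FALSE)
  step <- rnst_iterate(pair$content, pair$content, pair$guidance, b,
                       denoiser_spec("identity"), default_nst_config(b), rc)
  expect_identical(dim(step$record$candidate_losses), c(1L, 1L))
  expect_identical(step$record$depth_index, 1L)
  expect_identical(step$record$step_index, 1L)
})

test_that("the search reduces to pure style transfer in the analytic limit", {
  ## Nstyle = Nline = 1, lambda = 0, mu = 1, no identity candidate:
  ## one outer iteration must return exactly T_N0(x)
  b <- tiny_backbone()
  pair <- make_pair(phantom_spec(size = 32, seed = 11))
  nst_cfg <- default_nst_config(b)
  rc <- rnst_config(N0 = 8, Nstep = 0, Nstyle = 1, Nline = 1, Niter = 1,
                    mu = 1, lam = 0, include_identity_candidate = FALSE)
  res <- run_rnst(pair$content, pair$guidance, b, denoiser_spec("identity"),
                  nst_cfg, rc)
  cfg8 <- nst_cfg
  cfg8$inner_steps <- 8L
  expect_equal(res$final_image,
               clamp_ref <- pmin(pmax(run_nst(pair$content, pair$guidance,
                                              b, cfg8), 0), 1),
               tolerance = 1e-14)
})

test_that("reconstruction runs are deterministic with a consistent trace", {
  b <- tiny_backbone()
  pair <- make_pair(phantom_spec(size = 32, seed = 12))
  rc <- small_schedule(2L)
  r1 <- run_rnst(pair$content, pair$guidance, b, denoiser_spec("gaussian"),
                 rnst_cfg = rc, reference = pair$clean_reference,
                 keep_iterates = TRUE)
  r2 <- run_rnst(pair$content, pair$guidance, b, denoiser_spec("gaussian"),
                 rnst_cfg = rc)
  expect_identical(r1$final_image, r2$final_image)
  expect_length(r1$trace, 2L)
  ## trace replay: recorded indices reproduce the winner from the same state
  rec <- r1$trace[[1]]
  xd <- denoise(rec$x_before, denoiser_spec("gaussian"))
  cands <- build_candidate_directions(rec$x_before, pair$guidance, b,
                                      default_nst_config(b), rc)
  winner <- if (is.na(rec$depth_index)) rec$x_before else {
    candidate_update(rec$x_before, cands[[rec$depth_index]], xd,
                     rec$step_index * rc$mu, rc$lam)
  }
  expect_identical(winner, r1$trace[[2]]$x_before)
  expect_true(all(is.finite(vapply(r1$trace, `[[`, 0, "psnr"))))
})

test_that("identity candidates make the winning loss non-increasing", {
  b <- tiny_backbone()
  pair <- make_pair(phantom_spec(size = 32, seed = 13))
  res <- run_rnst(pair$content, pair$guidance, b, denoiser_spec("gaussian"),
                  rnst_cfg = small_schedule(3L))
  wl <- vapply(res$trace, `[[`, 0, "winner_loss")
  expect_true(all(diff(wl) <= 1e-12))
})

test_that("outer-loop configuration invariants are enforced", {
  expect_error(rnst_config(N0 = 0), class = "rnst_config_error")
  expect_error(rnst_config(Nstep = -1), class = "rnst_config_error")
  expect_error(rnst_config(mu = 0), class = "rnst_validation_error")
  expect_error(rnst_config(lam = -0.1), class = "rnst_validation_error")
})

test_that("presets carry the printed per-study settings", {
  p <- rnst_preset("nacc-resnet")
  expect_identical(p$backbone_name, "resnet50")
  expect_identical(p$rnst$Niter, 10L)
  expect_equal(p$rnst$mu, 0.1)
  expect_equal(p$rnst$lam, 0.3)
  expect_identical(c(p$rnst$N0, p$rnst$Nstep, p$rnst$Nstyle, p$rnst$Nline),
                   c(500L, 100L, 3L, 5L))
  expect_equal(p$nst$alpha / p$nst$beta, 1e-4)
  v <- rnst_preset("tse-vgg16-noisy")
  expect_identical(v$rnst$Niter, 50L)
  expect_equal(v$rnst$mu, 0.15)
  expect_equal(v$nst$alpha / v$nst$beta, 1e-6)
  expect_identical(v$denoiser$name, "bm3d")
  expect_equal(v$denoiser$sigma, 20 / 255)
})
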