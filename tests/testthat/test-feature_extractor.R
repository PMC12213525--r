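test_that("backbones expose the documented tap layers", {
  v <- build_backbone("vgg16")
  expect_length(v$style_taps, 8L)
  expect_length(v$content_taps, 1L)
  expect_identical(v$content_taps, "conv2_2")
  ## first style tap has 64 feature maps by construction of the architecture
  first_tap <- Filter(function(l) l$id == v$style_taps[1], v$layers)[[1]]
  expect_identical(first_tap$c_out, 64L)

  for (nm in c("resnet50", "resnet152")) {
    r <- build_backbone(nm)
    expect_length(r$style_taps, 4L)
    expect_length(r$content_taps, 3L)
  }

  t <- build_backbone("tiny-random", seed = 7)
  expect_length(t$style_taps, 4L)
  expect_identical(t$content_taps, "conv2")
})

test_that("backbone construction validates its arguments", {
  expect_error(build_backbone("vgg19"), class = "rnst_config_error")
  expect_error(build_backbone("tiny-random"), class = "rnst_config_error")
  expect_error(build_backbone("vgg16", seed = 1), class = "rnst_config_error")
  expect_error(build_backbone("tiny-random", seed = 1, style_taps = "conv9"),
               class = "rnst_config_error")
})

test_that("extraction without pretrained weights points to tiny-random", {
  img <- matrix(0.5, 64, 64)
  err <- expect_error(extract_features(img, build_backbone("vgg16"), "style"),
                      class = "rnst_config_error")
  expect_match(conditionMessage(err), "tiny-random")
  expect_error(extract_features(img, build_backbone("resnet50"), "style"),
               class = "rnst_config_error")
})

test_that("extraction is deterministic and seed-faithful", {
  img <- rand_image(32, seed = 11)
  b1 <- build_backbone("tiny-random", seed = 7)
  b2 <- build_backbone("tiny-random", seed = 7)
  b3 <- build_backbone("tiny-random", seed = 8)
  f1 <- extract_features(img, b1, "style")
  f2 <- extract_features(img, b2, "style")
  f3 <- extract_features(img, b3, "style")
  expect_identical(f1, f2)
  expect_false(isTRUE(all.equal(f1$conv1, f3$conv1)))
  ## repeated calls on the same backbone are bit-identical
  expect_identical(f1, extract_features(img, b1, "style"))
})

test_that("a zero image yields the constant per-layer bias response", {
  b <- tiny_backbone()
  fs <- extract_features(matrix(0, 64, 64), b, "style")
  for (f in fs) {
    expect_true(all(f == 0))  # biases are zero, so the response is zero
    expect_identical(dim(f), c(8L, 64L * 64L))
  }
})

test_that("feature map shapes follow the architecture", {
  b <- tiny_backbone()
  fs <- extract_features(rand_image(32), b, "style")
  expect_named(fs, paste0("conv", 1:4))
  for (f in fs) expect_identical(dim(f), c(8L, 32L * 32L))
  fc <- extract_features(rand_image(32), b, "content")
  expect_named(fc, "conv2")
})

test_that("first-tap features are translation covariant in the interior", {
  b <- tiny_backbone()
  img <- rand_image(32, seed = 3)
  shifted <- rbind(img[-1, ], img[1, ])    # shift up by one row
  a1 <- array(t(extract_features(img, b, "style")$conv1), c(32, 32, 8))
  a2 <- array(t(extract_features(shifted, b, "style")$conv1), c(32, 32, 8))
  ## interior rows only: boundary rows see the zero padding
  expect_equal(a2[2:29, 2:31, ], a1[3:30, 2:31, ], tolerance = 1e-12)
})

test_that("inputs are validated before extraction", {
  b <- tiny_backbone()
  expect_error(extract_features(matrix(0.5, 8, 8), b, "style"),
               class = "rnst_shape_error")
  bad <- matrix(0.5, 32, 32); bad[1] <- NA
  expect_error(extract_features(bad, b, "style"),
               class = "rnst_validation_error")
  expect_error(extract_features(matrix(2, 32, 32), b, "style"),
               class = "rnst_validation_error")
})

test_that("loss gradients match central finite differences", {
  b <- tiny_backbone()
  x <- rand_image(16, seed = 5)
  xc <- rand_image(16, seed = 6)
  xs <- rand_image(16, seed = 7)
  for (norm in c("l2", "l1")) {
    cfg <- nst_config(alpha = 1, beta = 1e6, norm = norm)
    ctx <- rnst:::nst_context(b, xs, xc, cfg)
    g <- rnst:::nst_loss_grad(x, ctx)$grad
    eps <- 1e-6
    idx <- with_local_seed(8, sample(length(x), 10))
    for (i in idx) {
      xp <- x; xp[i] <- xp[i] + eps
      xm <- x; xm[i] <- xm[i] - eps
      num <- (rnst:::nst_loss_grad(xp, ctx, grad = FALSE)$loss -
                rnst:::nst_loss_grad(xm, ctx, grad = FALSE)$loss) / (2 * eps)
      expect_equal(g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("max-pooling routes gradients to the argmax pixels", {
  ## values chosen with a unique maximum in every pooled window
  x <- array(c(1, 3, 2, 4,
               5, 6, 8, 7,
               0.9, 0.1, 0.8, 0.2,
               0.0, 2, 0.3, 0.4), c(4, 4, 1))
  fw <- rnst:::maxpool_forward(x)
  expect_identical(dim(fw$out), c(2L, 2L, 1L))
  expect_equal(fw$out[, , 1], matrix(c(6, 8, 2, 0.8), 2, 2))
  dy <- array(1, c(2, 2, 1))
  dx <- rnst:::maxpool_backward(dy, fw)
  expect_equal(sum(dx), 4)                 # one unit per pooled window
  expect_equal(dx[2, 2, 1], 1)             # the 6
  expect_equal(dx[3, 2, 1], 1)             # the 8
  ## finite-difference check through pool + square loss
  f <- function(v) {
    sum(rnst:::maxpool_forward(array(v, dim(x)))$out^2)
  }
  g_an <- 2 * fw$out
  dxa <- rnst:::maxpool_backward(g_an, fw)
  eps <- 1e-6
  for (i in c(1, 6, 11, 16)) {
    v <- as.vector(x)
    vp <- v; vp[i] <- vp[i] + eps
    vm <- v; vm[i] <- vm[i] - eps
    expect_equal(dxa[i], (f(vp) - f(vm)) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("backbone parameters never drift", {
  b <- tiny_backbone()
  cs <- backbone_checksum(b)
  invisible(extract_features(rand_image(32), b, "style"))
  invisible(run_nst(rand_image(32, 1), rand_image(32, 2), b,
                    nst_config(alpha = 1e-9, beta = 1, inner_steps = 5)))
  expect_identical(backbone_checksum(b), cs)
  expect_gt(cs["n"], 0)
})

test_that("vgg16 executes and differentiates with supplied weights", {
  ## small synthetic weight set exercising the conv/pool executor path
  plan <- rnst:::vgg16_plan()
  wl <- list()
  with_local_seed(99, {
    for (l in plan) {
      if (l$type != "conv") next
      wl[[l$id]] <- list(
        weight = array(stats::rnorm(l$k^2 * l$c_in * l$c_out,
                                    sd = sqrt(2 / (l$k^2 * l$c_in))) * 0.5,
                       c(l$k, l$k, l$c_in, l$c_out)),
        bias = rep(0, l$c_out))
    }
  })
  wf <- tempfile(fileext = ".rds")
  saveRDS(wl, wf)
  v <- build_backbone("vgg16", weights = wf)
  expect_true(v$executable)
  img <- rand_image(32, seed = 12)
  fs <- extract_features(img, v, "style")
  expect_identical(nrow(fs$conv1_1), 64L)
  expect_identical(ncol(fs$conv4_1), 4L * 4L)     # 32 / 2^3 after 3 pools
  expect_true(all(vapply(fs, function(f) all(is.finite(f)), TRUE)))
  ## gradient through pools and normalization stem
  cfg <- nst_config(alpha = 1, beta = 1e3, norm = "l2")
  ctx <- rnst:::nst_context(v, rand_image(32, 13), rand_image(32, 14), cfg)
  g <- rnst:::nst_loss_grad(img, ctx)$grad
  eps <- 1e-5
  for (i in c(40, 500)) {
    xp <- img; xp[i] <- xp[i] + eps
    xm <- img; xm[i] <- xm[i] - eps
    num <- (rnst:::nst_loss_grad(xp, ctx, grad = FALSE)$loss -
              rnst:::nst_loss_grad(xm, ctx, grad = FALSE)$loss) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-3)
  }
})
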