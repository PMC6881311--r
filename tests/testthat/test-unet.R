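test_that("architecture contract: depths, bottleneck, shapes, output range", {
  spec <- unet_spec(levels = 5, kernel = 3, pool = 2, base_filters = 16)
  expect_identical(unet_depths(spec), c(16L, 32L, 64L, 128L, 256L))
  expect_identical(unet_bottleneck_px(spec, 128L), 8L)
  m <- build_unet(spec, seed = 1)
  # weight shapes encode the doubling rule
  expect_identical(dim(m$weights$enc1_conv1$W), c(9L * 4L, 16L))
  expect_identical(dim(m$weights$enc5_conv2$W), c(9L * 256L, 256L))
  expect_identical(dim(m$weights$up4$W), c(256L, 4L * 128L))
  expect_identical(dim(m$weights$dec1_conv1$W), c(9L * 32L, 16L))
  x <- array(runif(128 * 128 * 4), c(128, 128, 4))
  p <- canopyseg:::unet_forward(m, x)$p
  expect_identical(dim(p), c(128L, 128L))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(unet_bottleneck_px(spec, 120L), "not divisible")
})

test_that("single-level spec degenerates to a plain convolution stack", {
  m <- build_unet(unet_spec(levels = 1, base_filters = 8), seed = 2)
  expect_setequal(names(m$weights), c("enc1_conv1", "enc1_conv2", "out"))
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  p <- canopyseg:::unet_forward(m, x)$p
  expect_identical(dim(p), c(16L, 16L))
})

test_that("forward input contracts are enforced", {
  m <- build_unet(unet_spec(levels = 3, base_filters = 4), seed = 3)
  expect_error(predict_tile(m, array(0, c(16, 16, 3))),
               "expected 4 predictor channels")
  expect_error(predict_tile(m, array(0, c(18, 18, 4))), "not divisible")
})

test_that("dice coefficient matches its closed form and bounds", {
  a <- matrix(c(1, 1, 1, 1), 2)
  b <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_coefficient(a, b, smooth = 0), 2 * 2 / (4 + 2))
  expect_equal(dice_coefficient(a, a, smooth = 0), 1)
  expect_equal(dice_coefficient(a * 0, a, smooth = 0), 0)
  expect_equal(dice_loss(a, b, smooth = 0), 1 / 3)
  expect_error(dice_coefficient(a, matrix(0, 3, 2)), "shape mismatch")
  # smooth term keeps empty-vs-empty defined
  expect_equal(dice_coefficient(a * 0, a * 0, smooth = 1), 1)
})

test_that("dice gradient agrees with numerical differentiation", {
  set.seed(5)
  p <- matrix(runif(16), 4)
  y <- matrix(rbinom(16, 1, 0.5), 4)
  g <- canopyseg:::dice_loss_grad(p, y, smooth = 1)
  eps <- 1e-6
  for (i in sample(16, 4)) {
    p2 <- p; p2[i] <- p2[i] + eps
    num <- (dice_loss(p2, y) - dice_loss(p, y)) / eps
    expect_equal(g[i], num, tolerance = 1e-4)
  }
})

test_that("predict_tile is deterministic and thresholds correctly", {
  m <- build_unet(unet_spec(levels = 2, base_filters = 4), seed = 4)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  a <- predict_tile(m, x)
  b <- predict_tile(m, x)
  expect_identical(a$probabilities, b$probabilities)
  expect_identical(a$labels, (a$probabilities >= 0.5) * 1)
  hi <- predict_tile(m, x, threshold = 1.0)
  expect_true(all(hi$labels[hi$probabilities < 1] == 0))
  # zeroed final layer gives sigmoid(0) = 0.5 everywhere
  m$weights$out$W[] <- 0
  m$weights$out$b[] <- 0
  expect_true(all(predict_tile(m, x)$probabilities == 0.5))
})

test_that("fused engine agrees with the layer-by-layer reference", {
  set.seed(6)
  for (cfg in list(c(levels = 3, base = 4, nb = 2),
                   c(levels = 2, base = 8, nb = 1))) {
    m <- build_unet(unet_spec(levels = cfg["levels"],
                              base_filters = cfg["base"]), seed = 7)
    nb <- cfg[["nb"]]
    x <- array(runif(32 * 32 * 4 * nb), c(32, 32, 4 * nb))
    ff <- canopyseg:::unet_forward(m, x, keep_cache = TRUE, n_batch = nb)
    fr <- canopyseg:::unet_forward_ref(m, x, keep_cache = TRUE, n_batch = nb)
    expect_equal(max(abs(ff$p - fr$p)), 0)
    y <- matrix(rbinom(1024, 1, 0.4), 32)
    pa <- array(ff$p, c(32, 32, nb))
    gp <- array(0, dim(pa))
    for (b in seq_len(nb)) gp[, , b] <- canopyseg:::dice_loss_grad(pa[, , b], y)
    gf <- canopyseg:::unet_backward(m, ff$cache, pa, gp)
    gr <- canopyseg:::unet_backward_ref(m, fr$cache, fr$p,
                                        if (nb == 1) gp[, , 1] else gp)
    for (nm in names(gf)) {
      expect_equal(gf[[nm]]$W, gr[[nm]]$W, tolerance = 1e-12)
      expect_equal(gf[[nm]]$b, gr[[nm]]$b, tolerance = 1e-12)
    }
  }
})

test_that("interior predictions are translation equivariant", {
  # shifting the input by one pooling period shifts the prediction, away
  # from the borders where padding breaks the symmetry
  m <- build_unet(unet_spec(levels = 2, base_filters = 8), seed = 8)
  set.seed(9)
  x <- array(runif(48 * 48 * 4), c(48, 48, 4))
  s <- 2  # one pooling period
  xs <- array(0, dim(x))
  xs[(1 + s):48, (1 + s):48, ] <- x[1:(48 - s), 1:(48 - s), ]
  p <- canopyseg:::unet_forward(m, x)$p
  ps <- canopyseg:::unet_forward(m, xs)$p
  inner <- 12:36
  expect_equal(ps[inner + s, inner + s], p[inner, inner], tolerance = 1e-4)
})

test_that("weights round trip through the weights file with spec checking", {
  dir <- withr::local_tempdir()
  m <- build_unet(unet_spec(levels = 2, base_filters = 4), seed = 10)
  path <- file.path(dir, "w.rds")
  save_weights(m, path)
  back <- load_weights(path)
  expect_identical(back$weights, m$weights)
  expect_identical(unclass(back$spec), unclass(m$spec))
  expect_error(load_weights(path, spec = unet_spec(levels = 3)),
               "different architecture")
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  expect_identical(predict_tile(back, x)$probabilities,
                   predict_tile(m, x)$probabilities)
})
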