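make_training_tileset <- function(n_train = 8, n_holdoff = 3, n_val = 4,
                                  tile_px = 16, seed = 21,
                                  pattern = c("quadrant", "empty")) {
  pattern <- match.arg(pattern)
  set.seed(seed)
  make_one <- function(i) {
    pred <- array(runif(tile_px * tile_px * 4, 0.4, 0.6),
                  c(tile_px, tile_px, 4))
    mask <- matrix(0, tile_px, tile_px)
    if (pattern == "quadrant") {
      # separable signal: a bright block in a random quadrant marks class 1
      q <- sample(0:1, 2, replace = TRUE)
      rs <- q[1] * tile_px / 2 + seq_len(tile_px / 2)
      cs <- q[2] * tile_px / 2 + seq_len(tile_px / 2)
      pred[rs, cs, 1] <- pred[rs, cs, 1] + 0.35
      mask[rs, cs] <- 1
    }
    structure(list(predictors = pred, mask = mask,
                   origin = c(row = i * tile_px, col = 0L),
                   cover = mean(mask)),
              class = "canopy_tile")
  }
  tiles <- lapply(seq_len(n_train + n_holdoff + n_val), make_one)
  structure(list(train = tiles[seq_len(n_train)],
                 holdoff = tiles[n_train + seq_len(n_holdoff)],
                 validation = tiles[n_train + n_holdoff + seq_len(n_val)],
                 spec = tile_spec(tile_px = tile_px, grid_spacing_m = 5),
                 provenance = list(seed = seed, crs_id = "EPSG:32719",
                                   geotransform = c(0, 1, 0, 100, 0, -1))),
            class = "tile_set")
}

quick_cfg <- function(...) {
  train_config(epochs = 2, steps_per_epoch = 4, batch_size = 4,
               learning_rate = 1e-3, seed = 31, ...)
}

no_aug <- augment_config(shear_range_rad = c(0, 0), rotation_step_deg = 360,
                         shift_range_frac = c(0, 0),
                         allow_hflip = FALSE, allow_vflip = FALSE)

test_that("checkpoint rule accepts exactly the epochs that beat the last accepted", {
  expect_identical(checkpoint_accepted(c(0.6, 0.55, 0.7)),
                   c(TRUE, FALSE, TRUE))
  expect_identical(checkpoint_accepted(c(0.5, 0.6, 0.58, 0.59, 0.61)),
                   c(TRUE, TRUE, FALSE, FALSE, TRUE))
  # a dip does not lower the bar under the default rule ...
  expect_identical(checkpoint_accepted(c(0.7, 0.4, 0.5)),
                   c(TRUE, FALSE, FALSE))
  # ... but does under the literal previous-epoch reading
  expect_identical(checkpoint_accepted(c(0.7, 0.4, 0.5), "previous_epoch"),
                   c(TRUE, FALSE, TRUE))
  expect_identical(checkpoint_accepted(numeric(0)), logical(0))
  # accepted hold-off accuracies are strictly increasing
  set.seed(12)
  for (i in 1:20) {
    accs <- runif(10)
    keep <- checkpoint_accepted(accs)
    expect_true(all(diff(accs[keep]) > 0))
  }
})

test_that("training reduces the dice loss on a separable tile set", {
  ts <- make_training_tileset()
  m <- build_unet(unet_spec(levels = 2, base_filters = 8), seed = 41)
  fit <- train(m, ts, no_aug,
               train_config(epochs = 4, steps_per_epoch = 10, batch_size = 4,
                            learning_rate = 1e-3, seed = 31))
  expect_lt(fit$log$loss[nrow(fit$log)], fit$log$loss[1])
  expect_identical(fit$log$accepted,
                   checkpoint_accepted(fit$log$holdoff_accuracy))
  expect_gt(fit$best_epoch, 0)
})

test_that("training is reproducible given the seed", {
  ts <- make_training_tileset()
  m <- build_unet(unet_spec(levels = 2, base_filters = 4), seed = 42)
  a <- train(m, ts, no_aug, quick_cfg())
  b <- train(m, ts, no_aug, quick_cfg())
  expect_identical(a$log, b$log)
  expect_identical(a$model$weights, b$model$weights)
})

test_that("all-zero masks train to near-zero predictions with finite loss", {
  ts <- make_training_tileset(pattern = "empty")
  m <- build_unet(unet_spec(levels = 2, base_filters = 4), seed = 43)
  fit <- train(m, ts, no_aug,
               train_config(epochs = 1, steps_per_epoch = 15, batch_size = 4,
                            learning_rate = 2e-3, seed = 33))
  expect_true(all(is.finite(fit$log$loss)))
  p <- predict_tile(fit$model, ts$validation[[1]]$predictors)$probabilities
  expect_lt(mean(p), 0.25)
})

test_that("empty partitions are rejected", {
  ts <- make_training_tileset()
  m <- build_unet(unet_spec(levels = 2, base_filters = 4), seed = 44)
  ts_empty <- ts; ts_empty$holdoff <- list()
  expect_error(train(m, ts_empty, no_aug, quick_cfg()), "holdoff")
  ts_empty <- ts; ts_empty$train <- list()
  expect_error(train(m, ts_empty, no_aug, quick_cfg()), "train")
})

test_that("training log serializes as a delimited table", {
  dir <- withr::local_tempdir()
  log <- data.frame(epoch = 1:2, loss = c(0.9, 0.7),
                    holdoff_accuracy = c(0.6, 0.8), accepted = c(TRUE, TRUE))
  path <- file.path(dir, "log.tsv")
  write_trainlog(log, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(back, log)
})
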