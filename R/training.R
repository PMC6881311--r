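# Model training: RMSprop on the dice loss with on-the-fly augmentation
# and the epoch checkpoint rule (weights of an epoch are only retained if
# its hold-off accuracy surpasses the previously accepted epoch's).

#' Training configuration
#'
#' @param learning_rate RMSprop learning rate.
#' @param epochs number of training epochs.
#' @param steps_per_epoch gradient steps per epoch. The default mirrors a
#'   full-scale run (20 epochs x 2500 steps = 50,000 steps); desk-scale
#'   profiles use far fewer.
#' @param batch_size tiles per gradient step.
#' @param rho RMSprop moving-average decay.
#' @param epsilon RMSprop stabilizer.
#' @param threshold probability threshold used for the per-epoch hold-off
#'   pixel accuracy (the checkpoint metric).
#' @param checkpoint_rule `"last_accepted"` compares each epoch's hold-off
#'   accuracy against the last accepted epoch (a dip does not lower the
#'   bar); `"previous_epoch"` compares against the immediately preceding
#'   epoch regardless of acceptance.
#' @param dice_scope `"batch"` (default) computes the dice coefficient over
#'   all tiles of a step pooled together, as is standard for dice-loss
#'   implementations and essential for a usable false-positive gradient on
#'   empty-mask tiles; `"tile"` averages per-tile dice losses instead.
#' @param smooth dice smoothing term.
#' @param seed integer seed; fixes batch draws, augmentation and (via
#'   [build_unet()] callers) initialization.
#' @param verbose emit a progress message per epoch.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 20L,
                         steps_per_epoch = 2500L, batch_size = 16L,
                         rho = 0.9, epsilon = 1e-7, threshold = 0.5,
                         checkpoint_rule = c("last_accepted", "previous_epoch"),
                         dice_scope = c("batch", "tile"),
                         smooth = 1, seed = 1L, verbose = FALSE) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  if (steps_per_epoch < 1) stop("steps_per_epoch must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size), rho = rho,
                 epsilon = epsilon, threshold = threshold,
                 checkpoint_rule = match.arg(checkpoint_rule),
                 dice_scope = match.arg(dice_scope),
                 smooth = smooth, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Epoch acceptance flags under the checkpoint rule
#'
#' @param accuracies numeric vector of per-epoch hold-off accuracies.
#' @param rule `"last_accepted"` (default) or `"previous_epoch"`.
#' @return logical vector: `TRUE` exactly for accepted epochs. The first
#'   epoch is always accepted (there is no earlier accuracy to surpass).
#' @export
checkpoint_accepted <- function(accuracies, rule = "last_accepted") {
  n <- length(accuracies)
  if (n == 0) return(logical(0))
  acc <- logical(n)
  acc[1] <- TRUE
  best <- accuracies[1]
  for (i in seq_len(n)[-1]) {
    ref <- if (rule == "previous_epoch") accuracies[i - 1] else best
    acc[i] <- accuracies[i] > ref
    if (acc[i]) best <- accuracies[i]
  }
  acc
}

# single RMSprop update over the named weight list
rmsprop_update <- function(weights, grads, state, cfg) {
  for (nm in names(grads)) {
    for (part in c("W", "b")) {
      gsq <- grads[[nm]][[part]]^2
      state[[nm]][[part]] <- cfg$rho * state[[nm]][[part]] + (1 - cfg$rho) * gsq
      weights[[nm]][[part]] <- weights[[nm]][[part]] -
        cfg$learning_rate * grads[[nm]][[part]] /
        (sqrt(state[[nm]][[part]]) + cfg$epsilon)
    }
  }
  list(weights = weights, state = state)
}

# stack a list of tiles into one batched predictor cube
stack_predictors <- function(tiles) {
  tp <- dim(tiles[[1]]$predictors)
  x <- array(0, c(tp[1], tp[2], tp[3] * length(tiles)))
  for (b in seq_along(tiles)) {
    x[, , (b - 1L) * tp[3] + seq_len(tp[3])] <- tiles[[b]]$predictors
  }
  x
}

holdoff_accuracy <- function(model, tiles, threshold, chunk = 16L) {
  accs <- numeric(length(tiles))
  for (i0 in seq(1L, length(tiles), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, length(tiles))
    p <- unet_forward(model, stack_predictors(tiles[idx]),
                      n_batch = length(idx))$p
    p <- array(p, c(dim(p)[1], dim(p)[2], length(idx)))
    for (j in seq_along(idx)) {
      accs[idx[j]] <- pixel_accuracy((p[, , j] >= threshold) * 1,
                                     tiles[[idx[j]]]$mask)
    }
  }
  mean(accs)
}

#' Train a U-net on a tile set
#'
#' Each step draws a batch (with replacement) from the training tiles,
#' applies a freshly sampled geometric augmentation per tile, and takes one
#' RMSprop step on the mean dice loss. After each epoch the thresholded
#' pixel accuracy on the un-augmented hold-off tiles decides checkpoint
#' acceptance; the returned model carries the best retained weights.
#' Fully reproducible given `cfg$seed`.
#'
#' @param model a `unet_model` (initial weights).
#' @param tiles a `tile_set` with non-empty `train` and `holdoff` partitions.
#' @param aug an [augment_config()].
#' @param cfg a [train_config()].
#' @return list with `model` (best weights), `log` (data frame: epoch,
#'   loss, holdoff_accuracy, accepted) and `best_epoch`.
#' @export
train <- function(model, tiles, aug = augment_config(), cfg = train_config()) {
  stopifnot(inherits(model, "unet_model"), inherits(tiles, "tile_set"))
  if (!length(tiles$train)) stop("tile set has an empty train partition")
  if (!length(tiles$holdoff)) stop("tile set has an empty holdoff partition")
  n_train <- length(tiles$train)
  withr::with_seed(cfg$seed, {
    state <- lapply(model$weights, function(l)
      list(W = array(0, dim(l$W)), b = numeric(length(l$b))))
    accs <- numeric(0)
    best_weights <- model$weights
    best_epoch <- 0L
    log_rows <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0
      for (st in seq_len(cfg$steps_per_epoch)) {
        idx <- sample.int(n_train, cfg$batch_size, replace = TRUE)
        batch <- lapply(idx, function(i)
          apply_transform(tiles$train[[i]], sample_transform(aug), aug))
        nb <- cfg$batch_size
        fw <- unet_forward(model, stack_predictors(batch),
                           keep_cache = TRUE, n_batch = nb)
        p <- array(fw$p, c(dim(fw$p)[1], dim(fw$p)[2], nb))
        if (cfg$dice_scope == "batch") {
          y <- array(0, dim(p))
          for (b in seq_len(nb)) y[, , b] <- batch[[b]]$mask
          step_loss <- dice_loss(p, y, cfg$smooth)
          gp <- dice_loss_grad(p, y, cfg$smooth)
        } else {
          gp <- array(0, dim(p))
          step_loss <- 0
          for (b in seq_len(nb)) {
            step_loss <- step_loss + dice_loss(p[, , b], batch[[b]]$mask,
                                               cfg$smooth)
            gp[, , b] <- dice_loss_grad(p[, , b], batch[[b]]$mask,
                                        cfg$smooth) / nb
          }
          step_loss <- step_loss / nb
        }
        if (!is.finite(step_loss)) {
          stop("non-finite loss at epoch ", ep, ", step ", st)
        }
        grads <- unet_backward(model, fw$cache, p, gp)
        upd <- rmsprop_update(model$weights, grads, state, cfg)
        model$weights <- upd$weights
        state <- upd$state
        ep_loss <- ep_loss + step_loss
      }
      ep_loss <- ep_loss / cfg$steps_per_epoch
      acc <- holdoff_accuracy(model, tiles$holdoff, cfg$threshold)
      accs <- c(accs, acc)
      accepted <- checkpoint_accepted(accs, cfg$checkpoint_rule)[ep]
      if (accepted) {
        best_weights <- model$weights
        best_epoch <- ep
      }
      log_rows[[ep]] <- data.frame(epoch = ep, loss = ep_loss,
                                   holdoff_accuracy = acc,
                                   accepted = accepted)
      if (cfg$verbose) {
        message(sprintf("epoch %d/%d: dice loss %.4f, hold-off accuracy %.4f%s",
                        ep, cfg$epochs, ep_loss, acc,
                        if (accepted) " *" else ""))
      }
    }
    model$weights <- best_weights
    list(model = model, log = do.call(rbind, log_rows),
         best_epoch = best_epoch)
  })
}

#' Write a training log as a plain-text delimited table
#'
#' @param log the `log` data frame returned by [train()].
#' @param path output `.tsv` path.
#' @export
write_trainlog <- function(log, path) {
  write.table(log, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
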