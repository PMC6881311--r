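# U-net encoder-decoder for binary segmentation.
#
# The architecture follows the classic design: `levels` encoder stages of
# two same-padding 3x3 convolutions with ReLU, 2x2 max pooling between
# stages, feature depth doubling with each pooling; a mirrored decoder of
# 2x2 transposed convolutions with skip concatenation from the matching
# encoder stage; a 1x1 convolution with sigmoid activation producing a
# per-pixel probability at the input resolution. Weights live in a plain
# named list; forward and backward passes are orchestrated in R over the
# package's C++ kernels, so the whole model runs on one CPU.

#' U-net architecture specification
#'
#' @param levels encoder depth (number of resolution stages).
#' @param kernel convolution kernel edge (odd).
#' @param pool pooling factor; only 2 is supported.
#' @param base_filters feature-map depth at the first stage; depth at stage
#'   k is `base_filters * 2^(k-1)`.
#' @param convs_per_level convolutions per stage.
#' @param in_channels predictor channels (4: RGB + normalized elevation).
#' @return object of class `unet_spec`.
#' @export
unet_spec <- function(levels = 5L, kernel = 3L, pool = 2L,
                      base_filters = 16L, convs_per_level = 2L,
                      in_channels = 4L) {
  levels <- as.integer(levels); kernel <- as.integer(kernel)
  if (levels < 1) stop("levels must be >= 1")
  if (kernel %% 2 != 1) stop("kernel must be odd for same-size padding")
  if (pool != 2L) stop("only pool = 2 is supported")
  if (convs_per_level < 1) stop("convs_per_level must be >= 1")
  structure(list(levels = levels, kernel = kernel, pool = 2L,
                 base_filters = as.integer(base_filters),
                 convs_per_level = as.integer(convs_per_level),
                 in_channels = as.integer(in_channels)),
            class = "unet_spec")
}

#' Per-stage feature depths of a spec
#'
#' @param spec a [unet_spec()].
#' @return integer vector of length `levels`: `base_filters * 2^(k-1)`.
#' @export
unet_depths <- function(spec) {
  as.integer(spec$base_filters * 2^(seq_len(spec$levels) - 1L))
}

#' Bottleneck spatial size for a given tile edge
#'
#' @param spec a [unet_spec()].
#' @param tile_px input tile edge in pixels.
#' @return `tile_px / pool^(levels - 1)`.
#' @export
unet_bottleneck_px <- function(spec, tile_px) {
  d <- as.integer(spec$pool^(spec$levels - 1L))
  if (tile_px %% d != 0) {
    stop("tile size ", tile_px, " is not divisible by pool^(levels-1) = ", d)
  }
  as.integer(tile_px) %/% d
}

he_init <- function(nin, nout, fan_in) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / fan_in)), nin, nout)
}

#' Build a U-net model with randomly initialized weights
#'
#' Initialization is fan-in-scaled normal ("He"), drawn from the current RNG
#' stream (or from `seed` when given), so models are reproducible.
#'
#' @param spec a [unet_spec()].
#' @param seed optional integer seed for the weight draw.
#' @return object of class `unet_model` holding the spec and a named weight
#'   list (`enc<k>_conv<j>`, `up<k>`, `dec<k>_conv<j>`, `out`).
#' @export
build_unet <- function(spec = unet_spec(), seed = NULL) {
  stopifnot(inherits(spec, "unet_spec"))
  init <- function() {
    k <- spec$kernel
    f <- unet_depths(spec)
    w <- list()
    cin <- spec$in_channels
    for (lv in seq_len(spec$levels)) {
      for (j in seq_len(spec$convs_per_level)) {
        fan <- k * k * cin
        w[[sprintf("enc%d_conv%d", lv, j)]] <-
          list(W = he_init(fan, f[lv], fan), b = numeric(f[lv]))
        cin <- f[lv]
      }
    }
    for (lv in rev(seq_len(spec$levels - 1L))) {
      w[[sprintf("up%d", lv)]] <-
        list(W = he_init(f[lv + 1], 4L * f[lv], 4 * f[lv + 1]),
             b = numeric(f[lv]))
      cin <- 2L * f[lv]
      for (j in seq_len(spec$convs_per_level)) {
        fan <- k * k * cin
        w[[sprintf("dec%d_conv%d", lv, j)]] <-
          list(W = he_init(fan, f[lv], fan), b = numeric(f[lv]))
        cin <- f[lv]
      }
    }
    w[["out"]] <- list(W = he_init(f[1], 1L, f[1]), b = 0)
    w
  }
  weights <- if (is.null(seed)) init() else withr::with_seed(seed, init())
  structure(list(spec = spec, weights = weights), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  np <- sum(vapply(x$weights, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("<unet_model> %d levels, base %d, kernel %dx%d, %s parameters\n",
              x$spec$levels, x$spec$base_filters, x$spec$kernel,
              x$spec$kernel, format(np, big.mark = ",")))
  invisible(x)
}

# Batched tensors are cubes whose slices hold `n_batch` samples of C
# channels each, grouped per sample (slice (b-1)*C + c). Interleaved
# per-sample concatenation of two batched cubes:
concat_channels <- function(a, b, n_batch = 1L) {
  ca <- dim(a)[3] %/% n_batch
  cb <- dim(b)[3] %/% n_batch
  out <- array(0, c(dim(a)[1], dim(a)[2], n_batch * (ca + cb)))
  off <- rep((seq_len(n_batch) - 1L) * (ca + cb), each = ca)
  pos_a <- off + rep(seq_len(ca), n_batch)
  off <- rep((seq_len(n_batch) - 1L) * (ca + cb), each = cb)
  pos_b <- off + ca + rep(seq_len(cb), n_batch)
  out[, , pos_a] <- a
  out[, , pos_b] <- b
  list(out = out, pos_a = pos_a, pos_b = pos_b)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# layer traversal order shared with the fused C++ engine
unet_layer_order <- function(spec) {
  nm <- character(0)
  for (lv in seq_len(spec$levels)) {
    nm <- c(nm, sprintf("enc%d_conv%d", lv, seq_len(spec$convs_per_level)))
  }
  for (lv in rev(seq_len(spec$levels - 1L))) {
    nm <- c(nm, sprintf("up%d", lv),
            sprintf("dec%d_conv%d", lv, seq_len(spec$convs_per_level)))
  }
  c(nm, "out")
}

validate_forward_input <- function(spec, d, n_batch) {
  if (length(d) != 3 || d[3] != spec$in_channels * n_batch) {
    stop("expected ", spec$in_channels, " predictor channels, got ",
         if (length(d) == 3) d[3] / n_batch else "a non-3D array")
  }
  div <- spec$pool^(spec$levels - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("input ", d[1], " x ", d[2],
         " is not divisible by pool^(levels-1) = ", div)
  }
}

# Forward pass through the fused single-precision engine. `x` holds n_batch
# samples of in_channels slices each. Returns the probability map (matrix
# for a single sample, H x W x n_batch array otherwise) and, when
# `keep_cache`, an opaque context consumed by unet_backward().
unet_forward <- function(model, x, keep_cache = FALSE, n_batch = 1L) {
  spec <- model$spec
  validate_forward_input(spec, dim(x), n_batch)
  ord <- unet_layer_order(spec)
  res <- cpp_unet_fw(x, model$weights[ord], spec$levels,
                     spec$convs_per_level, spec$kernel, n_batch, keep_cache)
  p <- if (n_batch == 1L) res$p[, , 1] else res$p
  cache <- if (keep_cache) list(ctx = res$ctx, n_batch = n_batch)
  list(p = p, cache = cache)
}

# Backpropagation from dL/dp through the fused engine; returns per-weight
# gradients (summed over the batch) named like the weights.
unet_backward <- function(model, cache, p, gp) {
  spec <- model$spec
  nb <- cache$n_batch
  ord <- unet_layer_order(spec)
  pa <- array(p, c(dim(p)[1], dim(p)[2], nb))
  ga <- array(gp, dim(pa))
  g <- cpp_unet_bw(cache$ctx, model$weights[ord], pa, ga, spec$levels,
                   spec$convs_per_level, spec$kernel)
  names(g) <- ord
  g
}

# Reference forward pass: same network assembled layer-by-layer from the
# exported kernels (used to cross-check the fused engine).
unet_forward_ref <- function(model, x, keep_cache = FALSE, n_batch = 1L) {
  spec <- model$spec
  w <- model$weights
  d <- dim(x)
  if (length(d) != 3 || d[3] != spec$in_channels * n_batch) {
    stop("expected ", spec$in_channels, " predictor channels, got ",
         if (length(d) == 3) d[3] / n_batch else "a non-3D array")
  }
  div <- spec$pool^(spec$levels - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0) {
    stop("input ", d[1], " x ", d[2], " is not divisible by pool^(levels-1) = ", div)
  }
  k <- spec$kernel
  cache <- if (keep_cache) list(conv = list(), pool = list(), n_batch = n_batch)
  cur <- x
  skips <- vector("list", spec$levels)
  for (lv in seq_len(spec$levels)) {
    for (j in seq_len(spec$convs_per_level)) {
      nm <- sprintf("enc%d_conv%d", lv, j)
      out <- cpp_conv2d_fw(cur, w[[nm]]$W, w[[nm]]$b, k, TRUE, n_batch)
      if (keep_cache) cache$conv[[nm]] <- list(x = cur, a = out)
      cur <- out
    }
    skips[[lv]] <- cur
    if (lv < spec$levels) {
      mp <- cpp_maxpool2_fw(cur)
      if (keep_cache) cache$pool[[lv]] <- list(idx = mp$idx, H = dim(cur)[1],
                                               W = dim(cur)[2])
      cur <- mp$out
    }
  }
  for (lv in rev(seq_len(spec$levels - 1L))) {
    nm <- sprintf("up%d", lv)
    up <- cpp_upconv2_fw(cur, w[[nm]]$W, w[[nm]]$b, n_batch)
    if (keep_cache) cache$conv[[nm]] <- list(x = cur)
    cc <- concat_channels(skips[[lv]], up, n_batch)
    cur <- cc$out
    for (j in seq_len(spec$convs_per_level)) {
      nm <- sprintf("dec%d_conv%d", lv, j)
      out <- cpp_conv2d_fw(cur, w[[nm]]$W, w[[nm]]$b, k, TRUE, n_batch)
      if (keep_cache) cache$conv[[nm]] <- list(x = cur, a = out)
      cur <- out
    }
  }
  z <- cpp_conv2d_fw(cur, w$out$W, w$out$b, 1L, FALSE, n_batch)
  if (keep_cache) cache$conv[["out"]] <- list(x = cur, a = z)
  p <- if (n_batch == 1L) sigmoid(z[, , 1]) else sigmoid(z)
  list(p = p, cache = cache)
}

# Reference backward pass matching unet_forward_ref().
unet_backward_ref <- function(model, cache, p, gp) {
  spec <- model$spec
  w <- model$weights
  k <- spec$kernel
  nb <- cache$n_batch
  g <- list()
  gz <- array(gp * p * (1 - p), c(dim(p)[1], dim(p)[2], nb))
  bw <- cpp_conv2d_bw(cache$conv[["out"]]$x, w$out$W, gz, 1L, FALSE,
                      cache$conv[["out"]]$a, nb)
  g[["out"]] <- list(W = bw$gW, b = bw$gb)
  gcur <- bw$gx
  gskip <- vector("list", spec$levels)
  for (lv in seq_len(spec$levels - 1L)) {
    for (j in rev(seq_len(spec$convs_per_level))) {
      nm <- sprintf("dec%d_conv%d", lv, j)
      bw <- cpp_conv2d_bw(cache$conv[[nm]]$x, w[[nm]]$W, gcur, k, TRUE,
                          cache$conv[[nm]]$a, nb)
      g[[nm]] <- list(W = bw$gW, b = bw$gb)
      gcur <- bw$gx
    }
    nf <- dim(gcur)[3] %/% (2L * nb)
    off <- rep((seq_len(nb) - 1L) * 2L * nf, each = nf)
    gskip[[lv]] <- gcur[, , off + rep(seq_len(nf), nb), drop = FALSE]
    gup <- gcur[, , off + nf + rep(seq_len(nf), nb), drop = FALSE]
    nm <- sprintf("up%d", lv)
    bw <- cpp_upconv2_bw(cache$conv[[nm]]$x, w[[nm]]$W, gup, nb)
    g[[nm]] <- list(W = bw$gW, b = bw$gb)
    gcur <- bw$gx
  }
  for (lv in rev(seq_len(spec$levels))) {
    if (lv < spec$levels) {
      gcur <- cpp_maxpool2_bw(cache$pool[[lv]]$idx, gcur,
                              cache$pool[[lv]]$H, cache$pool[[lv]]$W)
      gcur <- gcur + gskip[[lv]]
    }
    for (j in rev(seq_len(spec$convs_per_level))) {
      nm <- sprintf("enc%d_conv%d", lv, j)
      bw <- cpp_conv2d_bw(cache$conv[[nm]]$x, w[[nm]]$W, gcur, k, TRUE,
                          cache$conv[[nm]]$a, nb)
      g[[nm]] <- list(W = bw$gW, b = bw$gb)
      gcur <- bw$gx
    }
  }
  g
}

#' Dice coefficient between a prediction and a binary reference
#'
#' `(2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)`.
#' The training loss is `1 - dice_coefficient`. The smoothing term guards
#' against empty masks.
#'
#' @param pred real grid in [0, 1].
#' @param truth binary grid of the same dimensions.
#' @param smooth small positive constant.
#' @return real in (0, 1] (in [0, 1] as smooth tends to 0).
#' @export
dice_coefficient <- function(pred, truth, smooth = 1) {
  if (!identical(dim(pred), dim(truth))) {
    stop("shape mismatch: pred ", paste(dim(pred), collapse = " x "),
         " vs truth ", paste(dim(truth), collapse = " x "))
  }
  (2 * sum(pred * truth) + smooth) / (sum(pred) + sum(truth) + smooth)
}

#' Dice loss
#'
#' @inheritParams dice_coefficient
#' @return `1 - dice_coefficient(pred, truth, smooth)`.
#' @export
dice_loss <- function(pred, truth, smooth = 1) {
  1 - dice_coefficient(pred, truth, smooth)
}

# dL/dpred of the dice loss, closed form
dice_loss_grad <- function(pred, truth, smooth = 1) {
  den <- sum(pred) + sum(truth) + smooth
  num <- 2 * sum(pred * truth) + smooth
  -(2 * truth * den - num) / den^2
}

#' Predict the segmentation of one predictor tile
#'
#' @param model a `unet_model`.
#' @param predictors tile array (H x W x in_channels), channels conditioned
#'   as produced by the tiling stage.
#' @param threshold decision threshold on the probabilities.
#' @return object of class `segmentation_output` with `probabilities`,
#'   `threshold` and binary `labels` (1 where probability >= threshold).
#' @export
predict_tile <- function(model, predictors, threshold = 0.5) {
  stopifnot(inherits(model, "unet_model"))
  p <- unet_forward(model, predictors)$p
  structure(list(probabilities = p, threshold = threshold,
                 labels = (p >= threshold) * 1),
            class = "segmentation_output")
}

#' Save model weights (spec embedded) to a single file
#'
#' @param model a `unet_model`.
#' @param path output `.rds` path.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(spec = unclass(model$spec), weights = model$weights), path)
  invisible(path)
}

#' Load model weights saved by [save_weights()]
#'
#' @param path `.rds` path.
#' @param spec optional [unet_spec()]; when given, the embedded spec must
#'   match or loading fails.
#' @return a `unet_model`.
#' @export
load_weights <- function(path, spec = NULL) {
  obj <- readRDS(path)
  emb <- structure(obj$spec, class = "unet_spec")
  if (!is.null(spec) && !identical(unclass(spec), unclass(emb))) {
    stop("weights file was saved for a different architecture spec")
  }
  structure(list(spec = emb, weights = obj$weights), class = "unet_model")
}
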