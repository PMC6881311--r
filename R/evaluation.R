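# Cover-stratified accuracy and bias on the independent validation tiles.
#
# Validation tiles are grouped by reference cover of the target class
# (0-33%, 33-66%, 66-100%) before averaging pixel accuracy, so the summary
# is not dominated by the majority class distribution. Bias is the mean
# residual between predicted and reference cover; over-prediction of the
# target class yields positive bias.

#' Pixel accuracy between predicted and reference labels
#'
#' @param pred_labels binary grid.
#' @param truth binary grid of the same dimensions.
#' @return fraction of pixels where prediction equals reference.
#' @export
pixel_accuracy <- function(pred_labels, truth) {
  if (!identical(dim(pred_labels), dim(truth))) {
    stop("shape mismatch: pred ", paste(dim(pred_labels), collapse = " x "),
         " vs truth ", paste(dim(truth), collapse = " x "))
  }
  mean(pred_labels == truth)
}

#' Cover stratum of a tile
#'
#' Strata partition [0, 1] with half-open intervals and the last closed:
#' 1 for [0, 1/3), 2 for [1/3, 2/3), 3 for [2/3, 1].
#'
#' @param cover real in [0, 1].
#' @return integer stratum index in 1:3 (vectorized).
#' @export
assign_stratum <- function(cover) {
  if (any(cover < 0 | cover > 1)) stop("cover must be within [0, 1]")
  findInterval(cover, c(1 / 3, 2 / 3)) + 1L
}

#' Cover-stratified accuracy and bias of a model on validation tiles
#'
#' Tile-level pixel accuracies are averaged within each cover stratum; the
#' summary accuracy is the unweighted mean over occupied strata (or the
#' tile-weighted mean with `aggregate = "weighted"`). Bias is the mean over
#' tiles of (predicted cover - reference cover); the pixel-pooled mean
#' residual is reported alongside for transparency.
#'
#' @param tiles list of validation tiles (`canopy_tile`), or a `tile_set`
#'   whose `validation` partition is used.
#' @param model a `unet_model`.
#' @param threshold probability threshold for the predicted labels.
#' @param aggregate `"unweighted"` (default) or `"weighted"` stratum
#'   aggregation.
#' @return object of class `evaluation_report`: `strata_bounds`,
#'   `per_stratum_accuracy` (NA for empty strata), `n_tiles_per_stratum`,
#'   `accuracy`, `bias`, `bias_pixel`, `threshold`, `aggregate`.
#' @export
stratified_accuracy <- function(tiles, model, threshold = 0.5,
                                aggregate = c("unweighted", "weighted")) {
  aggregate <- match.arg(aggregate)
  if (inherits(tiles, "tile_set")) tiles <- tiles$validation
  if (!length(tiles)) stop("validation set is empty")
  acc <- cov_ref <- cov_pred <- resid_px <- numeric(length(tiles))
  for (i in seq_along(tiles)) {
    tl <- tiles[[i]]
    p <- unet_forward(model, tl$predictors)$p
    lab <- (p >= threshold) * 1
    acc[i] <- pixel_accuracy(lab, tl$mask)
    cov_ref[i] <- tl$cover
    cov_pred[i] <- mean(lab)
    resid_px[i] <- mean(lab - tl$mask)
  }
  stratum <- assign_stratum(cov_ref)
  per <- n_per <- rep(NA_real_, 3)
  for (s in 1:3) {
    in_s <- stratum == s
    n_per[s] <- sum(in_s)
    if (any(in_s)) per[s] <- mean(acc[in_s])
  }
  if (any(n_per == 0)) {
    message("empty cover stratum(s): ", paste(which(n_per == 0), collapse = ", "),
            "; excluded from the summary accuracy")
  }
  summary_acc <- if (aggregate == "unweighted") mean(per, na.rm = TRUE) else
    sum(per * n_per, na.rm = TRUE) / sum(n_per[!is.na(per)])
  structure(list(strata_bounds = c(0, 1 / 3, 2 / 3, 1),
                 per_stratum_accuracy = per,
                 n_tiles_per_stratum = as.integer(n_per),
                 accuracy = summary_acc,
                 bias = mean(cov_pred - cov_ref),
                 bias_pixel = mean(resid_px),
                 threshold = threshold, aggregate = aggregate),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  stratified accuracy: %.4f (%s over occupied strata)\n",
              x$accuracy, x$aggregate))
  for (s in 1:3) {
    cat(sprintf("  stratum %d [%0.2f, %0.2f%s: accuracy %s, n = %d\n",
                s, x$strata_bounds[s], x$strata_bounds[s + 1],
                if (s == 3) "]" else ")",
                ifelse(is.na(x$per_stratum_accuracy[s]), "-",
                       sprintf("%.4f", x$per_stratum_accuracy[s])),
                x$n_tiles_per_stratum[s]))
  }
  cat(sprintf("  bias (tile cover residual): %+.4f  (pixel-pooled: %+.4f)\n",
              x$bias, x$bias_pixel))
  invisible(x)
}

#' Serialize an evaluation report to JSON (lossless round trip)
#'
#' @param report an `evaluation_report`.
#' @param path output `.json` path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#'
#' @param path `.json` path.
#' @return an `evaluation_report`.
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$per_stratum_accuracy <- as.numeric(obj$per_stratum_accuracy)
  obj$n_tiles_per_stratum <- as.integer(obj$n_tiles_per_stratum)
  structure(obj, class = "evaluation_report")
}
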