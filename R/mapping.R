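# Map reconstruction: apply a trained model across a scene extract on a
# regular grid of tile-sized cells and merge the per-tile segmentations
# into one georeferenced raster.

# cell start offsets covering `total_px` with `tile_px` cells: abutting
# full cells, plus a final cell anchored flush to the far edge when the
# extent is not an exact multiple (its overlap takes the later prediction)
grid_starts <- function(total_px, tile_px) {
  if (total_px < tile_px) {
    stop("extract extent ", total_px, " px is smaller than one ", tile_px,
         " px tile")
  }
  s <- seq(0L, total_px - tile_px, by = tile_px)
  if (s[length(s)] + tile_px < total_px) s <- c(s, total_px - tile_px)
  as.integer(s)
}

#' Apply a model across a scene extract and merge tile segmentations
#'
#' The extract is covered by a regular grid of `tile_px` cells; each cell's
#' predictors are assembled exactly as during training (including per-tile
#' elevation normalization), predicted, and placed back at its origin.
#' When the extract is not a multiple of `tile_px`, the last row/column of
#' cells is anchored flush to the far edge; overlapping pixels take the
#' later cell's prediction (`merge = "overwrite"`) or the mean
#' (`merge = "average"`). Labels are derived from the merged probabilities
#' by one global threshold.
#'
#' @param scene a `canopy_scene`.
#' @param model a `unet_model`.
#' @param extract_window map-coordinate rectangle `c(xmin, ymin, xmax, ymax)`;
#'   `NULL` maps the full scene.
#' @param tile_px grid cell edge in pixels.
#' @param threshold label threshold on the merged probabilities.
#' @param merge overlap policy for flush edge cells.
#' @return object of class `segmentation_map`: `probabilities`, `labels`,
#'   `geotransform`, `crs_id`, `extent_m`.
#' @export
map_extract <- function(scene, model, extract_window = NULL, tile_px = 128L,
                        threshold = 0.5, merge = c("overwrite", "average")) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(model, "unet_model"))
  merge <- match.arg(merge)
  gt <- scene$geotransform
  H <- nrow(scene$dem); W <- ncol(scene$dem)
  if (is.null(extract_window)) {
    r0 <- 0L; c0 <- 0L; nr <- H; nc <- W
  } else {
    ew <- as.numeric(extract_window)
    c0 <- as.integer(round((ew[1] - gt[1]) / gt[2]))
    c1 <- as.integer(round((ew[3] - gt[1]) / gt[2]))
    r0 <- as.integer(round((ew[4] - gt[4]) / gt[6]))
    r1 <- as.integer(round((ew[2] - gt[4]) / gt[6]))
    if (r0 < 0 || c0 < 0 || r1 > H || c1 > W || r1 <= r0 || c1 <= c0) {
      stop("extract window outside the scene")
    }
    nr <- r1 - r0; nc <- c1 - c0
  }
  rows <- grid_starts(nr, tile_px)
  cols <- grid_starts(nc, tile_px)
  prob <- matrix(0, nr, nc)
  cnt <- if (merge == "average") matrix(0L, nr, nc) else NULL
  for (rs in rows) {
    for (cs in cols) {
      pred <- extract_predictors(scene$rgb, scene$dem, r0 + rs, c0 + cs,
                                 tile_px)
      p <- unet_forward(model, pred)$p
      ri <- (rs + 1):(rs + tile_px); ci <- (cs + 1):(cs + tile_px)
      if (merge == "overwrite") {
        prob[ri, ci] <- p
      } else {
        prob[ri, ci] <- prob[ri, ci] + p
        cnt[ri, ci] <- cnt[ri, ci] + 1L
      }
    }
  }
  if (merge == "average") prob <- prob / cnt
  gt2 <- gt
  gt2[1] <- gt[1] + c0 * gt[2]
  gt2[4] <- gt[4] + r0 * gt[6]
  structure(list(probabilities = prob, labels = (prob >= threshold) * 1,
                 geotransform = gt2, crs_id = scene$crs_id,
                 extent_m = c(nc * gt[2], nr * -gt[6])),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d x %d px (%.1f x %.1f m), %.3f labelled\n",
              nrow(x$probabilities), ncol(x$probabilities),
              x$extent_m[1], x$extent_m[2], mean(x$labels)))
  invisible(x)
}

#' Write a segmentation map (probability + label rasters)
#'
#' @param map a `segmentation_map`.
#' @param dir output directory.
#' @export
write_segmentation_map <- function(map, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(raster_grid(map$probabilities + 0.0, map$geotransform,
                           map$crs_id),
               file.path(dir, "probability.tif"))
  write_raster(raster_grid(map$labels, map$geotransform, map$crs_id),
               file.path(dir, "labels.tif"))
  invisible(dir)
}
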