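# Regular-grid tile sampling and train/hold-off/validation splitting.
#
# Candidate tile origins sit on a regular grid with metric spacing anchored
# at the scene's upper-left pixel; a seeded random subset of the candidates
# that fit fully inside the scene is drawn ("randomly sampled ... using a
# regular grid"). The spacing must be at least one tile edge so sampled
# windows can never overlap. Tiles crossing the scene edge are discarded,
# not padded.

#' Tile sampling specification
#'
#' @param tile_px tile edge length in pixels.
#' @param grid_spacing_m distance between candidate grid origins in metres;
#'   must be >= `tile_px * gsd` (overlap-free guarantee).
#' @param max_tiles cap on the number of sampled tiles.
#' @param train_fraction fraction of sampled tiles used for model fitting
#'   (the rest are the independent validation set).
#' @param holdoff_fraction fraction of the training tiles held off for the
#'   per-epoch accuracy check driving the checkpoint rule.
#' @param seed integer seed controlling candidate subsampling and the split.
#' @return object of class `tile_spec`.
#' @export
tile_spec <- function(tile_px = 128L, grid_spacing_m = 5, max_tiles = 4000L,
                      train_fraction = 0.666, holdoff_fraction = 0.20,
                      seed = 1L) {
  tile_px <- as.integer(tile_px)
  if (tile_px <= 0) stop("tile_px must be positive")
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (holdoff_fraction < 0 || holdoff_fraction >= 1) {
    stop("holdoff_fraction must be in [0, 1)")
  }
  if (max_tiles < 1) stop("max_tiles must be at least 1")
  structure(list(tile_px = tile_px, grid_spacing_m = grid_spacing_m,
                 max_tiles = as.integer(max_tiles),
                 train_fraction = train_fraction,
                 holdoff_fraction = holdoff_fraction,
                 seed = as.integer(seed)),
            class = "tile_spec")
}

# predictor block for a tile window: R, G, B scaled to [0, 1] and the
# elevation channel normalized to relative values within the tile's own
# window, then scaled to [0, 1] like the color bands. Shared verbatim by
# training-tile extraction and map-time inference.
extract_predictors <- function(rgb, dem, row0, col0, tile_px) {
  rs <- (row0 + 1):(row0 + tile_px)
  cs <- (col0 + 1):(col0 + tile_px)
  pred <- array(0, c(tile_px, tile_px, 4))
  pred[, , 1:3] <- rgb[rs, cs, ] / 255
  pred[, , 4] <- normalize_window_values(dem[rs, cs, drop = FALSE]) / 255
  pred
}

make_tile <- function(rgb, dem, mask, row0, col0, tile_px) {
  rs <- (row0 + 1):(row0 + tile_px)
  cs <- (col0 + 1):(col0 + tile_px)
  m <- mask[rs, cs]
  structure(list(predictors = extract_predictors(rgb, dem, row0, col0, tile_px),
                 mask = m, origin = c(row = row0, col = col0),
                 cover = mean(m)),
            class = "canopy_tile")
}

#' Cover fraction of a binary mask tile
#'
#' @param mask_tile binary matrix.
#' @return arithmetic mean of the mask values.
#' @export
tile_cover <- function(mask_tile) {
  if (any(!mask_tile %in% c(0, 1))) stop("mask tile must be binary")
  mean(mask_tile)
}

#' Sample training/hold-off/validation tiles from a scene
#'
#' @param scene a `canopy_scene`.
#' @param mask binary [raster_grid()] of the reference class, co-registered
#'   with the scene (e.g. [scene_mask()] or [rasterize_polygons()] output).
#' @param spec a [tile_spec()].
#' @return object of class `tile_set` with disjoint `train`, `holdoff` and
#'   `validation` lists of tiles, the spec, and provenance (seed, CRS).
#' @export
sample_tiles <- function(scene, mask, spec) {
  stopifnot(inherits(scene, "canopy_scene"), inherits(spec, "tile_spec"))
  gsd <- scene$geotransform[2]
  H <- nrow(scene$dem); W <- ncol(scene$dem)
  mvals <- if (inherits(mask, "raster_grid")) band_matrix(mask) else mask
  if (!identical(dim(mvals), c(H, W))) {
    stop("mask (", paste(dim(mvals), collapse = " x "),
         ") is not co-registered with the scene (", H, " x ", W, ")")
  }
  tile_m <- spec$tile_px * gsd
  if (spec$grid_spacing_m < tile_m - 1e-9) {
    stop("grid spacing ", spec$grid_spacing_m, " m is below the tile extent ",
         tile_m, " m; sampled tiles would overlap")
  }
  step_px <- spec$grid_spacing_m / gsd
  origins_axis <- function(total) {
    if (total < spec$tile_px) return(integer(0))
    ks <- seq(0L, floor((total - spec$tile_px) / step_px + 1e-9))
    o <- as.integer(round(ks * step_px))
    o[o + spec$tile_px <= total]
  }
  rows <- origins_axis(H); cols <- origins_axis(W)
  if (!length(rows) || !length(cols)) {
    stop("no ", spec$tile_px, " px tile fits the ", H, " x ", W, " px scene ",
         "on a ", spec$grid_spacing_m, " m grid")
  }
  cand <- expand.grid(row = rows, col = cols)
  withr::with_seed(spec$seed, {
    take <- min(nrow(cand), spec$max_tiles)
    sel <- cand[sample.int(nrow(cand), take), , drop = FALSE]
    tiles <- lapply(seq_len(take), function(i)
      make_tile(scene$rgb, scene$dem, mvals, sel$row[i], sel$col[i],
                spec$tile_px))
    ord <- sample.int(take)          # random split assignment, by tile
    n_pool <- round(spec$train_fraction * take)
    n_ho <- round(spec$holdoff_fraction * n_pool)
    ho_idx <- ord[seq_len(n_ho)]
    tr_idx <- ord[seq_len(n_pool)][-seq_len(n_ho)]
    va_idx <- ord[-seq_len(n_pool)]
    structure(list(train = tiles[tr_idx], holdoff = tiles[ho_idx],
                   validation = tiles[va_idx], spec = spec,
                   provenance = list(seed = spec$seed, crs_id = scene$crs_id,
                                     geotransform = scene$geotransform)),
              class = "tile_set")
  })
}

#' @export
print.tile_set <- function(x, ...) {
  cat(sprintf("<tile_set> %d train / %d hold-off / %d validation (%d px tiles)\n",
              length(x$train), length(x$holdoff), length(x$validation),
              x$spec$tile_px))
  invisible(x)
}

#' Persist a tile set as paired TIFFs plus a plain-text manifest
#'
#' @param tiles a `tile_set`.
#' @param dir output directory.
#' @export
write_tileset <- function(tiles, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gt <- tiles$provenance$geotransform
  rows <- list()
  for (split in c("train", "holdoff", "validation")) {
    for (i in seq_along(tiles[[split]])) {
      tl <- tiles[[split]][[i]]
      id <- sprintf("%s_%04d", split, i)
      gt_t <- gt
      gt_t[1] <- gt[1] + tl$origin["col"] * gt[2]
      gt_t[4] <- gt[4] + tl$origin["row"] * gt[6]
      write_raster(raster_grid(round(tl$predictors * 255), gt_t,
                               tiles$provenance$crs_id),
                   file.path(dir, paste0(id, "_pred.tif")))
      write_raster(raster_grid(tl$mask, gt_t, tiles$provenance$crs_id),
                   file.path(dir, paste0(id, "_mask.tif")))
      rows[[id]] <- data.frame(id = id, split = split,
                               row = tl$origin["row"], col = tl$origin["col"],
                               cover = tl$cover)
    }
  }
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
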