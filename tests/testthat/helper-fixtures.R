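# Shared fixtures: all built in code at test time.

# small scene used across tests (cached per session)
small_scene <- local({
  sc <- NULL
  function() {
    if (is.null(sc)) {
      sc <<- generate_scene(scene_config(
        width_m = 12, height_m = 12, n_canopies = 6,
        canopy_radius_range_m = c(0.5, 2), seed = 7))
    }
    sc
  }
})

small_tileset <- local({
  ts <- NULL
  function() {
    if (is.null(ts)) {
      sc <- small_scene()
      ts <<- sample_tiles(sc, scene_mask(sc),
                          tile_spec(tile_px = 64, grid_spacing_m = 2,
                                    max_tiles = 30, seed = 5))
    }
    ts
  }
})

# a template raster grid with unit-free geometry
make_template <- function(H, W, gsd = 1, x0 = 0, y0 = H * gsd,
                          crs = "EPSG:32719") {
  raster_grid(array(0, c(H, W, 1)), c(x0, gsd, 0, y0, 0, -gsd), crs_id = crs)
}

# axis-aligned rectangle polygon in map coordinates
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

# random star-convex polygon within a map-extent box
random_blob <- function(x0, y0, x1, y1, rmax = NULL) {
  if (is.null(rmax)) rmax <- 0.25 * min(x1 - x0, y1 - y0)
  r0 <- runif(1, 0.3 * rmax, rmax)
  cx <- runif(1, x0 + 1.4 * r0, x1 - 1.4 * r0)
  cy <- runif(1, y0 + 1.4 * r0, y1 - 1.4 * r0)
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  r <- r0 * (1 + 0.25 * sin(3 * th + runif(1, 0, 2 * pi)) +
               0.15 * cos(5 * th + runif(1, 0, 2 * pi)))
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# brute-force rasterization oracle: point-in-polygon test of every pixel
# center via mgcv::in.out (independent of the scanline implementation)
rasterize_oracle <- function(polygons, template) {
  d <- dim(template$values)
  gt <- template$geotransform
  rows <- rep(seq_len(d[1]) - 1, times = d[2])
  cols <- rep(seq_len(d[2]) - 1, each = d[1])
  xy <- px_center_xy_pub(gt, rows, cols)
  inside <- rep(FALSE, nrow(xy))
  for (ring in polygons) {
    bnd <- rbind(ring, ring[1, ])
    inside <- inside | mgcv::in.out(bnd, xy)
  }
  matrix(as.numeric(inside), d[1], d[2])
}

px_center_xy_pub <- function(gt, row, col) {
  cbind(gt[1] + (col + 0.5) * gt[2], gt[4] + (row + 0.5) * gt[6])
}

# tiny deterministic tile for augmentation tests
marker_tile <- function(tile_px = 32, r = 10, c = 20) {
  pred <- array(0, c(tile_px, tile_px, 4))
  mask <- matrix(0, tile_px, tile_px)
  pred[r + 1, c + 1, ] <- 1
  mask[r + 1, c + 1] <- 1
  structure(list(predictors = pred, mask = mask,
                 origin = c(row = 0L, col = 0L), cover = mean(mask)),
            class = "canopy_tile")
}
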