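test_that("candidate grid follows metric spacing and containment", {
  # 30 m scene, 5 m grid, 128-px tiles (3.84 m): origins at 0,5,...,25 m on
  # each axis and every window fits, so 36 candidates exist
  sc <- generate_scene(scene_config(width_m = 30, height_m = 30,
                                    n_canopies = 0, seed = 1))
  ts <- sample_tiles(sc, scene_mask(sc),
                     tile_spec(tile_px = 128, grid_spacing_m = 5,
                               max_tiles = 1000, seed = 2))
  n <- length(ts$train) + length(ts$holdoff) + length(ts$validation)
  expect_identical(n, 36L)
  origins <- do.call(rbind, lapply(c(ts$train, ts$holdoff, ts$validation),
                                   function(t) t$origin))
  steps_m <- sort(unique(origins[, "row"])) * 0.03
  expect_equal(steps_m, seq(0, 25, by = 5), tolerance = 0.03)
})

test_that("overlap-free guarantee is enforced and windows are disjoint", {
  sc <- small_scene()
  expect_error(
    sample_tiles(sc, scene_mask(sc),
                 tile_spec(tile_px = 128, grid_spacing_m = 3)),
    "3 m is below the tile extent 3.84 m")
  # property: over random specs satisfying the guarantee, all sampled
  # windows are pairwise disjoint (interval arithmetic over all pairs)
  set.seed(8)
  for (i in 1:5) {
    tp <- sample(c(32L, 64L), 1)
    spacing <- tp * 0.03 + runif(1, 0, 2)
    ts <- sample_tiles(sc, scene_mask(sc),
                       tile_spec(tile_px = tp, grid_spacing_m = spacing,
                                 max_tiles = 60, seed = i))
    tiles <- c(ts$train, ts$holdoff, ts$validation)
    org <- do.call(rbind, lapply(tiles, function(t) t$origin))
    for (a in seq_len(nrow(org) - 1)) {
      overlaps <- abs(org[-(1:a), "row", drop = FALSE] - org[a, "row"]) < tp &
        abs(org[-(1:a), "col", drop = FALSE] - org[a, "col"]) < tp
      expect_false(any(overlaps))
    }
  }
})

test_that("tiles partition into disjoint splits with the configured fractions", {
  ts <- small_tileset()
  n <- length(ts$train) + length(ts$holdoff) + length(ts$validation)
  key <- function(t) paste(t$origin, collapse = "_")
  keys <- c(vapply(ts$train, key, ""), vapply(ts$holdoff, key, ""),
            vapply(ts$validation, key, ""))
  expect_identical(anyDuplicated(keys), 0L)
  n_pool <- length(ts$train) + length(ts$holdoff)
  expect_equal(n_pool, round(0.666 * n))
  expect_equal(length(ts$holdoff), round(0.20 * n_pool))
})

test_that("sampling is deterministic given (scene, spec, seed)", {
  sc <- small_scene()
  spec <- tile_spec(tile_px = 64, grid_spacing_m = 2, max_tiles = 20, seed = 9)
  a <- sample_tiles(sc, scene_mask(sc), spec)
  b <- sample_tiles(sc, scene_mask(sc), spec)
  expect_identical(lapply(a$train, `[[`, "predictors"),
                   lapply(b$train, `[[`, "predictors"))
  expect_identical(lapply(a$validation, `[[`, "origin"),
                   lapply(b$validation, `[[`, "origin"))
})

test_that("tile predictors crop the scene and normalize channels", {
  sc <- small_scene()
  ts <- small_tileset()
  tl <- ts$train[[1]]
  rs <- tl$origin["row"] + 1:64
  cs <- tl$origin["col"] + 1:64
  # RGB channels are the scene pixels scaled by 1/255
  expect_equal(tl$predictors[, , 1] * 255, sc$rgb[rs, cs, 1])
  expect_equal(tl$predictors[, , 3] * 255, sc$rgb[rs, cs, 3])
  # elevation channel is the window-normalized DEM in [0, 1],
  # touching both endpoints
  expect_equal(min(tl$predictors[, , 4]), 0)
  expect_equal(max(tl$predictors[, , 4]), 1)
  dm <- sc$dem[rs, cs]
  expect_equal(tl$predictors[, , 4],
               (dm - min(dm)) / (max(dm) - min(dm)))
  # mask and cover
  expect_equal(tl$cover, mean(tl$mask))
})

test_that("tile_cover is the mean of the mask", {
  expect_equal(tile_cover(matrix(0, 128, 128)), 0)
  m <- matrix(0, 128, 128); m[1:32, 1:128] <- 1          # 4096 ones
  expect_equal(tile_cover(m), 0.25)
  half <- matrix(rep(c(0, 1), 8192), 128, 128)
  expect_equal(tile_cover(half), 0.5)
  expect_error(tile_cover(matrix(0.5, 2, 2)), "binary")
})

test_that("no fitting tile yields an informative error", {
  sc <- generate_scene(scene_config(width_m = 3, height_m = 3,
                                    n_canopies = 0, seed = 1))
  expect_error(sample_tiles(sc, scene_mask(sc),
                            tile_spec(tile_px = 128, grid_spacing_m = 5)),
               "no 128 px tile fits")
})

test_that("tile set persists with a manifest", {
  dir <- withr::local_tempdir()
  ts <- small_tileset()
  write_tileset(ts, dir)
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE, sep = "\t")
  n <- length(ts$train) + length(ts$holdoff) + length(ts$validation)
  expect_identical(nrow(man), n)
  expect_setequal(unique(man$split), c("train", "holdoff", "validation"))
  expect_true(all(file.exists(file.path(dir, paste0(man$id, "_pred.tif")))))
})
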