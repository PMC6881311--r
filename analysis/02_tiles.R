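#!/usr/bin/env Rscript
# Stage 2 — sample training/hold-off/validation tiles.
#
# Candidate origins on a regular 2 m grid (>= one 64-px tile edge at 3 cm,
# so windows cannot overlap); a seeded random subset is drawn and split
# 66.6% / 33.3% into fitting and validation, with 20% of the fitting tiles
# held off for the per-epoch checkpoint metric. Each tile carries R, G, B
# in [0,1] plus the tile-wise normalized elevation channel, and its binary
# reference mask.

suppressPackageStartupMessages(library(canopyseg))
seed <- 42L

scene <- read_scene("results/scene")
spec <- tile_spec(tile_px = 64L, grid_spacing_m = 2, max_tiles = 220L,
                  seed = canopyseg:::stage_seed(seed, "tiles"))
tiles <- sample_tiles(scene, scene_mask(scene), spec)
write_tileset(tiles, "results/tiles")

covers <- vapply(c(tiles$train, tiles$holdoff, tiles$validation),
                 `[[`, 0, "cover")
cat(sprintf("tiles: %d train / %d hold-off / %d validation (64 px, 2 m grid)\n",
            length(tiles$train), length(tiles$holdoff),
            length(tiles$validation)))
cat(sprintf("cover strata (all tiles): %d low / %d mid / %d high\n",
            sum(assign_stratum(covers) == 1), sum(assign_stratum(covers) == 2),
            sum(assign_stratum(covers) == 3)))
cat("wrote results/tiles/ (paired predictor/mask tiles + manifest.tsv)\n")
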