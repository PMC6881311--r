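#!/usr/bin/env Rscript
# Stage 3 — train the U-net.
#
# Desk-scale profile: 4 encoder levels with 16 base filters on 64-px tiles
# (the same 8-px bottleneck as the full-scale 5-level/128-px reference),
# dice loss, RMSprop at learning rate 1e-4, batch 16, 10 epochs x 80 steps
# with on-the-fly shear/rotation/shift/flip augmentation. Epoch weights are
# retained only when hold-off accuracy surpasses the last accepted epoch.

suppressPackageStartupMessages(library(canopyseg))
seed <- 42L

scene <- read_scene("results/scene")
tiles <- sample_tiles(scene, scene_mask(scene),
                      tile_spec(tile_px = 64L, grid_spacing_m = 2,
                                max_tiles = 220L,
                                seed = canopyseg:::stage_seed(seed, "tiles")))
model <- build_unet(unet_spec(levels = 4L, base_filters = 16L),
                    seed = canopyseg:::stage_seed(seed, "model"))
fit <- train(model, tiles, augment_config(),
             train_config(epochs = 10L, steps_per_epoch = 80L,
                          batch_size = 16L,
                          seed = canopyseg:::stage_seed(seed, "train"),
                          verbose = TRUE))

dir.create("results", showWarnings = FALSE)
write_trainlog(fit$log, "results/trainlog.tsv")
save_weights(fit$model, "results/weights.rds")
cat(sprintf("best epoch: %d (hold-off accuracy %.4f)\n", fit$best_epoch,
            max(fit$log$holdoff_accuracy[fit$log$accepted])))
cat("wrote results/trainlog.tsv and results/weights.rds\n")
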