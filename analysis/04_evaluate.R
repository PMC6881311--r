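#!/usr/bin/env Rscript
# Stage 4 — cover-stratified validation.
#
# The independent validation tiles are grouped by reference cover of the
# target class (0-33%, 33-66%, 66-100%) before averaging pixel accuracy,
# so the summary is not dominated by the abundant low-cover tiles. Bias is
# the mean residual between predicted and reference cover (positive =
# over-prediction).

suppressPackageStartupMessages(library(canopyseg))
seed <- 42L

scene <- read_scene("results/scene")
tiles <- sample_tiles(scene, scene_mask(scene),
                      tile_spec(tile_px = 64L, grid_spacing_m = 2,
                                max_tiles = 220L,
                                seed = canopyseg:::stage_seed(seed, "tiles")))
model <- load_weights("results/weights.rds")

report <- stratified_accuracy(tiles, model)
write_report(report, "results/evaluation.json")
print(report)

# compact summary table (accuracy in percent, as commonly reported)
tab <- data.frame(
  target_class = "synthetic canopy",
  accuracy_pct = round(100 * report$accuracy, 1),
  bias = round(report$bias, 4),
  acc_low_pct = round(100 * report$per_stratum_accuracy[1], 1),
  acc_mid_pct = round(100 * report$per_stratum_accuracy[2], 1),
  acc_high_pct = round(100 * report$per_stratum_accuracy[3], 1))
write.table(tab, "results/evaluation.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote results/evaluation.{json,tsv}\n")
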