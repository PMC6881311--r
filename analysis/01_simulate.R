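#!/usr/bin/env Rscript
# Stage 1 — synthesize the study scene.
#
# A 30 m x 30 m UAV-like scene at 3 cm ground sampling distance: RGB
# orthoimagery whose target canopies differ from the background only in
# texture (mean colors matched exactly), a co-registered elevation model
# with sloping terrain and canopy-height bumps, and the reference canopy
# polygons. Written as GeoTIFF + GeoJSON under results/scene/.

suppressPackageStartupMessages(library(canopyseg))
seed <- 42L

cfg <- scene_config(seed = canopyseg:::stage_seed(seed, "scene"))
scene <- generate_scene(cfg)
write_scene(scene, "results/scene")

cat(sprintf("scene: %d x %d px at %.2f cm, %d canopies\n",
            nrow(scene$dem), ncol(scene$dem), 100 * cfg$gsd_m,
            length(scene$polygons)))
cat(sprintf("target-class cover: %.1f%% of the scene\n",
            100 * scene_cover_fraction(scene)))
cat(sprintf("mean RGB | target: %s | background: %s (matched by design)\n",
            paste(round(cfg$mean_color_target), collapse = "/"),
            paste(round(cfg$mean_color_background), collapse = "/")))
cat("wrote results/scene/{ortho.tif,dem.tif,reference.geojson}\n")
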