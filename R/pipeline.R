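# End-to-end run: one YAML configuration, one global seed fanned out to the
# stages, artifacts persisted under a run directory.

stage_names <- c("scene", "tiles", "model", "train", "augment", "evaluate")

# per-stage seeds derived from the global seed by a fixed affine mix
# (documented, deterministic, and kept within 32-bit integer range)
stage_seed <- function(global_seed, stage) {
  idx <- match(stage, stage_names)
  if (is.na(idx)) stop("unknown stage: ", stage)
  as.integer((as.numeric(global_seed) + 1000003 * idx) %% .Machine$integer.max)
}

default_run_config <- function() {
  list(seed = 42L,
       scene = list(),                       # scene_config() arguments
       tiles = list(tile_px = 128L, grid_spacing_m = 5, max_tiles = 4000L,
                    train_fraction = 0.666, holdoff_fraction = 0.20),
       augment = list(),                     # augment_config() arguments
       model = list(levels = 5L, kernel = 3L, base_filters = 16L,
                    in_channels = 4L),
       train = list(learning_rate = 1e-4, epochs = 20L,
                    steps_per_epoch = 2500L, batch_size = 16L),
       evaluate = list(threshold = 0.5, aggregate = "unweighted"),
       map = list(tile_px = NULL, threshold = 0.5, merge = "overwrite"))
}

#' Load and validate a run configuration
#'
#' @param x path to a YAML file, or a list with the same structure. Fields
#'   missing from the input fall back to the defaults of the respective
#'   stage constructors; unknown fields raise an error naming their path.
#' @return object of class `run_config`.
#' @export
run_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("run configuration must be a list or a YAML path")
  base <- default_run_config()
  unknown <- setdiff(names(cfg), c(names(base), "out_dir"))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(base[[nm]]) && !is.null(cfg[[nm]])) {
      sub <- cfg[[nm]]
      if (!is.list(sub)) stop("configuration field '", nm, "' must be a mapping")
      base[[nm]][names(sub)] <- sub
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  if (is.null(base$seed)) stop("missing required configuration field: seed")
  base$seed <- as.integer(base$seed)
  structure(base, class = "run_config")
}

#' Serialize a run configuration to YAML
#'
#' `run_config(write_run_config(cfg, path))` reproduces `cfg` exactly.
#'
#' @param cfg a `run_config`.
#' @param path output `.yaml` path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Execute the full pipeline: simulate, tile, train, evaluate, map
#'
#' Stages run in order with per-stage seeds derived from the global seed;
#' every artifact (scene rasters, tile manifest, training log, evaluation
#' report, segmentation map, manifest) is written under `out_dir`. A stage
#' failure aborts with the stage name; artifacts of completed stages remain
#' on disk for inspection.
#'
#' @param config a `run_config`, or anything [run_config()] accepts.
#' @param out_dir run directory, created if needed.
#' @return (invisibly) list with `scene`, `tiles`, `fit`, `report`, `map`
#'   and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- run_config(if (inherits(config, "run_config")) unclass(config) else config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(cfg, file.path(out_dir, "config.yaml"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  scene <- run_stage("simulate", {
    sc_args <- cfg$scene
    sc_args$seed <- stage_seed(cfg$seed, "scene")
    scene <- generate_scene(do.call(scene_config, sc_args))
    write_scene(scene, file.path(out_dir, "scene"))
    scene
  })

  tiles <- run_stage("tiles", {
    sp_args <- cfg$tiles
    sp_args$seed <- stage_seed(cfg$seed, "tiles")
    tiles <- sample_tiles(scene, scene_mask(scene), do.call(tile_spec, sp_args))
    write_tileset(tiles, file.path(out_dir, "tiles"))
    tiles
  })

  fit <- run_stage("train", {
    model <- build_unet(do.call(unet_spec, cfg$model),
                        seed = stage_seed(cfg$seed, "model"))
    tr_args <- cfg$train
    tr_args$seed <- stage_seed(cfg$seed, "train")
    fit <- train(model, tiles, do.call(augment_config, cfg$augment),
                 do.call(train_config, tr_args))
    write_trainlog(fit$log, file.path(out_dir, "trainlog.tsv"))
    save_weights(fit$model, file.path(out_dir, "weights.rds"))
    fit
  })

  report <- run_stage("evaluate", {
    report <- stratified_accuracy(tiles, fit$model,
                                  threshold = cfg$evaluate$threshold,
                                  aggregate = cfg$evaluate$aggregate)
    write_report(report, file.path(out_dir, "evaluation.json"))
    report
  })

  segmap <- run_stage("map", {
    tp <- cfg$map$tile_px
    if (is.null(tp)) tp <- cfg$tiles$tile_px
    segmap <- map_extract(scene, fit$model, tile_px = tp,
                          threshold = cfg$map$threshold,
                          merge = cfg$map$merge)
    write_segmentation_map(segmap, file.path(out_dir, "map"))
    segmap
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("canopyseg")),
    r_version = as.character(getRversion()),
    global_seed = cfg$seed,
    stage_seeds = as.list(stats::setNames(
      vapply(stage_names, stage_seed, 0L, global_seed = cfg$seed),
      stage_names)),
    scene_cover = scene_cover_fraction(scene),
    n_tiles = c(train = length(tiles$train), holdoff = length(tiles$holdoff),
                validation = length(tiles$validation)),
    best_epoch = fit$best_epoch)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(scene = scene, tiles = tiles, fit = fit, report = report,
                 map = segmap, out_dir = out_dir))
}

#' Desk-scale run profile
#'
#' A reduced configuration sized so the whole pipeline (scene synthesis,
#' tiling, training, evaluation, mapping) completes on one CPU in minutes:
#' the default 30 m synthetic scene, 64-px tiles on a 2 m grid, a 4-level
#' U-net with 16 base filters (the same 8-px bottleneck as a 5-level
#' network on 128-px tiles), and 10 epochs of 80 RMSprop steps at batch 16.
#'
#' @param seed global seed.
#' @return a `run_config`.
#' @export
desk_profile <- function(seed = 42L) {
  run_config(list(
    seed = as.integer(seed),
    scene = list(),
    tiles = list(tile_px = 64L, grid_spacing_m = 2, max_tiles = 220L),
    model = list(levels = 4L, base_filters = 16L),
    train = list(epochs = 10L, steps_per_epoch = 80L, batch_size = 16L),
    map = list(tile_px = 64L)))
}
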