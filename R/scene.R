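# Synthetic UAV-like scene generator.
#
# The generator emulates the statistical structure that texture-based canopy
# segmentation exploits: target and background share (near-)identical mean
# RGB so per-pixel color is uninformative, and the class signal lives in the
# spatial grain of band-limited noise textures. Canopies are star-convex
# blobs with size variation down to below-tile scale; a crescent on the
# down-sun side of each canopy is darkened as cast shadow; dark distractor
# blobs fall on the background as well, so darkness alone does not identify
# the target class. The elevation model is smooth sloping terrain plus
# canopy-height bumps aligned with the polygons.

#' Configuration for a synthetic scene
#'
#' Defaults describe the standard study scene used throughout the package:
#' a 30 m x 30 m extent at 3 cm ground sampling distance with two dozen
#' shrub-like canopies whose mean color matches the background exactly.
#'
#' @param width_m,height_m scene extent in metres; must be integer multiples
#'   of `gsd_m`.
#' @param gsd_m ground sampling distance (metres per pixel).
#' @param n_canopies number of target-class canopy blobs.
#' @param canopy_radius_range_m min/max base radius of a canopy in metres.
#' @param texture_params list with elements `target` and `background`, each a
#'   list of `grain_px` (speckle correlation length in pixels), `contrast`
#'   (texture standard deviation in 8-bit counts) and `anisotropy_deg`
#'   (orientation of elongated grain; 0 with `aniso_ratio = 1` is isotropic),
#'   plus `aniso_ratio` (along/across grain length ratio).
#' @param shadow_fraction fraction in [0, 1) controlling the width of the
#'   darkened crescent on each canopy (0 disables shadows).
#' @param shadow_darkness multiplicative RGB factor inside shadows; the
#'   photogrammetric height signal inside shadows is attenuated by the same
#'   factor (dense matching degrades with radiance).
#' @param n_background_canopies number of non-target vegetation canopies:
#'   rendered with background texture (visually indistinct) but carrying
#'   elevation bumps and cast-shadow crescents of their own, so neither
#'   darkness nor height alone identifies the target class; `NULL` scales
#'   with `n_canopies` (3/4 of it).
#' @param sparse_fraction fraction of canopies rendered as dot-patterned
#'   sparse canopies with sub-50% within-polygon cover.
#' @param sparse_cover within-polygon cover of the target texture for sparse
#'   canopies.
#' @param mean_color_target,mean_color_background RGB triplets (0-255);
#'   constrained to differ by at most `color_tolerance` per channel so class
#'   separability is carried by texture, not mean color.
#' @param color_tolerance maximum allowed per-channel mean-color difference.
#' @param terrain_relief_m amplitude of the smooth background terrain.
#' @param canopy_height_m elevation bump height over canopies.
#' @param seed integer random seed; identical configs yield identical scenes.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(width_m = 30, height_m = 30, gsd_m = 0.03,
                         n_canopies = 24,
                         canopy_radius_range_m = c(0.6, 3.5),
                         texture_params = list(
                           target = list(grain_px = 6, contrast = 22,
                                         anisotropy_deg = 35, aniso_ratio = 2.5),
                           background = list(grain_px = 1.3, contrast = 22,
                                             anisotropy_deg = 0, aniso_ratio = 1)),
                         shadow_fraction = 0.25, shadow_darkness = 0.35,
                         n_background_canopies = NULL,
                         sparse_fraction = 0.15, sparse_cover = 0.45,
                         mean_color_target = c(96, 108, 74),
                         mean_color_background = c(96, 108, 74),
                         color_tolerance = 10,
                         terrain_relief_m = 2, canopy_height_m = 1.2,
                         seed = 42) {
  for (nm in c("width_m", "height_m")) {
    v <- get(nm)
    if (abs(v / gsd_m - round(v / gsd_m)) > 1e-8) {
      stop(nm, " = ", v, " is not an integer multiple of gsd_m = ", gsd_m)
    }
  }
  if (length(canopy_radius_range_m) != 2 ||
      canopy_radius_range_m[1] > canopy_radius_range_m[2] ||
      canopy_radius_range_m[1] <= 0) {
    stop("canopy_radius_range_m must be increasing and positive")
  }
  if (n_canopies > 0 && canopy_radius_range_m[2] > min(width_m, height_m) / 2) {
    stop("maximum canopy radius ", canopy_radius_range_m[2],
         " m exceeds half the scene extent ", min(width_m, height_m) / 2, " m")
  }
  if (shadow_fraction < 0 || shadow_fraction >= 1) {
    stop("shadow_fraction must be in [0, 1)")
  }
  if (sparse_fraction < 0 || sparse_fraction > 1) {
    stop("sparse_fraction must be in [0, 1]")
  }
  if (max(abs(mean_color_target - mean_color_background)) > color_tolerance) {
    stop("mean colors of target and background differ by more than ",
         color_tolerance, " counts; the generator requires near-equal means")
  }
  if (is.null(n_background_canopies)) {
    n_background_canopies <- round(0.75 * n_canopies)
  }
  structure(list(width_m = width_m, height_m = height_m, gsd_m = gsd_m,
                 n_canopies = n_canopies,
                 canopy_radius_range_m = canopy_radius_range_m,
                 texture_params = texture_params,
                 shadow_fraction = shadow_fraction,
                 shadow_darkness = shadow_darkness,
                 n_background_canopies = as.integer(n_background_canopies),
                 sparse_fraction = sparse_fraction,
                 sparse_cover = sparse_cover,
                 mean_color_target = mean_color_target,
                 mean_color_background = mean_color_background,
                 color_tolerance = color_tolerance,
                 terrain_relief_m = terrain_relief_m,
                 canopy_height_m = canopy_height_m,
                 seed = seed),
            class = "scene_config")
}

# star-convex blob: radial harmonics on a circle, in map coords
star_blob <- function(cx, cy, r0, n_vert = 72) {
  k <- 2:5
  amp <- pmin(0.12, abs(rnorm(length(k), 0, 0.08)))
  phi <- runif(length(k), 0, 2 * pi)
  th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
  r <- r0 * (1 + colSums(amp * cos(outer(k, th) + phi)))
  r <- pmax(r, 0.25 * r0)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

# dense interpolation matrix sampling a coarse axis at fine/step positions
interp_matrix <- function(n_fine, n_coarse, step) {
  pos <- (seq_len(n_fine) - 1) / step
  i0 <- pmin(floor(pos), n_coarse - 2)
  fr <- pos - i0
  A <- matrix(0, n_fine, n_coarse)
  A[cbind(seq_len(n_fine), i0 + 1)] <- 1 - fr
  A[cbind(seq_len(n_fine), i0 + 2)] <- fr
  A
}

# smooth random field ~N(0,1) pointwise, correlation length ~grain_px:
# coarse white noise, separable bilinear upscale, light blur, restandardized
smooth_noise_field <- function(H, W, grain_px) {
  g <- max(grain_px, 1)
  ch <- max(2L, ceiling(H / g) + 2L); cw <- max(2L, ceiling(W / g) + 2L)
  coarse <- matrix(rnorm(ch * cw), ch, cw)
  up <- interp_matrix(H, ch, g) %*% coarse %*% t(interp_matrix(W, cw, g))
  f <- cpp_gaussian_blur(up, min(g / 2, 8))
  (f - mean(f)) / max(stats::sd(f), 1e-12)
}

# band-limited texture field: zero-mean, sd = contrast, grain via Gaussian
# smoothing of white noise, optional anisotropy by axis-wise smoothing and
# rotation of the field
texture_field <- function(H, W, grain_px, contrast, anisotropy_deg = 0,
                          aniso_ratio = 1) {
  z <- matrix(rnorm(H * W), H, W)
  sig <- grain_px / 2
  if (aniso_ratio > 1) {
    z <- cpp_gaussian_blur_aniso(z, sig * aniso_ratio, sig / sqrt(aniso_ratio))
    if (anisotropy_deg %% 180 != 0) {
      th <- anisotropy_deg * pi / 180
      cy <- (H - 1) / 2; cx <- (W - 1) / 2
      # inverse rotation about the center
      A <- matrix(c(cos(th), -sin(th), cy - cos(th) * cy + sin(th) * cx,
                    sin(th),  cos(th), cx - sin(th) * cy - cos(th) * cx),
                  2, 3, byrow = TRUE)
      z <- cpp_warp_affine(array(z, c(H, W, 1)), A, 1L)[, , 1]
    }
  } else {
    z <- cpp_gaussian_blur(z, sig)
  }
  (z - mean(z)) / max(stats::sd(z), 1e-12) * contrast
}

shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  sr <- max(1, 1 + dr):min(H, H + dr)
  sc <- max(1, 1 + dc):min(W, W + dc)
  if (length(sr) && length(sc)) out[sr, sc] <- m[sr - dr, sc - dc]
  out
}

#' Generate a synthetic scene
#'
#' Renders the orthoimagery, elevation model and reference polygons for a
#' [scene_config()]. With `sparse_fraction = 0` the polygons mark exactly the
#' pixels carrying target texture (before shadow darkening); sparse canopies
#' deliberately interleave background inside their polygons. Identical
#' configs (including seed) produce bit-identical scenes.
#'
#' @param config a [scene_config()].
#' @return object of class `canopy_scene`: `rgb` (H x W x 3, 8-bit values),
#'   `dem` (H x W metres), `polygons` (list of n x 2 map-coordinate rings),
#'   `geotransform`, `crs_id`, and auxiliary `layers` (reference `mask`,
#'   `paint` = pixels rendered with target texture, `shadow` = darkened
#'   target-canopy pixels, `bg_shadow` = darkened background pixels,
#'   `distractor_mask` = non-target vegetation canopies).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(cfg) {
  H <- as.integer(round(cfg$height_m / cfg$gsd_m))
  W <- as.integer(round(cfg$width_m / cfg$gsd_m))
  gsd <- cfg$gsd_m
  # placeholder projected CRS with metre units; origin in its valid area
  x0 <- 500000; y0 <- 6100000
  gt <- c(x0, gsd, 0, y0, 0, -gsd)

  # bbox-local rasterization (identical pixels to a full-scene template but
  # without holding a full-size matrix per canopy)
  rasterize_local <- function(poly) {
    r0 <- max(0L, as.integer(floor((y0 - max(poly[, 2])) / gsd)) - 1L)
    r1 <- min(H, as.integer(ceiling((y0 - min(poly[, 2])) / gsd)) + 1L)
    c0 <- max(0L, as.integer(floor((min(poly[, 1]) - x0) / gsd)) - 1L)
    c1 <- min(W, as.integer(ceiling((max(poly[, 1]) - x0) / gsd)) + 1L)
    gt_l <- c(x0 + c0 * gsd, gsd, 0, y0 - r0 * gsd, 0, -gsd)
    tmpl <- raster_grid(array(0, c(r1 - r0, c1 - c0, 1)), gt_l)
    list(rs = r0 + seq_len(r1 - r0), cs = c0 + seq_len(c1 - c0),
         m = band_matrix(rasterize_polygons(list(poly), tmpl)))
  }

  # --- canopy polygons -------------------------------------------------
  n <- cfg$n_canopies
  polys <- list()
  radii <- numeric(0)
  if (n > 0) {
    r0 <- runif(n, cfg$canopy_radius_range_m[1], cfg$canopy_radius_range_m[2])
    for (i in seq_len(n)) {
      m <- 1.35 * r0[i]  # star_blob radius never exceeds 1.35 * r0
      cx <- x0 + runif(1, m, cfg$width_m - m)
      cy <- y0 - runif(1, m, cfg$height_m - m)
      polys[[i]] <- star_blob(cx, cy, r0[i])
    }
    radii <- r0
  }
  locals <- lapply(polys, rasterize_local)
  mask <- matrix(0, H, W)
  for (L in locals) mask[L$rs, L$cs] <- pmax(mask[L$rs, L$cs], L$m)

  # --- sparse canopies -------------------------------------------------
  n_sparse <- round(cfg$sparse_fraction * n)
  sparse_ids <- if (n_sparse > 0) sample.int(n, n_sparse) else integer(0)
  paint <- mask
  if (length(sparse_ids)) {
    dots_field <- smooth_noise_field(H, W, 4)
    dots <- dots_field > quantile(dots_field, 1 - cfg$sparse_cover)
    for (i in sparse_ids) {
      L <- locals[[i]]
      sub <- paint[L$rs, L$cs]
      sub[L$m == 1 & !dots[L$rs, L$cs]] <- 0
      paint[L$rs, L$cs] <- sub
    }
    rm(dots_field, dots)
  }

  # --- textures and composition ---------------------------------------
  tp <- cfg$texture_params
  tex_t <- texture_field(H, W, tp$target$grain_px, tp$target$contrast,
                         tp$target$anisotropy_deg,
                         if (is.null(tp$target$aniso_ratio)) 1 else tp$target$aniso_ratio)
  tex_b <- texture_field(H, W, tp$background$grain_px, tp$background$contrast,
                         tp$background$anisotropy_deg,
                         if (is.null(tp$background$aniso_ratio)) 1 else tp$background$aniso_ratio)
  alpha <- cpp_gaussian_blur(paint, 1)  # gradual class transition over ~2 px
  gains <- c(1, 1.05, 0.9)              # shared luminance texture, slight chroma
  rgb <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    rgb[, , ch] <- (1 - alpha) * (cfg$mean_color_background[ch] + gains[ch] * tex_b) +
      alpha * (cfg$mean_color_target[ch] + gains[ch] * tex_t)
  }
  rm(tex_t, tex_b, alpha)

  # --- non-target vegetation (background canopies) ---------------------
  # Rendered with background texture, so they are visually indistinct, but
  # they carry elevation bumps and cast-shadow crescents of their own:
  # neither darkness nor height alone identifies the target class, exactly
  # as in scenes with mixed vegetation.
  n_bg <- cfg$n_background_canopies
  dist_mask <- matrix(0, H, W)
  dist_locals <- list()
  dist_radii <- numeric(0)
  if (n_bg > 0) {
    rng <- 0.8 * cfg$canopy_radius_range_m
    rb <- runif(n_bg, rng[1], rng[2])
    for (j in seq_len(n_bg)) {
      m <- 1.35 * rb[j]
      bx <- x0 + runif(1, m, cfg$width_m - m)
      by <- y0 - runif(1, m, cfg$height_m - m)
      L <- rasterize_local(star_blob(bx, by, rb[j]))
      L$m[mask[L$rs, L$cs] == 1] <- 0   # target canopies win overlaps
      dist_locals[[j]] <- L
      dist_mask[L$rs, L$cs] <- pmax(dist_mask[L$rs, L$cs], L$m)
    }
    dist_radii <- rb
  }

  # --- cast shadows ----------------------------------------------------
  shadow <- matrix(0, H, W)
  bg_shadow <- matrix(0, H, W)
  if (cfg$shadow_fraction > 0) {
    # sun from the north-west: crescents darken the south-east side
    u <- c(dr = -1, dc = -1) / sqrt(2)
    crescent <- function(msk, r_m) {
      w_px <- max(1L, as.integer(round(cfg$shadow_fraction * r_m / gsd)))
      msk == 1 & shift_mask(msk, round(u[1] * w_px), round(u[2] * w_px)) == 0
    }
    for (i in seq_along(locals)) {
      L <- locals[[i]]
      shadow[L$rs, L$cs] <- pmax(shadow[L$rs, L$cs], crescent(L$m, radii[i]))
    }
    for (j in seq_along(dist_locals)) {
      L <- dist_locals[[j]]
      sh <- crescent(L$m, dist_radii[j]) & mask[L$rs, L$cs] == 0
      bg_shadow[L$rs, L$cs] <- pmax(bg_shadow[L$rs, L$cs], sh)
    }
    fac <- 1 - pmin(1, shadow + bg_shadow) * (1 - cfg$shadow_darkness)
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] * fac
    rm(fac)
  }
  rgb[] <- round(pmin(pmax(rgb, 0), 255))
  rm(locals, dist_locals)

  # --- elevation model -------------------------------------------------
  az <- runif(1, 0, 2 * pi)
  rr <- matrix(seq_len(H), H, W) / H
  cc <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  plane <- cos(az) * rr + sin(az) * cc
  rm(rr, cc)
  plane <- (plane - mean(plane)) / max(max(plane) - min(plane), 1e-12)
  undul <- smooth_noise_field(H, W, max(2, round(8 / gsd / 4)))
  undul <- undul / max(max(undul) - min(undul), 1e-12)
  terrain <- 1200 + cfg$terrain_relief_m * (plane + 0.5 * undul)
  rm(plane, undul)
  # photogrammetric height: bumps for target and non-target canopies,
  # attenuated inside cast shadows — dense image matching degrades with
  # radiance, so deeply shadowed crown parts lose their height signal
  att <- 1 - pmin(1, shadow + bg_shadow) * (1 - cfg$shadow_darkness)
  bumps <- cfg$canopy_height_m *
    cpp_gaussian_blur((mask + 0.9 * dist_mask) * att, 2)
  dem <- terrain + bumps
  rm(att, bumps, terrain)

  structure(list(rgb = rgb, dem = dem, polygons = polys,
                 geotransform = gt, crs_id = "EPSG:32719",
                 layers = list(mask = mask, paint = paint,
                               shadow = shadow, bg_shadow = bg_shadow,
                               distractor_mask = dist_mask),
                 config = cfg),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("<canopy_scene> %d x %d px (%.3g m gsd), %d canopies, cover %.3f\n",
              nrow(x$dem), ncol(x$dem), x$geotransform[2],
              length(x$polygons), scene_cover_fraction(x)))
  invisible(x)
}

#' Fraction of the scene covered by rasterized reference polygons
#'
#' @param scene a `canopy_scene`.
#' @return real in [0, 1]: rasterized polygon pixels / total pixels.
#' @export
scene_cover_fraction <- function(scene) {
  stopifnot(inherits(scene, "canopy_scene"))
  sum(scene$layers$mask) / length(scene$layers$mask)
}

#' Reference mask of a scene as a raster grid
#'
#' @param scene a `canopy_scene`.
#' @return single-band binary [raster_grid()] co-registered with the scene.
#' @export
scene_mask <- function(scene) {
  raster_grid(scene$layers$mask, scene$geotransform, crs_id = scene$crs_id)
}

#' Write a scene to a directory (RGB TIFF, DEM TIFF, GeoJSON polygons)
#'
#' @param scene a `canopy_scene`.
#' @param dir output directory, created if needed.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_raster(raster_grid(scene$rgb, scene$geotransform, scene$crs_id),
               file.path(dir, "ortho.tif"))
  write_raster(raster_grid(scene$dem, scene$geotransform, scene$crs_id),
               file.path(dir, "dem.tif"))
  write_polygons(scene$polygons, file.path(dir, "reference.geojson"),
                 crs_id = scene$crs_id)
  invisible(dir)
}

#' Read a scene directory written by [write_scene()]
#'
#' The auxiliary layers (`mask`) are reconstructed by rasterizing the
#' polygons; render-time layers (`paint`, shadows) are not persisted.
#'
#' @param dir directory containing `ortho.tif`, `dem.tif`,
#'   `reference.geojson`.
#' @return a `canopy_scene` without generator-internal layers.
#' @export
read_scene <- function(dir) {
  ortho <- read_raster(file.path(dir, "ortho.tif"))
  dem <- read_raster(file.path(dir, "dem.tif"))
  if (!identical(dim(ortho$values)[1:2], dim(dem$values)[1:2]) ||
      !isTRUE(all.equal(ortho$geotransform, dem$geotransform))) {
    stop("ortho and DEM are not co-registered")
  }
  polys <- read_polygons(file.path(dir, "reference.geojson"))
  mask <- band_matrix(rasterize_polygons(polys, ortho))
  structure(list(rgb = ortho$values, dem = band_matrix(dem),
                 polygons = polys, geotransform = ortho$geotransform,
                 crs_id = ortho$crs_id,
                 layers = list(mask = mask), config = NULL),
            class = "canopy_scene")
}
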