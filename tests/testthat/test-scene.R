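test_that("scene dimensions follow extent and ground sampling distance", {
  sc <- generate_scene(scene_config(width_m = 30, height_m = 30, gsd_m = 0.03,
                                    n_canopies = 2, seed = 1))
  expect_identical(dim(sc$rgb), c(1000L, 1000L, 3L))
  expect_identical(dim(sc$dem), c(1000L, 1000L))
  expect_equal(sc$geotransform[2], 0.03)
})

test_that("degenerate and invalid configurations are handled", {
  sc0 <- generate_scene(scene_config(width_m = 6, height_m = 6,
                                     n_canopies = 0, seed = 2))
  expect_length(sc0$polygons, 0)
  expect_equal(scene_cover_fraction(sc0), 0)
  expect_error(scene_config(width_m = 10.01), "width_m")
  expect_error(scene_config(height_m = 7.07), "height_m")
  expect_error(scene_config(width_m = 6, height_m = 6,
                            canopy_radius_range_m = c(1, 4)),
               "exceeds half the scene extent")
  expect_error(scene_config(mean_color_target = c(200, 108, 74)),
               "near-equal")
  expect_error(scene_config(shadow_fraction = 1), "shadow_fraction")
})

test_that("identical configs give bit-identical scenes", {
  cfg <- scene_config(width_m = 9, height_m = 9, n_canopies = 5,
                      canopy_radius_range_m = c(0.5, 1.5), seed = 7)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$rgb, b$rgb)
  expect_identical(a$dem, b$dem)
  expect_identical(a$polygons, b$polygons)
})

test_that("polygons are valid, inside the extent, and mark the painted pixels", {
  cfg <- scene_config(width_m = 9, height_m = 9, n_canopies = 5,
                      canopy_radius_range_m = c(0.5, 1.5),
                      sparse_fraction = 0, seed = 3)
  sc <- generate_scene(cfg)
  gt <- sc$geotransform
  for (i in seq_along(sc$polygons)) {
    ring <- sc$polygons[[i]]
    expect_silent(canopyseg:::validate_polygon(ring, i))
    expect_gt(abs(canopyseg:::polygon_area(ring)), 0)
    expect_true(all(ring[, 1] >= gt[1] & ring[, 1] <= gt[1] + 9))
    expect_true(all(ring[, 2] <= gt[4] & ring[, 2] >= gt[4] - 9))
  }
  # with no sparse canopies, polygons mark exactly the target-texture pixels
  expect_identical(sc$layers$paint, sc$layers$mask)
})

test_that("sparse canopies interleave background but keep full polygons", {
  cfg <- scene_config(width_m = 9, height_m = 9, n_canopies = 6,
                      canopy_radius_range_m = c(0.8, 1.5),
                      sparse_fraction = 0.5, sparse_cover = 0.4, seed = 11)
  sc <- generate_scene(cfg)
  expect_lt(sum(sc$layers$paint), sum(sc$layers$mask))
  expect_true(all(sc$layers$paint <= sc$layers$mask))
})

test_that("scene cover fraction equals rasterized polygon share", {
  # one 10 m x 10 m square in a 100 m x 100 m scene covers 1% +- boundary
  sc <- generate_scene(scene_config(width_m = 100, height_m = 100, gsd_m = 0.5,
                                    n_canopies = 0, seed = 1))
  gt <- sc$geotransform
  sq <- rect_poly(gt[1] + 45, gt[4] - 55, gt[1] + 55, gt[4] - 45)
  sc$polygons <- list(sq)
  sc$layers$mask <- band_matrix(rasterize_polygons(list(sq), scene_mask(sc)))
  brute <- sum(rasterize_oracle(list(sq), scene_mask(sc)))
  expect_identical(sum(sc$layers$mask), brute)
  expect_equal(scene_cover_fraction(sc), 0.01,
               tolerance = 4 * 10 / 0.5 / 200^2)  # one boundary-pixel ring
  # full-cover and empty extremes
  sc$layers$mask <- matrix(1, 200, 200)
  expect_equal(scene_cover_fraction(sc), 1)
})

test_that("mean colors match while textures differ in grain", {
  sc <- small_scene()
  mask <- sc$layers$mask == 1
  shadowed <- (sc$layers$shadow + sc$layers$bg_shadow) > 0
  keep_t <- mask & !shadowed
  keep_b <- !mask & !shadowed
  for (ch in 1:3) {
    m_t <- mean(sc$rgb[, , ch][keep_t])
    m_b <- mean(sc$rgb[, , ch][keep_b])
    expect_lt(abs(m_t - m_b), 6)
  }
})

test_that("class signal is textural: RGB-linear near chance, local variance separates", {
  sc <- small_scene()
  mask <- sc$layers$mask
  set.seed(99)
  # balanced pixel sample
  id1 <- sample(which(mask == 1), 2000)
  id0 <- sample(which(mask == 0), 2000)
  idx <- c(id1, id0)
  y <- rep(c(1, 0), each = 2000)
  X <- cbind(sc$rgb[, , 1][idx], sc$rgb[, , 2][idx], sc$rgb[, , 3][idx])
  fit <- suppressWarnings(glm(y ~ X, family = binomial()))
  pred <- fitted(fit) >= 0.5
  bal_rgb <- (mean(pred[y == 1]) + mean(!pred[y == 0])) / 2
  expect_lt(bal_rgb, 0.60)          # near-chance on per-pixel color alone
  # local standard deviation at the coarse-grain scale separates classes
  lum <- (sc$rgb[, , 1] + sc$rgb[, , 2] + sc$rgb[, , 3]) / 3
  lsd <- canopyseg:::cpp_local_sd(lum, 3L)
  fit2 <- suppressWarnings(glm(y ~ lsd[idx], family = binomial()))
  pred2 <- fitted(fit2) >= 0.5
  bal_tex <- (mean(pred2[y == 1]) + mean(!pred2[y == 0])) / 2
  expect_gt(bal_tex, 0.75)
})

test_that("every polygon is rendered with target texture over >= 95% of its pixels", {
  cfg <- scene_config(width_m = 12, height_m = 12, n_canopies = 5,
                      canopy_radius_range_m = c(0.8, 2.5),
                      sparse_fraction = 0, seed = 13)
  sc <- generate_scene(cfg)
  # band-pass energy at the target grain scale: the fine background grain
  # is removed by the smoothing, the coarse target grain survives
  lum <- (sc$rgb[, , 1] + sc$rgb[, , 2] + sc$rgb[, , 3]) / 3
  energy <- canopyseg:::cpp_local_sd(canopyseg:::cpp_gaussian_blur(lum, 3), 5L)
  bg_med <- median(energy[sc$layers$mask == 0 & sc$layers$bg_shadow == 0])
  tmpl <- scene_mask(sc)
  for (i in seq_along(sc$polygons)) {
    pm <- band_matrix(rasterize_polygons(sc$polygons[i], tmpl)) == 1
    # geometric consistency: the polygon's rasterized pixels carry the
    # target texture field
    expect_gte(mean(sc$layers$paint[pm] == 1), 0.95)
    # and the texture is statistically distinguishable canopy-wide
    expect_gt(median(energy[pm]), 1.5 * bg_med)
  }
})

test_that("scene write/read round trip is co-registered and consistent", {
  dir <- withr::local_tempdir()
  sc <- small_scene()
  write_scene(sc, dir)
  back <- read_scene(dir)
  expect_identical(back$rgb, sc$rgb + 0.0)
  expect_lt(max(abs(back$dem - sc$dem)), 1e-3)
  expect_equal(back$geotransform, sc$geotransform)
  expect_identical(back$layers$mask, sc$layers$mask)
})
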