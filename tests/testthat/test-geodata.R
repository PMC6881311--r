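test_that("raster round trip preserves values, geotransform and CRS", {
  dir <- withr::local_tempdir()
  # 8-bit 3-band imagery: exact round trip
  set.seed(1)
  v8 <- array(sample(0:255, 4 * 5 * 3, replace = TRUE), c(4, 5, 3))
  g8 <- raster_grid(v8, c(500000, 0.03, 0, 6100000, 0, -0.03), "EPSG:32719")
  p8 <- file.path(dir, "rgb.tif")
  write_raster(g8, p8)
  r8 <- read_raster(p8)
  expect_identical(r8$values, v8 + 0.0)
  expect_equal(r8$geotransform, g8$geotransform)
  expect_identical(r8$crs_id, "EPSG:32719")
  expect_identical(dim(r8$values)[3], 3L)

  # float elevation: one round trip quantizes to storage precision,
  # a second round trip is exact
  vf <- matrix(1200 + rnorm(20), 4, 5)
  gf <- raster_grid(vf, c(0, 1, 0, 4, 0, -1), "EPSG:32719")
  pf <- file.path(dir, "dem.tif")
  write_raster(gf, pf)
  r1 <- read_raster(pf)
  expect_lt(max(abs(band_matrix(r1) - vf)), 1e-5)
  expect_identical(dim(r1$values)[3], 1L)
  write_raster(r1, pf)
  r2 <- read_raster(pf)
  expect_equal(r2$values, r1$values, tolerance = 1e-8)
})

test_that("read_raster error and warning contracts", {
  expect_error(read_raster("no/such/file.tif"), "does not exist")
  bad <- withr::local_tempfile(fileext = ".tif")
  writeLines("not a tiff", bad)
  expect_error(read_raster(bad), "cannot read raster")
  # missing sidecars: readable, but CRS unknown with a warning
  ok <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 3, 3), ok)
  expect_warning(expect_warning(r <- read_raster(ok), "unknown"), "world file")
  expect_identical(r$crs_id, "unknown")
})

test_that("polygon GeoJSON round trip", {
  dir <- withr::local_tempdir()
  polys <- list(rect_poly(1, 1, 4, 3), random_blob(0, 0, 10, 10))
  path <- file.path(dir, "polys.geojson")
  write_polygons(polys, path, crs_id = "EPSG:32719")
  back <- read_polygons(path)
  expect_length(back, 2)
  expect_equal(back[[1]][, "x"], polys[[1]][, "x"])
  expect_equal(back[[2]], polys[[2]], ignore_attr = TRUE)
  expect_identical(attr(back, "crs_id"), "EPSG:32719")
})

test_that("rasterize_polygons matches the stated pixel rules", {
  tmpl <- make_template(100, 100)
  # empty layer: all-zero mask, not an error
  empty <- rasterize_polygons(list(), tmpl)
  expect_equal(sum(empty$values), 0)
  expect_identical(dim(empty$values)[1:2], c(100L, 100L))
  # rectangle covering exactly pixel centers of rows 10-19, cols 10-19
  # (pixel centers at col + 0.5; y counts down from 100)
  rect <- rect_poly(10, 100 - 20, 20, 100 - 10)
  m <- band_matrix(rasterize_polygons(list(rect), tmpl))
  expect_equal(sum(m), 100)
  expect_equal(sum(m[11:20, 11:20]), 100)
  # union of overlapping polygons equals the union mask
  r2 <- rect_poly(15, 100 - 25, 25, 100 - 15)
  m1 <- band_matrix(rasterize_polygons(list(rect), tmpl))
  m2 <- band_matrix(rasterize_polygons(list(r2), tmpl))
  mu <- band_matrix(rasterize_polygons(list(rect, r2), tmpl))
  expect_identical(mu, pmax(m1, m2))
})

test_that("invalid polygons are rejected with their index", {
  tmpl <- make_template(20, 20)
  bowtie <- cbind(x = c(0, 10, 0, 10), y = c(0, 10, 10, 0))
  expect_error(rasterize_polygons(list(rect_poly(1, 1, 3, 3), bowtie), tmpl),
               "polygon 2")
  degenerate <- cbind(x = c(0, 5, 10), y = c(0, 0, 0))
  expect_error(rasterize_polygons(list(degenerate), tmpl), "zero area")
})

test_that("rasterization area agrees with polygon area within the boundary bound", {
  set.seed(42)
  tmpl <- make_template(128, 128)
  for (i in 1:20) {
    poly <- random_blob(0, 0, 128, 128)
    m <- band_matrix(rasterize_polygons(list(poly), tmpl))
    a_poly <- abs(canopyseg:::polygon_area(poly))
    a_mask <- sum(m)            # pixel area = 1
    bound <- canopyseg:::polygon_perimeter(poly) * 1.0
    expect_lt(abs(a_mask - a_poly), bound)
  }
})

test_that("normalize_dem maps window extrema to 0 and 255", {
  g <- raster_grid(matrix(c(10, 20, 30, 5, 5, 7), 1), c(0, 1, 0, 1, 0, -1))
  out <- normalize_dem(g, c(0L, 1L, 0L, 3L))
  expect_equal(as.numeric(band_matrix(out)), c(0, 127.5, 255))
  out2 <- normalize_dem(raster_grid(matrix(c(2, 4, 8), 1), c(0, 1, 0, 1, 0, -1)))
  expect_equal(as.numeric(band_matrix(out2)), c(0, 85, 255))
  # degenerate constant window: all zeros by convention
  expect_message(
    cz <- normalize_dem(g, c(0L, 1L, 3L, 5L)), "constant")
  expect_equal(as.numeric(band_matrix(cz)), c(0, 0))
  # always within [0, 255]
  set.seed(3)
  gg <- raster_grid(matrix(rnorm(400, 1200, 5), 20), c(0, 1, 0, 20, 0, -1))
  nn <- band_matrix(normalize_dem(gg))
  expect_gte(min(nn), 0)
  expect_lte(max(nn), 255)
  # window bounds checked
  expect_error(normalize_dem(gg, c(0L, 25L, 0L, 5L)), "outside raster")
})
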