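# Raster / vector geodata handling.
#
# Rasters live in memory as a `raster_grid`: a matrix (one band) or an
# H x W x B array plus a GDAL-style geotransform and a CRS identifier.
# On disk a raster is a TIFF with two plain-text sidecars: an ESRI world
# file (<name>.tfw) carrying the geotransform and a small JSON metadata
# file (<name>.meta.json) carrying CRS, value scaling and bit depth.
# Pixel coordinates are row-major and 0-based; windows are half-open
# [row0, row1) x [col0, col1). The geotransform is c(x0, dx, 0, y0, 0, -dy)
# with (x0, y0) the map coordinate of the top-left corner of pixel (0, 0).

#' Construct a raster grid
#'
#' @param values matrix (single band) or H x W x B array with B in {1, 3, 4}.
#' @param geotransform numeric length-6 GDAL-style affine
#'   `c(x0, dx, 0, y0, 0, -dy)` mapping pixel (row, col) to map (x, y).
#' @param crs_id CRS identifier string, e.g. `"EPSG:32719"`; `"unknown"` if
#'   not available.
#' @param nodata optional sentinel value.
#' @return object of class `raster_grid`.
#' @export
raster_grid <- function(values, geotransform, crs_id = "unknown", nodata = NULL) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  stopifnot(length(dim(values)) == 3L)
  d <- dim(values)
  if (d[1] < 1L || d[2] < 1L) stop("raster must have positive dimensions")
  if (!d[3] %in% c(1L, 3L, 4L)) {
    stop("band count must be 1, 3 or 4, got ", d[3])
  }
  geotransform <- as.numeric(geotransform)
  if (length(geotransform) != 6L) stop("geotransform must have 6 elements")
  if (geotransform[2] == 0 || geotransform[6] == 0) {
    stop("geotransform is not invertible (zero pixel size)")
  }
  structure(list(values = values, geotransform = geotransform,
                 crs_id = crs_id, nodata = nodata),
            class = "raster_grid")
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<raster_grid> %d x %d px, %d band(s), crs %s\n",
              d[1], d[2], d[3], x$crs_id))
  cat(sprintf("  geotransform: origin (%.3f, %.3f), pixel %.4g x %.4g\n",
              x$geotransform[1], x$geotransform[4],
              x$geotransform[2], -x$geotransform[6]))
  invisible(x)
}

# map coordinate of pixel centers; row/col 0-based
px_center_xy <- function(gt, row, col) {
  cbind(x = gt[1] + (col + 0.5) * gt[2],
        y = gt[4] + (row + 0.5) * gt[6])
}

# fractional 0-based (row, col) of a map coordinate
map_to_px <- function(gt, x, y) {
  cbind(row = (y - gt[4]) / gt[6], col = (x - gt[1]) / gt[2])
}

band_matrix <- function(grid, band = 1L) grid$values[, , band]

world_file_path <- function(path) sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
meta_file_path <- function(path) sub("\\.tiff?$", ".meta.json", path, ignore.case = TRUE)

#' Write a raster grid to a TIFF with world-file and metadata sidecars
#'
#' 8-bit storage is used for integer-valued rasters in [0, 255] (orthoimagery,
#' masks), 32-bit float storage otherwise (elevation, probabilities). Float
#' values are stored rescaled into [0, 1]; the offset/scale needed to recover
#' the original units travel in the JSON sidecar. One round trip quantizes to
#' the storage precision (exact for 8-bit data); further round trips are
#' lossless.
#'
#' @param grid a [raster_grid()].
#' @param path output path ending in `.tif`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  eightbit <- max(abs(v - round(v))) < 1e-9 && min(v) >= 0 && max(v) <= 255
  if (eightbit) {
    stored <- v / 255
    meta <- list(bits = 8L, offset = 0, scale = 255)
  } else {
    off <- min(v); sc <- max(v) - off
    if (sc == 0) sc <- 1
    stored <- (v - off) / sc
    meta <- list(bits = 32L, offset = off, scale = sc)
  }
  if (dim(stored)[3] == 1L) stored <- stored[, , 1]
  tiff::writeTIFF(stored, path, bits.per.sample = meta$bits)
  gt <- grid$geotransform
  # ESRI world file: dx, rot, rot, -dy, then center of the top-left pixel
  writeLines(formatC(c(gt[2], 0, 0, gt[6],
                       gt[1] + gt[2] / 2, gt[4] + gt[6] / 2),
                     format = "g", digits = 17),
             world_file_path(path))
  meta$crs_id <- grid$crs_id
  meta$nodata <- grid$nodata
  jsonlite::write_json(meta, meta_file_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raster written by [write_raster()]
#'
#' @param path path to the TIFF.
#' @return a [raster_grid()]; band order preserved. A missing CRS sidecar
#'   yields a warning and `crs_id = "unknown"` with an identity-scaled
#'   geotransform.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file does not exist: ", path)
  vals <- tryCatch(tiff::readTIFF(path),
                   error = function(e) stop("cannot read raster ", path, ": ",
                                            conditionMessage(e)))
  if (is.matrix(vals)) vals <- array(vals, c(dim(vals), 1L))
  mpath <- meta_file_path(path); wpath <- world_file_path(path)
  if (file.exists(mpath)) {
    meta <- jsonlite::read_json(mpath, simplifyVector = TRUE)
    vals <- vals * meta$scale + meta$offset
    if (meta$bits == 8L) vals <- round(vals)
    crs <- meta$crs_id
    nodata <- meta$nodata
    if (is.null(nodata) || length(nodata) == 0) nodata <- NULL
  } else {
    warning("no metadata sidecar for ", path, "; CRS recorded as unknown")
    crs <- "unknown"; nodata <- NULL
  }
  if (file.exists(wpath)) {
    w <- as.numeric(readLines(wpath))
    gt <- c(w[5] - w[1] / 2, w[1], 0, w[6] - w[4] / 2, 0, w[4])
  } else {
    warning("no world file for ", path, "; using identity geotransform")
    gt <- c(0, 1, 0, 0, 0, -1)
  }
  raster_grid(vals, gt, crs_id = crs, nodata = nodata)
}

#' Write polygons to GeoJSON
#'
#' @param polygons list of n x 2 matrices of map (x, y) vertices (open rings).
#' @param path output `.geojson` path.
#' @param crs_id CRS identifier recorded in the file.
#' @export
write_polygons <- function(polygons, path, crs_id = "unknown") {
  feats <- lapply(seq_along(polygons), function(i) {
    ring <- polygons[[i]]
    ring <- rbind(ring, ring[1, , drop = FALSE])  # close ring
    list(type = "Feature", properties = list(id = i),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) ring[j, ]))))
  })
  obj <- list(type = "FeatureCollection",
              crs = list(type = "name",
                         properties = list(name = crs_id)),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' @param path `.geojson` path written by [write_polygons()] (or any
#'   FeatureCollection of Polygons).
#' @return list of n x 2 open-ring matrices with attribute `crs_id`.
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("polygon file does not exist: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  crs <- tryCatch(obj$crs$properties$name, error = function(e) NULL)
  polys <- lapply(obj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  })
  attr(polys, "crs_id") <- if (is.null(crs)) "unknown" else crs
  polys
}

# signed shoelace area (map coords, open ring)
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_perimeter <- function(ring) {
  d <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE]) - ring
  sum(sqrt(rowSums(d^2)))
}

# proper self-intersection test over non-adjacent edge pairs, O(V^2)
polygon_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  a <- ring
  b <- rbind(ring[-1, , drop = FALSE], ring[1, , drop = FALSE])
  cross <- function(ox, oy, px, py, qx, qy) (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  for (i in 1:(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    js <- seq(i + 2, jmax)
    if (!length(js)) next
    d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[js, 1], a[js, 2])
    d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[js, 1], b[js, 2])
    d3 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], a[i, 1], a[i, 2])
    d4 <- cross(a[js, 1], a[js, 2], b[js, 1], b[js, 2], b[i, 1], b[i, 2])
    if (any(d1 * d2 < 0 & d3 * d4 < 0)) return(TRUE)
  }
  FALSE
}

validate_polygon <- function(ring, index = NA) {
  if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
    stop("polygon ", index, " is not an n x 2 matrix with >= 3 vertices")
  }
  if (abs(polygon_area(ring)) <= 0) {
    stop("polygon ", index, " has zero area")
  }
  if (polygon_self_intersects(ring)) {
    stop("polygon ", index, " is self-intersecting")
  }
  invisible(TRUE)
}

#' Rasterize polygons to a binary mask
#'
#' A pixel is 1 iff its center falls inside any polygon (even-odd rule;
#' pixel-center containment, not all-touched). An empty polygon list yields
#' an all-zero mask.
#'
#' @param polygons list of n x 2 matrices of map (x, y) vertices.
#' @param template a [raster_grid()] supplying dimensions, geotransform
#'   and CRS.
#' @return single-band `raster_grid` of 0/1 values.
#' @export
rasterize_polygons <- function(polygons, template) {
  stopifnot(inherits(template, "raster_grid"))
  d <- dim(template$values)
  H <- d[1]; W <- d[2]
  gt <- template$geotransform
  mask <- matrix(0, H, W)
  for (i in seq_along(polygons)) {
    ring <- polygons[[i]]
    validate_polygon(ring, i)
    # pixel-row range overlapped by the polygon bbox
    ymin <- min(ring[, 2]); ymax <- max(ring[, 2])
    r0 <- max(0L, floor((gt[4] - ymax) / -gt[6] - 0.5))
    r1 <- min(H - 1L, ceiling((gt[4] - ymin) / -gt[6]))
    if (r0 > r1) next
    x1 <- ring[, 1]; y1 <- ring[, 2]
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    for (r in r0:r1) {
      yc <- gt[4] + (r + 0.5) * gt[6]
      hit <- (y1 > yc) != (y2 > yc)
      if (!any(hit)) next
      xc <- x1[hit] + (yc - y1[hit]) / (y2[hit] - y1[hit]) * (x2[hit] - x1[hit])
      xc <- sort(xc)
      for (k in seq(1, length(xc) - 1, by = 2)) {
        # columns whose center x lies in (xc[k], xc[k+1])
        c0 <- ceiling((xc[k] - gt[1]) / gt[2] - 0.5)
        c1 <- floor((xc[k + 1] - gt[1]) / gt[2] - 0.5 - 1e-12)
        c0 <- max(0L, c0); c1 <- min(W - 1L, c1)
        if (c0 <= c1) mask[r + 1, (c0 + 1):(c1 + 1)] <- 1
      }
    }
  }
  raster_grid(mask, gt, crs_id = template$crs_id)
}

#' Normalize elevation values to relative 0-255 within a window
#'
#' Maps the window minimum to 0 and the maximum to 255, removing the
#' absolute terrain component so the elevation channel carries local
#' canopy relief only. A constant window maps to all zeros.
#'
#' @param dem single-band [raster_grid()].
#' @param window integer `c(row0, row1, col0, col1)`, 0-based half-open;
#'   `NULL` for the full raster.
#' @return `raster_grid` of the window with values in [0, 255].
#' @export
normalize_dem <- function(dem, window = NULL) {
  stopifnot(inherits(dem, "raster_grid"))
  d <- dim(dem$values)
  if (d[3] != 1L) stop("normalize_dem expects a single-band raster")
  if (is.null(window)) window <- c(0L, d[1], 0L, d[2])
  w <- as.integer(window)
  if (w[1] < 0 || w[3] < 0 || w[2] > d[1] || w[4] > d[2] ||
      w[1] >= w[2] || w[3] >= w[4]) {
    stop("window [", paste(w, collapse = ", "), ") outside raster ",
         d[1], " x ", d[2])
  }
  sub <- dem$values[(w[1] + 1):w[2], (w[3] + 1):w[4], 1, drop = FALSE]
  out <- normalize_window_values(sub)
  gt <- dem$geotransform
  gt2 <- gt
  gt2[1] <- gt[1] + w[3] * gt[2]
  gt2[4] <- gt[4] + w[1] * gt[6]
  raster_grid(out, gt2, crs_id = dem$crs_id)
}

# shared kernel: also used when assembling tile predictor channels
normalize_window_values <- function(v) {
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    message("constant elevation window; normalized to all zeros")
    return(array(0, dim(v)))
  }
  (v - lo) / (hi - lo) * 255
}
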