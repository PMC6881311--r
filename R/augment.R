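# Joint geometric augmentation of predictor tiles and masks.
#
# One transform descriptor (shear, rotation in fixed steps, per-axis shift,
# flips) is applied with identical geometry to every predictor channel
# (bilinear interpolation) and to the mask (nearest neighbour, so labels
# stay binary). Pixels mapped from outside the tile are filled by border
# reflection, avoiding an artificial background class.

#' Augmentation configuration
#'
#' @param shear_range_rad shear angle range in radians, within [0, 0.2].
#' @param rotation_step_deg rotations are drawn from multiples of this step
#'   in [0, 360) (20 gives 0, 20, ..., 340 degrees).
#' @param shift_range_frac per-axis shift magnitude range as a fraction of
#'   the tile edge, within [0, 0.15]; the sign of each shift is random.
#' @param allow_hflip,allow_vflip enable horizontal / vertical flips.
#' @param fill_mode border strategy; only `"reflect"` is supported.
#' @return object of class `augment_config`.
#' @export
augment_config <- function(shear_range_rad = c(0, 0.2),
                           rotation_step_deg = 20,
                           shift_range_frac = c(0, 0.15),
                           allow_hflip = TRUE, allow_vflip = TRUE,
                           fill_mode = "reflect") {
  if (shear_range_rad[1] < 0 || shear_range_rad[2] > 0.2 ||
      shear_range_rad[1] > shear_range_rad[2]) {
    stop("shear_range_rad must be an increasing range within [0, 0.2]")
  }
  if (shift_range_frac[1] < 0 || shift_range_frac[2] > 0.15 ||
      shift_range_frac[1] > shift_range_frac[2]) {
    stop("shift_range_frac must be an increasing range within [0, 0.15]")
  }
  if (rotation_step_deg <= 0 || 360 %% rotation_step_deg != 0) {
    stop("rotation_step_deg must divide 360")
  }
  if (!identical(fill_mode, "reflect")) {
    stop("only fill_mode = \"reflect\" is supported")
  }
  structure(list(shear_range_rad = shear_range_rad,
                 rotation_step_deg = rotation_step_deg,
                 shift_range_frac = shift_range_frac,
                 allow_hflip = allow_hflip, allow_vflip = allow_vflip,
                 fill_mode = fill_mode),
            class = "augment_config")
}

#' Draw a random transform descriptor
#'
#' Draws from the current RNG stream (seed it once per training run).
#'
#' @param config an [augment_config()].
#' @return list with `shear_rad` (signed; magnitude drawn from the range,
#'   matching generator-style symmetric deformations), `rot_deg` (multiple
#'   of the rotation step), `shift_frac` (signed, per axis: row then col),
#'   `hflip`, `vflip`.
#' @export
sample_transform <- function(config) {
  stopifnot(inherits(config, "augment_config"))
  n_rot <- 360 %/% config$rotation_step_deg
  list(shear_rad = runif(1, config$shear_range_rad[1],
                         config$shear_range_rad[2]) * sample(c(-1, 1), 1),
       rot_deg = config$rotation_step_deg * (sample.int(n_rot, 1) - 1L),
       shift_frac = runif(2, config$shift_range_frac[1],
                          config$shift_range_frac[2]) *
         sample(c(-1, 1), 2, replace = TRUE),
       hflip = config$allow_hflip && runif(1) < 0.5,
       vflip = config$allow_vflip && runif(1) < 0.5)
}

identity_transform <- function() {
  list(shear_rad = 0, rot_deg = 0, shift_frac = c(0, 0),
       hflip = FALSE, vflip = FALSE)
}

# forward 3x3 affine on homogeneous (row, col, 1), about the tile center:
# shift o (flip o rotate o shear) centered
transform_matrix <- function(t, tile_px) {
  ctr <- (tile_px - 1) / 2
  Tm <- function(dr, dc) matrix(c(1, 0, dr, 0, 1, dc, 0, 0, 1), 3, 3, byrow = TRUE)
  th <- t$rot_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  S <- matrix(c(1, tan(t$shear_rad), 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Fm <- diag(3)
  if (t$vflip) Fm[1, 1] <- -1   # vertical flip: rows reversed
  if (t$hflip) Fm[2, 2] <- -1   # horizontal flip: cols reversed
  shift <- Tm(t$shift_frac[1] * tile_px, t$shift_frac[2] * tile_px)
  shift %*% Tm(ctr, ctr) %*% Fm %*% R %*% S %*% Tm(-ctr, -ctr)
}

#' Apply a transform descriptor jointly to a tile's predictors and mask
#'
#' @param tile a `canopy_tile`.
#' @param t transform descriptor from [sample_transform()] (or
#'   [identity_transform()]).
#' @param config the [augment_config()] (fill mode).
#' @return a new `canopy_tile` of identical dimensions with recomputed cover.
#' @export
apply_transform <- function(tile, t, config = augment_config()) {
  stopifnot(inherits(tile, "canopy_tile"))
  tp <- dim(tile$mask)[1]
  M <- transform_matrix(t, tp)
  ident <- max(abs(M - diag(3))) < 1e-12
  if (ident) return(tile)
  A <- solve(M)[1:2, , drop = FALSE]     # inverse map: output px -> source px
  pred <- cpp_warp_affine(tile$predictors, A, 1L)
  mask <- cpp_warp_affine(array(tile$mask, c(tp, tp, 1)), A, 0L)[, , 1]
  structure(list(predictors = pred, mask = mask, origin = tile$origin,
                 cover = mean(mask)),
            class = "canopy_tile")
}
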