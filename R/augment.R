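#' Augmentation configuration
#'
#' Two-stage pipeline: color jitter (brightness / contrast / saturation) on
#' the original RGB tile before stain separation, then independent geometric
#' and brightness augmentation of the H and E channel images (random
#' rotation, random crop, random flips, multiplicative brightness). All
#' jitter ranges are closed intervals that must contain 1 so the identity is
#' reachable; setting every range to `c(1, 1)`, `rotate = FALSE`,
#' `flip_h = flip_v = 0` and `crop = NULL` makes the pipeline an exact no-op.
#'
#' @param rgb_brightness,rgb_contrast,rgb_saturation multiplicative jitter
#'   ranges for the RGB stage.
#' @param crop side of the random crop applied to channel images (`NULL` =
#'   no crop; paper-scale tiles use 256 of 400, i.e. 64%).
#' @param rotate draw a uniform rotation angle in `[0, 360)` degrees.
#' @param flip_h,flip_v flip probabilities.
#' @param channel_brightness multiplicative jitter range for channel images.
#' @return an `augment_config`.
#' @export
augment_config <- function(rgb_brightness = c(0.9, 1.1),
                           rgb_contrast = c(0.9, 1.1),
                           rgb_saturation = c(0.9, 1.1),
                           crop = NULL, rotate = TRUE,
                           flip_h = 0.5, flip_v = 0.5,
                           channel_brightness = c(0.9, 1.1)) {
  check_range <- function(r, name) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0 || r[1] > 1 || r[2] < 1) {
      stop_classm(sprintf(
        "%s must be a positive interval [lo, hi] containing 1", name),
        "classm_config_error")
    }
  }
  check_range(rgb_brightness, "rgb_brightness")
  check_range(rgb_contrast, "rgb_contrast")
  check_range(rgb_saturation, "rgb_saturation")
  check_range(channel_brightness, "channel_brightness")
  stopifnot(flip_h >= 0, flip_h <= 1, flip_v >= 0, flip_v <= 1)
  structure(list(rgb_brightness = rgb_brightness, rgb_contrast = rgb_contrast,
                 rgb_saturation = rgb_saturation, crop = crop,
                 rotate = rotate, flip_h = flip_h, flip_v = flip_v,
                 channel_brightness = channel_brightness),
            class = "augment_config")
}

#' Identity augmentation configuration (exact no-op)
#' @return an `augment_config` whose pipeline returns inputs unchanged.
#' @export
identity_augment_config <- function() {
  augment_config(rgb_brightness = c(1, 1), rgb_contrast = c(1, 1),
                 rgb_saturation = c(1, 1), crop = NULL, rotate = FALSE,
                 flip_h = 0, flip_v = 0, channel_brightness = c(1, 1))
}

#' Color-jitter an RGB tile
#'
#' Brightness scales intensities; contrast blends with the tile's mean gray
#' level; saturation blends each pixel with its own luminance
#' (0.299 R + 0.587 G + 0.114 B). Factors are drawn uniformly from the
#' configured ranges; output is clipped to `[0, I0]`.
#'
#' @param tile an [rgb_tile()].
#' @param config an [augment_config()].
#' @param rng an [rng_stream()].
#' @return a jittered [rgb_tile()].
#' @export
jitter_rgb <- function(tile, config, rng) {
  stopifnot(inherits(tile, "rgb_tile"), inherits(config, "augment_config"))
  f <- with_rng(rng, c(runif(1, config$rgb_brightness[1], config$rgb_brightness[2]),
                       runif(1, config$rgb_contrast[1], config$rgb_contrast[2]),
                       runif(1, config$rgb_saturation[1], config$rgb_saturation[2])))
  px <- tile$pixels * f[1]
  if (f[2] != 1) px <- mean(px) + (px - mean(px)) * f[2]
  if (f[3] != 1) {
    lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    for (c in 1:3) px[, , c] <- lum + (px[, , c] - lum) * f[3]
  }
  rgb_tile(clip(px, 0, tile$background_intensity),
           tile$background_intensity, tile$slide_id, validate = FALSE)
}

#' Geometric + brightness augmentation of a single channel image
#'
#' Applies, in order: continuous-angle rotation about the image center with
#' reflection padding (bilinear resampling), random crop to `config$crop`,
#' random horizontal / vertical flip, multiplicative brightness jitter, clip
#' to `[0, 1]`. H and E images of the same sample are augmented with
#' separate `rng` streams, so they receive independent rotations, crops and
#' flips.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param config an [augment_config()].
#' @param rng an [rng_stream()].
#' @return augmented numeric matrix.
#' @export
augment_channel <- function(image, config, rng) {
  stopifnot(is.matrix(image), inherits(config, "augment_config"))
  if (!is.null(config$crop) && config$crop > min(dim(image))) {
    stop_classm("crop size exceeds image size", "classm_shape_error")
  }
  if (config$rotate) {
    ang <- with_rng(rng, runif(1, 0, 360))
    image <- rotate_bilinear(image, ang)
  }
  if (!is.null(config$crop)) {
    cs <- config$crop
    r0 <- with_rng(rng, sample.int(nrow(image) - cs + 1L, 1L)) - 1L
    c0 <- with_rng(rng, sample.int(ncol(image) - cs + 1L, 1L)) - 1L
    image <- image[r0 + seq_len(cs), c0 + seq_len(cs), drop = FALSE]
  }
  if (config$flip_h > 0 && with_rng(rng, runif(1)) < config$flip_h) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
  }
  if (config$flip_v > 0 && with_rng(rng, runif(1)) < config$flip_v) {
    image <- image[rev(seq_len(nrow(image))), , drop = FALSE]
  }
  br <- config$channel_brightness
  if (br[1] != 1 || br[2] != 1) {
    image <- image * with_rng(rng, runif(1, br[1], br[2]))
  }
  clip(image, 0, 1)
}

#' Rotate a matrix by an arbitrary angle (bilinear, reflection padding)
#'
#' Output pixel `(r, c)` samples the input at the location obtained by
#' rotating `(r, c)` by `-angle` about the image center; out-of-range
#' coordinates are reflected. Exact (no interpolation blur) at multiples of
#' 90 degrees on any square image.
#'
#' @param image numeric matrix.
#' @param angle_deg rotation angle, degrees, counter-clockwise.
#' @return rotated matrix of the same shape.
#' @export
rotate_bilinear <- function(image, angle_deg) {
  cpp_rotate_reflect(image, angle_deg)
}
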