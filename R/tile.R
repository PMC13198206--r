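#' RGB tile container
#'
#' A tile is an 8-bit RGB image patch cropped from a whole-slide image (or
#' rendered by the simulator), together with the background ("blank glass")
#' intensity `I0` against which optical density is measured and the identifier
#' of the slide it came from. Stain separation is adaptive at the slide level,
#' so `slide_id` decides which stain basis is applied.
#'
#' @param pixels numeric array `height x width x 3` (R, G, B), values in
#'   `[0, background_intensity]`.
#' @param background_intensity scalar `I0` (default 255).
#' @param slide_id opaque identifier.
#' @param validate check the pixel invariants (skipped on hot internal paths
#'   whose outputs are clipped by construction).
#' @return an object of class `rgb_tile`.
#' @export
rgb_tile <- function(pixels, background_intensity = 255, slide_id = "slide",
                     validate = TRUE) {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    stop_classm("tile pixels must be a height x width x 3 array", "classm_shape_error")
  }
  if (validate) {
    if (any(!is.finite(pixels)) || any(pixels < 0)) {
      stop_classm("tile pixel intensities must be finite and non-negative", "classm_domain_error")
    }
    if (any(pixels > background_intensity)) {
      stop_classm("tile pixel intensities exceed background_intensity", "classm_domain_error")
    }
  }
  structure(list(pixels = pixels, background_intensity = background_intensity,
                 slide_id = slide_id), class = "rgb_tile")
}

#' @export
print.rgb_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_tile %dx%d slide=%s I0=%g>\n", d[1], d[2], x$slide_id,
              x$background_intensity))
  invisible(x)
}

#' Convert an RGB tile to optical density (Beer-Lambert)
#'
#' Per channel `C`, `OD_C = log10(I0_C / I_C)`: zero absorption at blank
#' background, increasing as transmitted light decreases. Intensities are
#' floored at `epsilon` (default half a quantization level) so fully black
#' pixels give a large but finite OD.
#'
#' @param tile an [rgb_tile()].
#' @param epsilon positive intensity floor applied before the log.
#' @return numeric array `height x width x 3` of optical densities (>= 0).
#' @export
rgb_to_od <- function(tile, epsilon = 0.5) {
  stopifnot(inherits(tile, "rgb_tile"))
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    stop_classm("epsilon must be a positive scalar", "classm_domain_error")
  }
  od <- log10(tile$background_intensity / pmax(tile$pixels, epsilon))
  # background_intensity/I is >= 1 everywhere by the tile invariant
  array(od, dim(tile$pixels))
}

#' Reconstruct an RGB tile from optical densities
#'
#' Inverse of [rgb_to_od()]: `I = round(I0 * 10^-OD)` clipped to `[0, I0]`.
#' Used by the simulator's forward renderer and for round-trip checks.
#'
#' @param od numeric array `height x width x 3`, entries >= 0.
#' @param background_intensity scalar `I0`.
#' @param slide_id slide identifier for the resulting tile.
#' @return an [rgb_tile()].
#' @export
od_to_rgb <- function(od, background_intensity = 255, slide_id = "slide") {
  d <- dim(od)
  if (length(d) != 3L || d[3] != 3L) {
    stop_classm("od must be a height x width x 3 array", "classm_shape_error")
  }
  if (any(!is.finite(od)) || any(od < 0)) {
    stop_classm("optical densities must be finite and non-negative", "classm_domain_error")
  }
  px <- clip(round(background_intensity * 10^(-od)), 0, background_intensity)
  rgb_tile(array(px, d), background_intensity, slide_id)
}

#' Read / write tiles as 8-bit PNG
#'
#' @param path file path.
#' @param slide_id slide identifier attached to the tile on read.
#' @param background_intensity `I0` attached on read.
#' @return `read_tile_png` returns an [rgb_tile()]; `write_tile_png` returns
#'   `path` invisibly.
#' @export
read_tile_png <- function(path, slide_id = "slide", background_intensity = 255) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  rgb_tile(round(img * 255), background_intensity, slide_id)
}

#' @rdname read_tile_png
#' @param tile an [rgb_tile()].
#' @export
write_tile_png <- function(tile, path) {
  stopifnot(inherits(tile, "rgb_tile"))
  png::writePNG(tile$pixels / tile$background_intensity, path)
  invisible(path)
}

#' Read / write single-channel concentration images as 16-bit PGM
#'
#' Separated H/E channel images live in `[0, 1]`; 8 bits would quantize them
#' visibly, and the available PNG writer is 8-bit only, so channel images are
#' stored as 16-bit binary PGM (P5), which round-trips losslessly at 1/65535
#' resolution.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @return `read_channel_pgm` returns a numeric matrix in `[0, 1]`.
#' @export
write_channel_pgm <- function(img, path) {
  stopifnot(is.matrix(img), all(is.finite(img)), all(img >= 0 & img <= 1))
  v <- as.integer(round(t(img) * 65535))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(img), nrow(img)), "65535"), con)
  writeBin(v, con, size = 2L, endian = "big")
  invisible(path)
}

#' @rdname write_channel_pgm
#' @export
read_channel_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  stopifnot(magic == "P5")
  dims <- scan(text = readLines(con, n = 1L), quiet = TRUE)
  maxv <- scan(text = readLines(con, n = 1L), quiet = TRUE)
  v <- readBin(con, "integer", n = dims[1] * dims[2], size = 2L,
               signed = FALSE, endian = "big")
  t(matrix(v / maxv, nrow = dims[1], ncol = dims[2]))
}
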