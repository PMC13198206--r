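#' Per-slide specification for the tile simulator
#'
#' Real slides differ in staining chemistry and scanner brightness, which is
#' what makes adaptive (per-slide) stain separation worthwhile. A `SlideSpec`
#' carries a ground-truth stain basis obtained by rotating the canonical
#' Ruifrok-Johnston H/E pair within the stain plane by per-slide drift
#' angles, plus a multiplicative brightness factor applied to the background
#' intensity at render time.
#'
#' @param slide_id identifier.
#' @param seed integer seed; drift and brightness are drawn from it.
#' @param drift_deg maximum absolute in-plane rotation of each stain vector,
#'   degrees (default 8).
#' @param brightness_range range the brightness factor is drawn from
#'   (default `c(0.9, 1.0)`, i.e. never above the nominal background so the 8-bit range cannot saturate; must stay within `[0.7, 1.3]`).
#' @return a `slide_spec` with `true_basis` (a calibrated-format
#'   `stain_basis` holding the ground-truth vectors, unit norm scales).
#' @export
slide_spec <- function(slide_id, seed, drift_deg = 8,
                       brightness_range = c(0.9, 1.0)) {
  stopifnot(drift_deg >= 0, drift_deg <= 45,
            brightness_range[1] >= 0.7, brightness_range[2] <= 1.3)
  rng <- rng_stream(seed)
  canon <- fixed_default_basis()
  rot <- with_rng(rng, runif(2, -drift_deg, drift_deg)) * pi / 180
  brightness <- with_rng(rng, runif(1, brightness_range[1], brightness_range[2]))
  # absorbances are physically non-negative: clamp drifted vectors into the
  # positive octant (the canonical E red component is small, so an in-plane
  # rotation can otherwise push it slightly negative) and renormalize
  clamp_unit <- function(v) {
    v <- pmax(v, 0.01)
    v / sqrt(sum(v^2))
  }
  frame <- plane_frame(clamp_unit(rotate_in_plane(canon$V_H, canon, rot[1])),
                       clamp_unit(rotate_in_plane(canon$V_E, canon, rot[2])))
  basis <- new_stain_basis(frame$vx, frame$vy, frame$vres,
                           frame$theta_1, frame$theta_2, slide_id,
                           norm_scale_h = 1, norm_scale_e = 1,
                           params = list(drift_deg = rot * 180 / pi))
  # per-slide appearance nuisance: real slides differ in cellularity and in
  # effective stain uptake, so class-conditional textures are modulated by
  # slide-level gains — the main reason labeled-only training on a handful
  # of slides generalizes poorly to unseen slides
  gains <- with_rng(rng, c(density = runif(1, 0.6, 1.45),
                           h = runif(1, 0.8, 1.25),
                           e = runif(1, 0.8, 1.25)))
  structure(list(slide_id = slide_id, true_basis = basis,
                 brightness_factor = brightness, texture_gain = gains,
                 seed = seed),
            class = "slide_spec")
}

rotate_in_plane <- function(v, basis, angle) {
  x <- sum(v * basis$axes[, 1]); y <- sum(v * basis$axes[, 2])
  phi <- atan2(y, x) + angle
  r <- sqrt(x^2 + y^2)
  r * cos(phi) * basis$axes[, 1] + r * sin(phi) * basis$axes[, 2]
}

#' Class-conditional texture specification
#'
#' Class signal is carried jointly by H-channel morphology (density and size
#' of nuclei-like blobs) and E-channel level (cytoplasm field amplitude), so
#' that each stain view alone is informative — the co-training presumption.
#' `necrosis_flag` additionally draws large smooth patches of suppressed H
#' and elevated E, mimicking necrotic regions.
#'
#' @param class_id class name.
#' @param nuclei_density expected blob count on a 96x96 tile (scaled by area
#'   for other sizes).
#' @param nuclei_radius_range blob radius range in pixels.
#' @param h_amplitude_range,e_amplitude_range per-structure concentration
#'   amplitude ranges, within `[0, 1.5]`.
#' @param e_grid resolution of the coarse grid behind the cytoplasm field on
#'   a 96-px tile: low values give smooth stroma, high values a granular
#'   texture — spatial-frequency signal readable from the Eosin view alone,
#'   so that view is individually informative (the co-training presumption).
#' @param necrosis_flag draw necrosis-like low-H/high-E patches.
#' @return a `class_texture_spec`.
#' @export
class_texture_spec <- function(class_id, nuclei_density, nuclei_radius_range,
                               h_amplitude_range, e_amplitude_range,
                               e_grid = 5L, necrosis_flag = FALSE) {
  stopifnot(nuclei_density >= 0, e_grid >= 2,
            all(h_amplitude_range >= 0), all(h_amplitude_range <= 1.5),
            all(e_amplitude_range >= 0), all(e_amplitude_range <= 1.5))
  structure(list(class_id = class_id, nuclei_density = nuclei_density,
                 nuclei_radius_range = nuclei_radius_range,
                 h_amplitude_range = h_amplitude_range,
                 e_amplitude_range = e_amplitude_range,
                 e_grid = as.integer(e_grid),
                 necrosis_flag = necrosis_flag),
            class = "class_texture_spec")
}

#' Default three-class texture set
#'
#' A desk-scale analogue of a benign / carcinoma / necrosis split: benign
#' tissue has sparse small nuclei over a moderate eosin field; carcinoma has
#' dense, larger, strongly stained nuclei with reduced cytoplasm staining;
#' necrosis has few nuclei, a strong eosin field and large low-H patches.
#' Amplitude ranges deliberately overlap so single-pixel statistics do not
#' separate the classes — texture must be learned.
#'
#' @return named list of [class_texture_spec()].
#' @export
default_textures <- function() {
  list(
    benign = class_texture_spec("benign",
      nuclei_density = 20, nuclei_radius_range = c(1.8, 3.0),
      h_amplitude_range = c(0.40, 0.85), e_amplitude_range = c(0.30, 0.60),
      e_grid = 4L),
    carcinoma = class_texture_spec("carcinoma",
      nuclei_density = 34, nuclei_radius_range = c(2.2, 4.2),
      h_amplitude_range = c(0.50, 1.0), e_amplitude_range = c(0.22, 0.50),
      e_grid = 12L),
    necrosis = class_texture_spec("necrosis",
      nuclei_density = 8, nuclei_radius_range = c(1.8, 3.0),
      h_amplitude_range = c(0.30, 0.60), e_amplitude_range = c(0.40, 0.75),
      e_grid = 6L, necrosis_flag = TRUE))
}

#' Render one synthetic H&E tile
#'
#' Draws ground-truth concentration fields — `alpha_H` as a sum of Gaussian
#' nuclei blobs over a low background, `alpha_E` as a smooth bilinearly
#' upsampled cytoplasm field, optionally modulated by necrosis patches —
#' mixes them through the slide's true stain vectors in OD space, adds
#' isotropic OD noise, and converts to 8-bit RGB with the slide's brightness
#' factor applied to the background intensity. Deterministic given `seed`.
#'
#' @param slide a [slide_spec()].
#' @param texture a [class_texture_spec()].
#' @param size tile side in pixels (default 96, minimum 32).
#' @param noise_sd standard deviation of additive OD noise (default 0.01).
#' @param seed integer seed.
#' @return list with `tile` ([rgb_tile()]), `alpha_h`, `alpha_e` ground-truth
#'   matrices, `class_id`, `slide_id`.
#' @export
render_tile <- function(slide, texture, size = 96, noise_sd = 0.01, seed = 1) {
  stopifnot(inherits(slide, "slide_spec"), inherits(texture, "class_texture_spec"))
  if (size < 32) stop_classm("tile size must be >= 32", "classm_domain_error")
  rng <- rng_stream(seed)
  gains <- slide$texture_gain %||% c(density = 1, h = 1, e = 1)
  xs <- seq_len(size)
  alpha_h <- matrix(with_rng(rng, runif(1, 0.01, 0.05)), size, size)

  n_blobs <- with_rng(rng, rpois(1, texture$nuclei_density *
                                   gains[["density"]] * (size / 96)^2))
  if (n_blobs > 0) {
    cx <- with_rng(rng, runif(n_blobs, 1, size))
    cy <- with_rng(rng, runif(n_blobs, 1, size))
    rr <- with_rng(rng, runif(n_blobs, texture$nuclei_radius_range[1],
                              texture$nuclei_radius_range[2]))
    aa <- with_rng(rng, gains[["h"]] *
                     runif(n_blobs, texture$h_amplitude_range[1],
                           texture$h_amplitude_range[2]))
    for (b in seq_len(n_blobs)) {
      alpha_h <- alpha_h + aa[b] *
        (exp(-(xs - cy[b])^2 / (2 * rr[b]^2)) %o%
           exp(-(xs - cx[b])^2 / (2 * rr[b]^2)))
    }
  }

  # smooth cytoplasm field: coarse grid, bilinear upsample; nuclei displace
  # cytoplasm, so eosin is suppressed where the hematoxylin blobs are dense
  # (this also gives the near-pure-stain pixels the angle estimator relies on)
  grid_n <- max(2L, as.integer(round((texture$e_grid %||% 5L) * size / 96)))
  coarse <- matrix(with_rng(rng, gains[["e"]] *
                              runif(grid_n^2, texture$e_amplitude_range[1],
                                    texture$e_amplitude_range[2])),
                   grid_n, grid_n)
  alpha_e <- bilinear_upsample(coarse, size)
  nuc_mask <- clip((alpha_h - 0.1) / 0.5, 0, 1)
  alpha_e <- alpha_e * (1 - 0.9 * nuc_mask)

  if (texture$necrosis_flag) {
    n_patch <- with_rng(rng, sample(1:3, 1))
    pcx <- with_rng(rng, runif(n_patch, 1, size))
    pcy <- with_rng(rng, runif(n_patch, 1, size))
    prr <- with_rng(rng, runif(n_patch, size / 5, size / 2.5))
    mask <- matrix(0, size, size)
    for (b in seq_len(n_patch)) {
      mask <- pmax(mask, exp(-(xs - pcy[b])^2 / (2 * prr[b]^2)) %o%
                     exp(-(xs - pcx[b])^2 / (2 * prr[b]^2)))
    }
    alpha_h <- alpha_h * (1 - 0.8 * mask)
    alpha_e <- alpha_e * (1 + 0.5 * mask)
  }

  alpha_h <- clip(alpha_h, 0, 1.5)
  alpha_e <- clip(alpha_e, 0, 1.5)

  b <- slide$true_basis
  od <- outer(alpha_h, b$V_H) + outer(alpha_e, b$V_E)
  if (noise_sd > 0) {
    od <- od + array(with_rng(rng, rnorm(length(od), 0, noise_sd)), dim(od))
  }
  od <- pmax(od, 0)
  i0_true <- 255 * slide$brightness_factor
  px <- clip(round(i0_true * 10^(-od)), 0, 255)
  tile <- rgb_tile(array(px, dim(od)), background_intensity = 255,
                   slide_id = slide$slide_id)
  list(tile = tile, alpha_h = alpha_h, alpha_e = alpha_e,
       class_id = texture$class_id, slide_id = slide$slide_id)
}

bilinear_upsample <- function(coarse, size) {
  n <- nrow(coarse)
  pos <- seq(1, n, length.out = size)
  i0 <- pmin(floor(pos), n - 1L)
  fr <- pos - i0
  rows <- coarse[i0, , drop = FALSE] * (1 - fr) + coarse[i0 + 1L, , drop = FALSE] * fr
  rows[, i0, drop = FALSE] * rep(1 - fr, each = size) +
    rows[, i0 + 1L, drop = FALSE] * rep(fr, each = size)
}

#' Generate a synthetic semi-supervised tile dataset
#'
#' Renders tiles across several simulated slides and assembles the manifest
#' of a semi-supervised experiment: per-class labeled training tiles,
#' unlabeled training tiles (true class hidden, stored only in a diagnostic
#' sidecar), and validation / test tiles. Slides are partitioned so that
#' validation and test tiles never come from a training slide, mirroring
#' slide-level splits in whole-slide-image studies. Labeled tiles are
#' additionally restricted to a subset of the training slides
#' (`labeled_slide_fraction`), while unlabeled tiles come from all of them —
#' the typical situation when annotation covers few slides but raw slides
#' abound, and the structural reason unlabeled data carries appearance
#' variation the labeled set lacks.
#'
#' @param out_dir output directory; created. If `NULL`, tiles are kept
#'   in memory only.
#' @param classes named list of [class_texture_spec()] (default
#'   [default_textures()]).
#' @param n_slides total number of slides (default 9; at least 3).
#' @param labeled_slide_fraction fraction of the training slides that carry
#'   labeled tiles (default 1/3, at least one slide).
#' @param n_labeled_per_class,n_unlabeled,n_val_per_class,n_test_per_class
#'   split sizes.
#' @param size tile side in pixels.
#' @param noise_sd OD noise level.
#' @param drift_deg per-slide stain drift bound, degrees.
#' @param seed master seed; everything derives from it.
#' @return list with `manifest` (data.frame: tile_path, slide_id, label,
#'   split), `tiles` (named list of render results keyed by tile_path),
#'   `slides` (list of [slide_spec()]), `truth` (hidden labels for unlabeled
#'   tiles and true bases), `class_names`.
#' @export
generate_dataset <- function(out_dir = NULL, classes = default_textures(),
                             n_slides = 9, labeled_slide_fraction = 1 / 3,
                             n_labeled_per_class = 30,
                             n_unlabeled = 600, n_val_per_class = 20,
                             n_test_per_class = 20, size = 96,
                             noise_sd = 0.02, drift_deg = 8, seed = 1) {
  stopifnot(length(classes) >= 2, n_slides >= 3,
            n_labeled_per_class >= 0, n_unlabeled >= 0)
  class_names <- vapply(classes, function(cl) cl$class_id, character(1))
  rng <- rng_stream(seed)
  slide_seeds <- with_rng(rng, sample.int(2^30, n_slides))
  slides <- lapply(seq_len(n_slides), function(i)
    slide_spec(sprintf("slide%02d", i), slide_seeds[i], drift_deg = drift_deg))

  n_val_slides <- max(1L, round(n_slides / 5))
  n_test_slides <- max(1L, round(n_slides / 5))
  if (n_slides - n_val_slides - n_test_slides < 1L) {
    stop_classm("too few slides to partition into train/val/test", "classm_config_error")
  }
  perm <- with_rng(rng, sample.int(n_slides))
  split_of_slide <- rep("train", n_slides)
  split_of_slide[perm[seq_len(n_val_slides)]] <- "val"
  split_of_slide[perm[n_val_slides + seq_len(n_test_slides)]] <- "test"
  train_slides <- which(split_of_slide == "train")
  n_lab_slides <- max(1L, round(length(train_slides) * labeled_slide_fraction))
  labeled_slides <- train_slides[seq_len(n_lab_slides)]

  rows <- list(); tiles <- list(); hidden <- list()
  emit <- function(split, class_idx, labeled) {
    sl_pool <- switch(split,
                      train_labeled = labeled_slides,
                      train_unlabeled = train_slides,
                      which(split_of_slide == split))
    sl <- slides[[sl_pool[with_rng(rng, sample.int(length(sl_pool), 1))]]]
    tseed <- with_rng(rng, sample.int(2^30, 1))
    r <- render_tile(sl, classes[[class_idx]], size = size,
                     noise_sd = noise_sd, seed = tseed)
    path <- sprintf("%s_%05d.png", split, length(rows) + 1L)
    rows[[length(rows) + 1L]] <<- data.frame(
      tile_path = path, slide_id = sl$slide_id,
      label = if (labeled) class_names[class_idx] else "",
      split = split, stringsAsFactors = FALSE)
    tiles[[path]] <<- r
    if (!labeled) hidden[[path]] <<- class_names[class_idx]
  }
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_labeled_per_class)) emit("train_labeled", ci, TRUE)
  }
  for (k in seq_len(n_unlabeled)) {
    emit("train_unlabeled", with_rng(rng, sample(seq_along(classes), 1)), FALSE)
  }
  for (ci in seq_along(classes)) {
    for (k in seq_len(n_val_per_class)) emit("val", ci, TRUE)
    for (k in seq_len(n_test_per_class)) emit("test", ci, TRUE)
  }
  manifest <- do.call(rbind, rows)
  ds <- list(manifest = manifest, tiles = tiles, slides = slides,
             truth = list(hidden_labels = hidden,
                          bases = lapply(slides, function(s) s$true_basis)),
             class_names = unname(class_names),
             params = list(size = size, noise_sd = noise_sd,
                           drift_deg = drift_deg, seed = seed))
  if (!is.null(out_dir)) write_dataset(ds, out_dir)
  ds
}

#' Write a generated dataset to disk
#'
#' Emits PNG tiles, `manifest.csv` and a `truth.json` sidecar (true stain
#' bases and hidden labels of unlabeled tiles — diagnostics only, never read
#' by training).
#'
#' @param ds result of [generate_dataset()].
#' @param out_dir directory, created if needed.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (path in names(ds$tiles)) {
    write_tile_png(ds$tiles[[path]]$tile, file.path(out_dir, path))
  }
  write.csv(ds$manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  truth <- list(
    hidden_labels = ds$truth$hidden_labels,
    class_names = ds$class_names,
    params = ds$params,
    bases = lapply(ds$truth$bases, function(b)
      list(slide_id = b$slide_id, V_H = b$V_H, V_E = b$V_E)))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load a tile dataset from a directory
#'
#' Reads `manifest.csv` and every referenced tile into memory. Labels use
#' empty string for unlabeled rows.
#'
#' @param dir dataset directory.
#' @return list with `manifest`, `tiles` (list of [rgb_tile()] keyed by
#'   tile_path), `class_names`.
#' @export
load_dataset <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  manifest$label[is.na(manifest$label)] <- ""
  tiles <- list()
  for (i in seq_len(nrow(manifest))) {
    tiles[[manifest$tile_path[i]]] <- list(
      tile = read_tile_png(file.path(dir, manifest$tile_path[i]),
                           slide_id = manifest$slide_id[i]))
  }
  cn <- sort(unique(manifest$label[manifest$label != ""]))
  list(manifest = manifest, tiles = tiles, class_names = cn)
}
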