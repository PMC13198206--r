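#' Adaptive H&E stain separation
#'
#' Hematoxylin and Eosin absorb light linearly in optical-density (OD) space:
#' each tissue pixel's OD vector is approximately `alpha_H * V_H +
#' alpha_E * V_E` for unit stain vectors `V_H`, `V_E` that vary from slide to
#' slide with staining conditions. The fit proceeds slide by slide:
#'
#' 1. pool foreground OD pixels across the slide's tiles;
#' 2. PCA of the OD covariance gives an orthonormal frame `V_x, V_y,
#'    V_residual` (descending eigenvalue); the third axis is treated as
#'    residual noise and discarded downstream;
#' 3. every retained pixel gets an angle `phi = atan2(<od, V_y>, <od, V_x>)`
#'    in the stain plane; robust extremes of the angle distribution — the
#'    `outlier_fraction` and `1 - outlier_fraction` quantiles, with pixels of
#'    projected norm below `min_od_norm` excluded as near-background — give
#'    the two stain directions, allowing a fraction of noisy pixels to fall
#'    outside the stain wedge;
#' 4. of the two extreme vectors, Hematoxylin is the one absorbing more red
#'    light (larger red OD component); axis signs are fixed so that `V_H`
#'    lies in quadrant IV (`theta_H < 0`) and `V_E` in quadrant I
#'    (`theta_E > 0`).
#'
#' @param od_pixels numeric matrix `n x 3` of OD vectors pooled across one
#'   slide's tiles.
#' @param outlier_fraction fraction of pixels allowed outside the stain wedge
#'   on each side (default 0.01).
#' @param min_od_norm pixels closer to the OD origin than this are treated as
#'   background and excluded (default 0.1).
#' @param min_pixels minimum number of foreground pixels required (default 1000).
#' @param slide_id identifier recorded in the basis.
#' @return a `stain_basis` object with norm scales unset (see
#'   [calibrate_norm_scales()]).
#' @export
fit_stain_basis <- function(od_pixels, outlier_fraction = 0.01,
                            min_od_norm = 0.1, min_pixels = 1000,
                            slide_id = "slide") {
  stopifnot(is.matrix(od_pixels), ncol(od_pixels) == 3)
  stopifnot(outlier_fraction >= 0, outlier_fraction < 0.5, min_od_norm >= 0)
  norms <- sqrt(rowSums(od_pixels^2))
  fg <- od_pixels[norms >= min_od_norm, , drop = FALSE]
  if (nrow(fg) < min_pixels) {
    stop_classm(sprintf(
      "insufficient tissue: %d foreground OD pixels (norm >= %g), need %d",
      nrow(fg), min_od_norm, min_pixels), "classm_insufficient_tissue_error")
  }
  eg <- eigen(cov(fg), symmetric = TRUE)
  if (eg$values[2] <= 0 || eg$values[2] / eg$values[1] < 1e-9) {
    stop_classm("degenerate OD covariance: pixels span no stain plane (rank < 2)",
                "classm_singular_plane_error")
  }
  vx <- eg$vectors[, 1]
  vy <- eg$vectors[, 2]
  vres <- eg$vectors[, 3]

  # orient V_x along the bulk of the tissue cloud
  px <- fg %*% vx
  if (mean(px) < 0) {
    vx <- -vx
    px <- -px
  }
  py <- fg %*% vy
  keep <- sqrt(px^2 + py^2) >= min_od_norm
  phi <- atan2(py[keep], px[keep])
  th <- unname(quantile(phi, c(outlier_fraction, 1 - outlier_fraction),
                        type = 7))
  w_lo <- cos(th[1]) * vx + sin(th[1]) * vy
  w_hi <- cos(th[2]) * vx + sin(th[2]) * vy
  # Hematoxylin absorbs more red light than Eosin
  if (w_lo[1] >= w_hi[1]) {
    v_h <- w_lo; theta_h <- th[1]; v_e <- w_hi; theta_e <- th[2]
  } else {
    v_h <- w_hi; theta_h <- th[2]; v_e <- w_lo; theta_e <- th[1]
  }
  if (theta_h > 0) {  # flip V_y so H sits in quadrant IV, E in quadrant I
    vy <- -vy
    theta_h <- -theta_h
    theta_e <- -theta_e
  }
  if (!(theta_h < 0 && theta_e > 0)) {
    # wide or one-sided stain wedges can place both extremes on the same
    # side of the first eigenvector; re-anchor the in-plane frame on the
    # bisector of the two stain vectors so the quadrant convention holds
    fr <- plane_frame(v_h, v_e)
    vx <- fr$vx; vy <- fr$vy; vres <- fr$vres
    theta_h <- fr$theta_1; theta_e <- fr$theta_2
  }
  new_stain_basis(vx, vy, vres, theta_h, theta_e, slide_id,
                  params = list(outlier_fraction = outlier_fraction,
                                min_od_norm = min_od_norm,
                                min_pixels = min_pixels))
}

new_stain_basis <- function(vx, vy, vres, theta_h, theta_e, slide_id,
                            norm_scale_h = NA_real_, norm_scale_e = NA_real_,
                            norm_target = 0.5, params = list()) {
  v_h <- cos(theta_h) * vx + sin(theta_h) * vy
  v_e <- cos(theta_e) * vx + sin(theta_e) * vy
  forward <- cbind(v_h, v_e, vres, deparse.level = 0)
  structure(list(
    slide_id = slide_id,
    axes = cbind(vx, vy, vres, deparse.level = 0),
    theta_H = theta_h, theta_E = theta_e,
    V_H = v_h, V_E = v_e,
    forward_matrix = forward,
    inverse_matrix = solve(forward),
    norm_scale_H = norm_scale_h, norm_scale_E = norm_scale_e,
    norm_target = norm_target,
    params = params), class = "stain_basis")
}

#' @export
print.stain_basis <- function(x, ...) {
  cat(sprintf("<stain_basis slide=%s theta_H=%.1f deg theta_E=%.1f deg scales=(%s, %s)>\n",
              x$slide_id, x$theta_H * 180 / pi, x$theta_E * 180 / pi,
              format(x$norm_scale_H, digits = 3), format(x$norm_scale_E, digits = 3)))
  invisible(x)
}

#' Project OD pixels onto stain concentrations
#'
#' Applies the inverse stain matrix pixelwise:
#' `(alpha_H, alpha_E, alpha_res)' = Mat_RGB->HERes x V_OD`. Small negative
#' concentrations produced by noise are clipped to zero (stain amounts are
#' physically non-negative); the residual coordinate is returned unclipped
#' for reconstruction diagnostics.
#'
#' @param od numeric array `h x w x 3` (or matrix `n x 3`) of OD vectors.
#' @param basis a `stain_basis`.
#' @param max_condition maximum acceptable condition number of the forward
#'   matrix (default 1e6).
#' @return list with `h`, `e`, `residual` arrays shaped like the input plane.
#' @export
project_to_concentrations <- function(od, basis, max_condition = 1e6) {
  stopifnot(inherits(basis, "stain_basis"))
  if (kappa(basis$forward_matrix, exact = TRUE) > max_condition) {
    stop_classm("stain basis is ill-conditioned (stain vectors nearly parallel)",
                "classm_ill_conditioned_basis_error")
  }
  d <- dim(od)
  m <- if (length(d) == 3L) matrix(od, ncol = 3L) else od
  stopifnot(ncol(m) == 3L)
  a <- m %*% t(basis$inverse_matrix)
  shape_out <- function(v) if (length(d) == 3L) array(v, d[1:2]) else v
  list(h = shape_out(pmax(a[, 1], 0)),
       e = shape_out(pmax(a[, 2], 0)),
       residual = shape_out(a[, 3]))
}

#' Set per-slide normalization scales on a stain basis
#'
#' The raw concentration scale varies with stain strength, so each channel is
#' normalized by the slide's `percentile`-th concentration value (an
#' approximation of the channel maximum robust to outliers), mapped to
#' `target` and later clipped at 1. Normalization divides raw values by
#' `norm_scale / target`.
#'
#' @param basis a `stain_basis`.
#' @param h_samples,e_samples pooled raw concentration samples for the slide.
#' @param percentile quantile used as the robust maximum (default 99).
#' @param target value the percentile is mapped to (default 0.5).
#' @return the basis with `norm_scale_H`, `norm_scale_E` set.
#' @export
calibrate_norm_scales <- function(basis, h_samples, e_samples,
                                  percentile = 99, target = 0.5) {
  stopifnot(inherits(basis, "stain_basis"),
            length(h_samples) > 0, length(e_samples) > 0,
            percentile > 0, percentile <= 100, target > 0)
  scale_one <- function(x, name) {
    s <- unname(quantile(x, percentile / 100, type = 7))
    if (s <= 0) {
      warning(sprintf("degenerate stain: all %s concentrations are zero; scale set to 1", name),
              call. = FALSE)
      s <- 1
    }
    s
  }
  basis$norm_scale_H <- scale_one(h_samples, "Hematoxylin")
  basis$norm_scale_E <- scale_one(e_samples, "Eosin")
  basis$norm_target <- target
  basis
}

#' Separate a tile into normalized H and E channel images
#'
#' Composes [rgb_to_od()], [project_to_concentrations()] and per-channel
#' normalization (divide by `norm_scale / target`, clip to `[0, 1]`). All
#' tiles of a slide must be separated with that slide's calibrated basis.
#'
#' @param tile an [rgb_tile()].
#' @param basis a calibrated `stain_basis` (norm scales set).
#' @return a `channel_pair`: list with `h`, `e` matrices in `[0, 1]` and
#'   `basis_ref` (the slide id of the basis used).
#' @export
separate_tile <- function(tile, basis) {
  stopifnot(inherits(tile, "rgb_tile"), inherits(basis, "stain_basis"))
  if (!is.finite(basis$norm_scale_H) || !is.finite(basis$norm_scale_E)) {
    stop_classm("stain basis is not calibrated (norm scales unset); run calibrate_norm_scales first",
                "classm_uncalibrated_basis_error")
  }
  conc <- project_to_concentrations(rgb_to_od(tile), basis)
  channel_pair(
    h = clip(conc$h / (basis$norm_scale_H / basis$norm_target), 0, 1),
    e = clip(conc$e / (basis$norm_scale_E / basis$norm_target), 0, 1),
    basis_ref = basis$slide_id)
}

#' @rdname separate_tile
#' @param h,e numeric matrices in `[0, 1]` of equal shape.
#' @param basis_ref slide id of the basis that produced the pair.
#' @export
channel_pair <- function(h, e, basis_ref = "unknown") {
  stopifnot(is.matrix(h), is.matrix(e), all(dim(h) == dim(e)))
  structure(list(h = h, e = e, basis_ref = basis_ref), class = "channel_pair")
}

#' Globally fixed stain basis (non-adaptive ablation)
#'
#' Returns the widely used Ruifrok & Johnston H&E optical-density stain pair
#' (H = (0.650, 0.704, 0.286), E = (0.072, 0.990, 0.105), normalized to unit
#' length) assembled into the same basis structure as the adaptive fit, with
#' unit norm scales. Used for the "without adaptive stain separation"
#' ablation: every slide is separated with this one matrix.
#'
#' @param norm_target target value for normalization (default 0.5).
#' @return a calibrated `stain_basis` with `slide_id = "fixed_default"`.
#' @export
fixed_default_basis <- function(norm_target = 0.5) {
  v_h <- c(0.650, 0.704, 0.286)
  v_e <- c(0.072, 0.990, 0.105)
  v_h <- v_h / sqrt(sum(v_h^2))
  v_e <- v_e / sqrt(sum(v_e^2))
  frame <- plane_frame(v_h, v_e)
  new_stain_basis(frame$vx, frame$vy, frame$vres,
                  frame$theta_1, frame$theta_2,
                  slide_id = "fixed_default",
                  norm_scale_h = 1, norm_scale_e = 1,
                  norm_target = norm_target,
                  params = list(provenance = "Ruifrok-Johnston standard H&E OD vectors"))
}

# Orthonormal in-plane frame for a given stain-vector pair: V_x bisects the
# pair so that theta_H = -theta_E < 0 (quadrant convention holds by
# construction). Returns angles ordered (H, E).
plane_frame <- function(v_h, v_e) {
  vres <- c(v_h[2] * v_e[3] - v_h[3] * v_e[2],
            v_h[3] * v_e[1] - v_h[1] * v_e[3],
            v_h[1] * v_e[2] - v_h[2] * v_e[1])
  vres <- vres / sqrt(sum(vres^2))
  vx <- v_h + v_e
  vx <- vx / sqrt(sum(vx^2))
  vy <- c(vres[2] * vx[3] - vres[3] * vx[2],
          vres[3] * vx[1] - vres[1] * vx[3],
          vres[1] * vx[2] - vres[2] * vx[1])
  if (sum(v_e * vy) < 0) {
    vy <- -vy
    vres <- -vres
  }
  list(vx = vx, vy = vy, vres = vres,
       theta_1 = atan2(sum(v_h * vy), sum(v_h * vx)),
       theta_2 = atan2(sum(v_e * vy), sum(v_e * vx)))
}

#' Pool foreground OD pixels across a slide's tiles
#'
#' Subsamples up to `cap` foreground OD pixels (norm >= `min_od_norm`)
#' uniformly across the given tiles with a fixed seed, for slide-level basis
#' fitting.
#'
#' @param tiles list of [rgb_tile()] from one slide.
#' @param cap maximum number of pixels retained (default 200000).
#' @param min_od_norm background threshold (default 0.1).
#' @param seed integer seed for the subsample.
#' @param epsilon intensity floor for [rgb_to_od()].
#' @return numeric matrix `n x 3` of OD pixels.
#' @export
pool_od_pixels <- function(tiles, cap = 200000, min_od_norm = 0.1, seed = 1,
                           epsilon = 0.5) {
  ods <- lapply(tiles, function(t) {
    m <- matrix(rgb_to_od(t, epsilon), ncol = 3L)
    m[sqrt(rowSums(m^2)) >= min_od_norm, , drop = FALSE]
  })
  pool <- do.call(rbind, ods)
  if (nrow(pool) > cap) {
    rng <- rng_stream(seed)
    idx <- with_rng(rng, sample.int(nrow(pool), cap))
    pool <- pool[idx, , drop = FALSE]
  }
  pool
}

#' Fit and calibrate stain bases for every slide in a dataset
#'
#' Convenience wrapper: for each slide, pools foreground OD pixels over that
#' slide's tiles, fits the adaptive basis, projects the pooled pixels and
#' calibrates the normalization scales. Bases are fitted once and then reused
#' unchanged throughout training.
#'
#' @param tiles list of [rgb_tile()] (all slides mixed).
#' @param outlier_fraction,min_od_norm,min_pixels passed to [fit_stain_basis()].
#' @param percentile,target passed to [calibrate_norm_scales()].
#' @param cap,seed passed to [pool_od_pixels()].
#' @return named list of calibrated `stain_basis`, one per slide id.
#' @export
fit_slide_bases <- function(tiles, outlier_fraction = 0.01, min_od_norm = 0.1,
                            min_pixels = 1000, percentile = 99, target = 0.5,
                            cap = 200000, seed = 1) {
  ids <- vapply(tiles, function(t) t$slide_id, character(1))
  bases <- list()
  for (sid in unique(ids)) {
    pool <- pool_od_pixels(tiles[ids == sid], cap = cap,
                           min_od_norm = min_od_norm, seed = seed)
    b <- fit_stain_basis(pool, outlier_fraction = outlier_fraction,
                         min_od_norm = min_od_norm, min_pixels = min_pixels,
                         slide_id = sid)
    conc <- project_to_concentrations(pool, b)
    bases[[sid]] <- calibrate_norm_scales(b, conc$h, conc$e,
                                          percentile = percentile,
                                          target = target)
  }
  bases
}

#' Serialize stain bases to / from JSON
#'
#' The JSON round-trips every field losslessly (matrices row-major, full
#' double precision).
#'
#' @param bases named list of `stain_basis` (or a single basis).
#' @param path output / input file path.
#' @return `read_bases_json` returns a named list of `stain_basis`.
#' @export
write_bases_json <- function(bases, path) {
  if (inherits(bases, "stain_basis")) bases <- setNames(list(bases), bases$slide_id)
  ser <- lapply(bases, function(b) list(
    slide_id = b$slide_id,
    axes = as.vector(t(b$axes)),
    theta_H = b$theta_H, theta_E = b$theta_E,
    V_H = b$V_H, V_E = b$V_E,
    forward_matrix = as.vector(t(b$forward_matrix)),
    inverse_matrix = as.vector(t(b$inverse_matrix)),
    norm_scale_H = b$norm_scale_H, norm_scale_E = b$norm_scale_E,
    norm_target = b$norm_target,
    params = b$params))
  # 17 significant digits round-trip IEEE doubles
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' @rdname write_bases_json
#' @export
read_bases_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(b) {
    axes <- matrix(unlist(b$axes), 3, 3, byrow = TRUE)
    out <- new_stain_basis(axes[, 1], axes[, 2], axes[, 3],
                           b$theta_H, b$theta_E, b$slide_id,
                           norm_scale_h = b$norm_scale_H %||% NA_real_,
                           norm_scale_e = b$norm_scale_E %||% NA_real_,
                           norm_target = b$norm_target %||% 0.5,
                           params = as.list(b$params))
    # stored matrices are authoritative; recomputation is a cross-check
    out$forward_matrix <- matrix(unlist(b$forward_matrix), 3, 3, byrow = TRUE)
    out$inverse_matrix <- matrix(unlist(b$inverse_matrix), 3, 3, byrow = TRUE)
    out$V_H <- unlist(b$V_H)
    out$V_E <- unlist(b$V_E)
    out
  })
}
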