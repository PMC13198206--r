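#' Dual-encoder classifier
#'
#' The classifier consumes a co-registered pair of single-channel images (the
#' separated Hematoxylin and Eosin views of one tile) through two encoders of
#' identical architecture but disjoint parameters, averages the two feature
#' vectors elementwise and applies a linear + softmax head. The encoders'
#' features are also the embeddings compared by the cross-stain contrastive
#' loss; optional projection heads (3-layer perceptrons) can be interposed
#' for the contrastive loss only.
#'
#' Two architectures expose the same contract: `"smallconv"`, a 4-block
#' convolutional network for desk-scale runs, and `"resnet"`, a deeper
#' residual network in the spirit of an 18-layer residual encoder (no batch
#' normalization; random initialization).
#'
#' @param arch `"smallconv"` or `"resnet"`.
#' @param feature_dim encoder output dimension `D` (default 128).
#' @param n_classes number of classes `C`.
#' @param seed integer seed for He-normal initialization.
#' @param projection_heads add projection heads for the contrastive loss.
#' @param proj_dim,proj_hidden projection head output / hidden widths.
#' @return a `dual_encoder` model object.
#' @export
dual_encoder <- function(arch = c("smallconv", "resnet"), feature_dim = 128,
                         n_classes = 3, seed = 1, projection_heads = FALSE,
                         proj_dim = 64, proj_hidden = 128) {
  arch <- match.arg(arch)
  rng <- rng_stream(seed)
  model <- list(
    arch = arch, feature_dim = feature_dim, n_classes = n_classes,
    encoder_H = make_encoder(arch, feature_dim, rng),
    encoder_E = make_encoder(arch, feature_dim, rng),
    classifier = list(w = he_mat(feature_dim, n_classes, rng),
                      b = numeric(n_classes)),
    projection_heads = projection_heads)
  if (projection_heads) {
    model$proj_H <- make_mlp(feature_dim, proj_hidden, proj_dim, rng)
    model$proj_E <- make_mlp(feature_dim, proj_hidden, proj_dim, rng)
  }
  structure(model, class = "dual_encoder")
}

he_kernel <- function(cin, cout, rng) {
  array(with_rng(rng, rnorm(9 * cin * cout, 0, sqrt(2 / (9 * cin)))),
        c(3, 3, cin, cout))
}

he_mat <- function(din, dout, rng) {
  matrix(with_rng(rng, rnorm(din * dout, 0, sqrt(2 / din))), din, dout)
}

make_encoder <- function(arch, feature_dim, rng) {
  conv <- function(cin, cout) list(type = "conv", w = he_kernel(cin, cout, rng),
                                   b = numeric(cout))
  res <- function(ch) list(type = "resblock",
                           w1 = he_kernel(ch, ch, rng), b1 = numeric(ch),
                           w2 = he_kernel(ch, ch, rng), b2 = numeric(ch))
  layers <- switch(arch,
    smallconv = list(
      conv(1, 16), list(type = "relu"), list(type = "pool"),
      conv(16, 32), list(type = "relu"), list(type = "pool"),
      conv(32, 64), list(type = "relu"), list(type = "pool"),
      conv(64, feature_dim), list(type = "relu"), list(type = "gap")),
    resnet = list(
      conv(1, 16), list(type = "relu"),
      res(16), res(16), list(type = "pool"),
      conv(16, 32), list(type = "relu"),
      res(32), res(32), list(type = "pool"),
      conv(32, 64), list(type = "relu"),
      res(64), res(64), list(type = "pool"),
      conv(64, feature_dim), list(type = "relu"),
      res(feature_dim), list(type = "gap")))
  list(arch = arch, layers = layers, feature_dim = feature_dim)
}

make_mlp <- function(din, hidden, dout, rng) {
  list(w1 = he_mat(din, hidden, rng), b1 = numeric(hidden),
       w2 = he_mat(hidden, hidden, rng), b2 = numeric(hidden),
       w3 = he_mat(hidden, dout, rng), b3 = numeric(dout))
}

#' Adapt pretrained 3-channel first-layer kernels to 1 channel
#'
#' An RGB-pretrained first convolution layer is reused on single-channel
#' stain images by summing its kernels over the input-channel axis: applying
#' the summed kernel to a single-channel image gives the same response as
#' applying the original kernels to that image replicated across 3 channels.
#'
#' @param kernels numeric array `kh x kw x 3 x Cout`.
#' @return numeric array `kh x kw x 1 x Cout`.
#' @export
adapt_first_layer <- function(kernels) {
  d <- dim(kernels)
  if (length(d) != 4L || d[3] != 3L) {
    stop_classm("kernels must have exactly 3 input channels (kh x kw x 3 x Cout)",
                "classm_shape_error")
  }
  out <- kernels[, , 1, , drop = FALSE] + kernels[, , 2, , drop = FALSE] +
    kernels[, , 3, , drop = FALSE]
  array(out, c(d[1], d[2], 1L, d[4]))
}

# ---- forward / backward ----------------------------------------------------

encoder_forward <- function(enc, x) {
  cache <- vector("list", length(enc$layers))
  for (i in seq_along(enc$layers)) {
    ly <- enc$layers[[i]]
    cache[[i]] <- switch(ly$type,
      conv = list(x = x),
      relu = list(mask = x > 0),
      pool = list(dim = dim(x)),
      resblock = NULL,
      gap = list(dim = dim(x)))
    x <- switch(ly$type,
      conv = cpp_conv2d_forward(x, ly$w, ly$b),
      relu = x * cache[[i]]$mask,
      pool = cpp_avgpool2_forward(x),
      resblock = {
        h1 <- cpp_conv2d_forward(x, ly$w1, ly$b1)
        m1 <- h1 > 0
        h2 <- cpp_conv2d_forward(h1 * m1, ly$w2, ly$b2)
        s <- x + h2
        m2 <- s > 0
        cache[[i]] <- list(x = x, h1 = h1, m1 = m1, m2 = m2)
        s * m2
      },
      gap = {
        d <- dim(x)
        m <- matrix(colMeans(matrix(x, d[1] * d[2], d[3] * d[4])), d[3], d[4])
        t(m)  # B x C
      })
  }
  list(features = x, cache = cache)
}

encoder_backward <- function(enc, cache, dfeat) {
  grads <- vector("list", length(enc$layers))
  dx <- dfeat
  for (i in rev(seq_along(enc$layers))) {
    ly <- enc$layers[[i]]
    ca <- cache[[i]]
    dx <- switch(ly$type,
      conv = {
        g <- cpp_conv2d_backward(ca$x, ly$w, dx)
        grads[[i]] <- list(w = g$dw, b = g$db)
        g$dx
      },
      relu = dx * ca$mask,
      pool = cpp_avgpool2_backward(dx, ca$dim),
      resblock = {
        ds <- dx * ca$m2
        g2 <- cpp_conv2d_backward(ca$h1 * ca$m1, ly$w2, ds)
        dh1 <- g2$dx * ca$m1
        g1 <- cpp_conv2d_backward(ca$x, ly$w1, dh1)
        grads[[i]] <- list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db)
        ds + g1$dx
      },
      gap = {
        d <- ca$dim
        n_sp <- d[1] * d[2]
        # dx is B x C; spread evenly over spatial positions
        array(rep(as.vector(t(dx)) / n_sp, each = n_sp), d)
      })
  }
  grads
}

mlp_forward <- function(mlp, x) {
  h1 <- sweep(x %*% mlp$w1, 2, mlp$b1, "+"); m1 <- h1 > 0; a1 <- h1 * m1
  h2 <- sweep(a1 %*% mlp$w2, 2, mlp$b2, "+"); m2 <- h2 > 0; a2 <- h2 * m2
  out <- sweep(a2 %*% mlp$w3, 2, mlp$b3, "+")
  list(out = out, cache = list(x = x, a1 = a1, m1 = m1, a2 = a2, m2 = m2))
}

mlp_backward <- function(mlp, cache, dout) {
  g <- list()
  g$w3 <- t(cache$a2) %*% dout; g$b3 <- colSums(dout)
  da2 <- (dout %*% t(mlp$w3)) * cache$m2
  g$w2 <- t(cache$a1) %*% da2; g$b2 <- colSums(da2)
  da1 <- (da2 %*% t(mlp$w2)) * cache$m1
  g$w1 <- t(cache$x) %*% da1; g$b1 <- colSums(da1)
  list(grads = g, dx = da1 %*% t(mlp$w1))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of the dual encoder on a batch of channel pairs
#'
#' @param model a [dual_encoder()].
#' @param h_batch,e_batch numeric arrays `H x W x 1 x B` (use
#'   [stack_channels()] to build them from matrices); co-indexed.
#' @param keep_cache keep intermediate activations for a backward pass.
#' @return list with `f_H`, `f_E` (`B x D` feature matrices), `probs`
#'   (`B x C`, rows sum to 1), `logits`, and when projection heads are
#'   enabled `p_H`, `p_E` (projected features for contrastive use only).
#' @export
model_forward <- function(model, h_batch, e_batch, keep_cache = FALSE) {
  stopifnot(inherits(model, "dual_encoder"))
  if (!identical(dim(h_batch)[4], dim(e_batch)[4])) {
    stop_classm("H and E batches must have equal batch size", "classm_shape_error")
  }
  fh <- encoder_forward(model$encoder_H, h_batch)
  fe <- encoder_forward(model$encoder_E, e_batch)
  favg <- (fh$features + fe$features) / 2
  logits <- sweep(favg %*% model$classifier$w, 2, model$classifier$b, "+")
  out <- list(f_H = fh$features, f_E = fe$features,
              probs = softmax_rows(logits), logits = logits)
  if (isTRUE(model$projection_heads)) {
    ph <- mlp_forward(model$proj_H, fh$features)
    pe <- mlp_forward(model$proj_E, fe$features)
    out$p_H <- ph$out; out$p_E <- pe$out
    if (keep_cache) out$proj_cache <- list(H = ph$cache, E = pe$cache)
  }
  if (keep_cache) out$cache <- list(H = fh$cache, E = fe$cache,
                                    favg = favg, h = h_batch, e = e_batch)
  out
}

#' Stack single-channel matrices into an `H x W x 1 x B` batch array
#' @param images list of numeric matrices with equal shape.
#' @return numeric array `H x W x 1 x B`.
#' @export
stack_channels <- function(images) {
  d <- dim(images[[1]])
  array(unlist(images, use.names = FALSE), c(d[1], d[2], 1L, length(images)))
}

# Backward through head + both encoders (+ projection heads).
# dZ: B x C gradient at the logits; d_fH/d_fE: extra gradients injected at
# the feature level (contrastive terms); d_pH/d_pE at the projection level.
model_backward <- function(model, fw, dZ, d_fH = NULL, d_fE = NULL,
                           d_pH = NULL, d_pE = NULL) {
  B <- nrow(fw$probs)
  D <- model$feature_dim
  grads <- list()
  grads$classifier <- list(w = t(fw$cache$favg) %*% dZ, b = colSums(dZ))
  dfavg <- dZ %*% t(model$classifier$w)
  dfh <- dfavg / 2
  dfe <- dfavg / 2
  if (!is.null(d_fH)) dfh <- dfh + d_fH
  if (!is.null(d_fE)) dfe <- dfe + d_fE
  if (isTRUE(model$projection_heads) && !is.null(d_pH)) {
    bh <- mlp_backward(model$proj_H, fw$proj_cache$H, d_pH)
    be <- mlp_backward(model$proj_E, fw$proj_cache$E, d_pE)
    grads$proj_H <- bh$grads; grads$proj_E <- be$grads
    dfh <- dfh + bh$dx; dfe <- dfe + be$dx
  }
  grads$encoder_H <- encoder_backward(model$encoder_H, fw$cache$H, dfh)
  grads$encoder_E <- encoder_backward(model$encoder_E, fw$cache$E, dfe)
  grads
}

# ---- optimizer -------------------------------------------------------------

# Walk model parameter arrays and matching gradient entries.
param_paths <- function(model) {
  paths <- list()
  add <- function(p) paths[[length(paths) + 1L]] <<- p
  for (side in c("encoder_H", "encoder_E")) {
    for (i in seq_along(model[[side]]$layers)) {
      ly <- model[[side]]$layers[[i]]
      for (nm in intersect(names(ly), c("w", "b", "w1", "b1", "w2", "b2"))) {
        add(list(side, "layers", i, nm))
      }
    }
  }
  add(list("classifier", "w")); add(list("classifier", "b"))
  if (isTRUE(model$projection_heads)) {
    for (side in c("proj_H", "proj_E")) {
      for (nm in c("w1", "b1", "w2", "b2", "w3", "b3")) add(list(side, nm))
    }
  }
  paths
}

get_path <- function(obj, path) { for (p in path) obj <- obj[[p]]; obj }

set_path <- function(obj, path, value) {
  if (length(path) == 1L) { obj[[path[[1]]]] <- value; return(obj) }
  obj[[path[[1]]]] <- set_path(obj[[path[[1]]]], path[-1], value)
  obj
}

grad_path <- function(grads, path) {
  # gradients mirror the model tree except encoder layers drop the "layers" level
  if (path[[1]] %in% c("encoder_H", "encoder_E")) {
    grads[[path[[1]]]][[path[[3]]]][[path[[4]]]]
  } else if (path[[1]] %in% c("proj_H", "proj_E")) {
    grads[[path[[1]]]][[path[[2]]]]
  } else {
    grads[[path[[1]]]][[path[[2]]]]
  }
}

#' RMSprop optimizer state
#' @param model a [dual_encoder()].
#' @param lr initial learning rate.
#' @param rho squared-gradient smoothing constant.
#' @param eps numerical stabilizer.
#' @return an `rmsprop` state object.
#' @export
rmsprop_init <- function(model, lr = 1e-4, rho = 0.9, eps = 1e-8) {
  paths <- param_paths(model)
  v <- lapply(paths, function(p) {
    x <- get_path(model, p)
    if (is.null(dim(x))) numeric(length(x)) else array(0, dim(x))
  })
  structure(list(paths = paths, v = v, lr = lr, rho = rho, eps = eps),
            class = "rmsprop")
}

#' One RMSprop update in place
#' @param model a [dual_encoder()].
#' @param grads gradient tree from the backward pass.
#' @param state an [rmsprop_init()] state.
#' @param lr learning rate for this step (defaults to `state$lr`).
#' @return list with updated `model` and `state`.
#' @export
rmsprop_step <- function(model, grads, state, lr = state$lr) {
  for (i in seq_along(state$paths)) {
    p <- state$paths[[i]]
    g <- grad_path(grads, p)
    if (is.null(g)) next
    state$v[[i]] <- state$rho * state$v[[i]] + (1 - state$rho) * g^2
    upd <- get_path(model, p) - lr * g / (sqrt(state$v[[i]]) + state$eps)
    model <- set_path(model, p, upd)
  }
  list(model = model, state = state)
}

# ---- checkpoints -----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' Writes the parameter container (`<prefix>.rds`) and a JSON sidecar
#' (`<prefix>.json`) with architecture name, feature dimension, class count,
#' best validation balanced accuracy and epoch.
#'
#' @param model a [dual_encoder()].
#' @param prefix file path prefix.
#' @param meta named list merged into the sidecar.
#' @return `load_checkpoint` returns the model with a `meta` attribute.
#' @export
save_checkpoint <- function(model, prefix, meta = list()) {
  saveRDS(model, paste0(prefix, ".rds"))
  side <- c(list(arch = model$arch, feature_dim = model$feature_dim,
                 n_classes = model$n_classes), meta)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(prefix) {
  model <- readRDS(paste0(prefix, ".rds"))
  attr(model, "meta") <- jsonlite::read_json(paste0(prefix, ".json"),
                                             simplifyVector = TRUE)
  model
}
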