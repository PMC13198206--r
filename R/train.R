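#' Training configuration
#'
#' Defaults are the published operating point: batch 64 with 32 labeled
#' (8 per class in the 4-class profile; the 3-class profile uses 11 per
#' class giving 33), 1000 iterations per epoch, RMSprop with initial
#' learning rate 1e-4 and multiplicative per-epoch decay, early stopping
#' with patience 100 epochs, loss weights per [loss_weights()]. Ablation
#' switches select the model variants: `use_mixup = FALSE` gives the
#' contrastive-only variant (unlabeled samples contribute only through the
#' contrastive term), `use_contrastive = FALSE` drops the cross-stain loss,
#' `view_mode` swaps the stain views for raw RGB channel pairs, and
#' `use_adaptive_stains = FALSE` uses the fixed published stain matrix for
#' every slide.
#'
#' @param batch_size total batch size.
#' @param labeled_per_class labeled tiles per class per batch.
#' @param n_classes class count (checked against the data at fit time).
#' @param iterations_per_epoch training iterations per epoch.
#' @param max_epochs hard epoch cap.
#' @param patience_epochs early-stopping patience (>= 1).
#' @param lr,lr_decay initial learning rate and per-epoch decay factor.
#' @param warmup_iters iterations of labeled-only (supervised) training
#'   before the MixUp / pseudo-label / contrastive terms activate. With
#'   pretrained encoders (the paper-scale setting) this is unnecessary and
#'   defaults to 0; from random initialization it plays the same role —
#'   pseudo-labels are only useful once the classifier is better than
#'   chance.
#' @param lambda_u_rampup_iters the unlabeled-loss weight is ramped linearly
#'   from 0 to `weights$lambda_U` over this many iterations after warm-up,
#'   the usual guard against early self-confirmation on garbage
#'   pseudo-labels (0 disables the ramp).
#' @param weights a [loss_weights()].
#' @param augment an [augment_config()] (its `crop` must divide by 8 after
#'   cropping for the convolutional encoders).
#' @param view_mode one of `"HE"`, `"RedGreen"`, `"RedBlue"`, `"GreenBlue"`.
#' @param use_mixup,use_contrastive,use_rgb_aug,use_adaptive_stains,use_projection_heads
#'   ablation switches.
#' @param contrastive_kind `"triplet"` or `"infonce"`.
#' @param contrastive_aggregate `"mean"` or `"sum"` over the batch.
#' @param encoder `"smallconv"` or `"resnet"`.
#' @param feature_dim encoder feature dimension.
#' @param seed master seed; all randomness derives from it.
#' @return a `train_config`.
#' @export
train_config <- function(batch_size = 64, labeled_per_class = 8,
                         n_classes = 4, iterations_per_epoch = 1000,
                         max_epochs = 10000, patience_epochs = 100,
                         lr = 1e-4, lr_decay = 0.97,
                         warmup_iters = 0,
                         lambda_u_rampup_iters = 16000,
                         weights = loss_weights(),
                         augment = augment_config(crop = 256),
                         view_mode = c("HE", "RedGreen", "RedBlue", "GreenBlue"),
                         use_mixup = TRUE, use_contrastive = TRUE,
                         use_rgb_aug = TRUE, use_adaptive_stains = TRUE,
                         use_projection_heads = FALSE,
                         contrastive_kind = c("triplet", "infonce"),
                         contrastive_aggregate = c("mean", "sum"),
                         encoder = c("smallconv", "resnet"),
                         feature_dim = 128, seed = 1) {
  view_mode <- match.arg(view_mode)
  contrastive_kind <- match.arg(contrastive_kind)
  contrastive_aggregate <- match.arg(contrastive_aggregate)
  encoder <- match.arg(encoder)
  labeled_per_batch <- labeled_per_class * n_classes
  if (labeled_per_batch > batch_size) {
    stop_classm("labeled_per_class x n_classes exceeds batch_size",
                "classm_config_error")
  }
  if (patience_epochs < 1) stop_classm("patience must be >= 1", "classm_config_error")
  structure(list(batch_size = batch_size, labeled_per_class = labeled_per_class,
                 n_classes = n_classes, labeled_per_batch = labeled_per_batch,
                 iterations_per_epoch = iterations_per_epoch,
                 max_epochs = max_epochs, patience_epochs = patience_epochs,
                 lr = lr, lr_decay = lr_decay,
                 warmup_iters = warmup_iters,
                 lambda_u_rampup_iters = lambda_u_rampup_iters,
                 weights = weights,
                 augment = augment, view_mode = view_mode,
                 use_mixup = use_mixup, use_contrastive = use_contrastive,
                 use_rgb_aug = use_rgb_aug,
                 use_adaptive_stains = use_adaptive_stains,
                 use_projection_heads = use_projection_heads,
                 contrastive_kind = contrastive_kind,
                 contrastive_aggregate = contrastive_aggregate,
                 encoder = encoder, feature_dim = feature_dim, seed = seed),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A configuration sized for CPU runs on simulator data: small encoder,
#' small batches, short epochs, larger initial learning rate and faster
#' decay (the encoders are randomly initialized rather than pretrained, and
#' the budget is a few hundred iterations), margin scaled to the feature
#' geometry of the small encoder (`m = 37 * sqrt(D / 512)`), the published
#' batch-sum contrastive formulation, and the unlabeled-loss weight ramped
#' over the whole (short) run. Loss weights other than the margin keep
#' their published values.
#'
#' @param tile_size side of the simulator tiles the profile will see.
#' @param n_classes class count.
#' @param seed master seed.
#' @param ... overrides passed to [train_config()].
#' @export
desk_config <- function(tile_size = 96, n_classes = 3, seed = 1, ...) {
  crop <- max(16, 8 * floor(tile_size / 16))  # ~half the tile, divisible by 8
  args <- list(
    batch_size = 24, labeled_per_class = 4, n_classes = n_classes,
    iterations_per_epoch = 100, max_epochs = 15, patience_epochs = 15,
    lr = 1e-3, lr_decay = 0.9, lambda_u_rampup_iters = NULL,
    # margin scaled to the small encoder's feature geometry; contrastive
    # weight and aggregation follow the published batch-sum formulation
    weights = loss_weights(m = 13),
    contrastive_aggregate = "sum",
    augment = augment_config(crop = crop),
    encoder = "smallconv", feature_dim = 64, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  if (is.null(args$lambda_u_rampup_iters)) {
    # ramp over the whole (short) desk budget
    args$lambda_u_rampup_iters <-
      args$iterations_per_epoch * args$max_epochs
  }
  do.call(train_config, args)
}

#' Assemble a balanced training batch
#'
#' Exactly `labeled_per_class` labeled tiles per class (with replacement when
#' a class pool is smaller than requested), the remainder of the batch
#' filled with unlabeled tiles sampled uniformly.
#'
#' @param labeled_by_class list (one element per class) of index vectors into
#'   the labeled pool.
#' @param unlabeled_pool index vector of unlabeled tiles (may be empty).
#' @param config a [train_config()].
#' @param rng an [rng_stream()].
#' @return list with `labeled` (data.frame `idx`, `class_idx`) and
#'   `unlabeled` (index vector).
#' @export
balanced_batch <- function(labeled_by_class, unlabeled_pool, config, rng) {
  if (any(lengths(labeled_by_class) == 0)) {
    stop_classm("every class needs at least one labeled tile",
                "classm_config_error")
  }
  k <- config$labeled_per_class
  lab <- do.call(rbind, lapply(seq_along(labeled_by_class), function(ci) {
    pool <- labeled_by_class[[ci]]
    idx <- with_rng(rng, pool[sample.int(length(pool), k,
                                         replace = length(pool) < k)])
    data.frame(idx = idx, class_idx = ci)
  }))
  n_unlab <- config$batch_size - nrow(lab)
  unlab <- if (n_unlab > 0 && length(unlabeled_pool) > 0) {
    with_rng(rng, unlabeled_pool[sample.int(length(unlabeled_pool), n_unlab,
                                            replace = length(unlabeled_pool) < n_unlab)])
  } else integer(0)
  list(labeled = lab, unlabeled = unlab)
}

#' Build the two input views of a tile
#'
#' In `"HE"` mode delegates to [separate_tile()] with the slide's adaptive
#' basis (or the fixed default basis when adaptive separation is switched
#' off). The RGB ablation modes return the two named raw channels scaled to
#' `[0, 1]`. All modes return the same `channel_pair` contract.
#'
#' @param tile an [rgb_tile()].
#' @param basis the slide's calibrated `stain_basis` (HE mode).
#' @param config a [train_config()].
#' @return a `channel_pair`.
#' @export
make_views <- function(tile, basis, config) {
  if (config$view_mode == "HE") {
    b <- if (config$use_adaptive_stains) basis else fixed_default_basis()
    if (is.null(b)) {
      stop_classm(sprintf("no stain basis available for slide %s", tile$slide_id),
                  "classm_missing_basis_error")
    }
    return(separate_tile(tile, b))
  }
  ch <- switch(config$view_mode,
               RedGreen = c(1L, 2L), RedBlue = c(1L, 3L), GreenBlue = c(2L, 3L))
  channel_pair(tile$pixels[, , ch[1]] / tile$background_intensity,
               tile$pixels[, , ch[2]] / tile$background_intensity,
               basis_ref = "raw_rgb")
}

center_crop <- function(img, size) {
  if (is.null(size) || size >= min(dim(img))) return(img)
  r0 <- floor((nrow(img) - size) / 2)
  c0 <- floor((ncol(img) - size) / 2)
  img[r0 + seq_len(size), c0 + seq_len(size), drop = FALSE]
}

# Full augmented view pipeline for one tile.
# train = FALSE gives the deterministic evaluation pipeline: no jitter, no
# rotation/flip, center crop.
tile_to_pair <- function(tile, bases, config, rng = NULL, train = TRUE) {
  if (train && config$use_rgb_aug) {
    tile <- jitter_rgb(tile, config$augment, rng)
  }
  basis <- bases[[tile$slide_id]]
  pair <- make_views(tile, basis, config)
  if (train) {
    pair$h <- augment_channel(pair$h, config$augment, rng)
    pair$e <- augment_channel(pair$e, config$augment, rng)
  } else {
    pair$h <- center_crop(pair$h, config$augment$crop)
    pair$e <- center_crop(pair$e, config$augment$crop)
  }
  pair
}

# ---- training state --------------------------------------------------------

# Organize an in-memory dataset (from generate_dataset or load_dataset) for
# training: label maps, split indices, slide bases.
prepare_training_data <- function(ds, config, bases = NULL) {
  man <- ds$manifest
  class_names <- ds$class_names %||% sort(unique(man$label[man$label != ""]))
  if (length(class_names) != config$n_classes) {
    stop_classm(sprintf("config expects %d classes, data has %d",
                        config$n_classes, length(class_names)),
                "classm_config_error")
  }
  tiles <- lapply(ds$tiles, function(t) t$tile %||% t)
  paths <- man$tile_path
  if (is.null(bases)) {
    bases <- if (config$view_mode == "HE" && config$use_adaptive_stains) {
      fit_slide_bases(tiles[paths], seed = config$seed)
    } else list()
  }
  lab_idx <- which(man$split == "train_labeled")
  labeled_by_class <- lapply(class_names, function(cn) lab_idx[man$label[lab_idx] == cn])
  list(manifest = man, tiles = tiles, class_names = class_names,
       bases = bases,
       labeled_by_class = labeled_by_class,
       unlabeled_pool = which(man$split == "train_unlabeled"),
       val_idx = which(man$split == "val"),
       test_idx = which(man$split == "test"))
}

# Deterministic channel pairs for an index set (evaluation pipeline),
# stacked into batch arrays.
eval_pairs <- function(td, idx, config) {
  pairs <- lapply(idx, function(i)
    tile_to_pair(td$tiles[[td$manifest$tile_path[i]]], td$bases, config,
                 train = FALSE))
  list(h = stack_channels(lapply(pairs, `[[`, "h")),
       e = stack_channels(lapply(pairs, `[[`, "e")),
       labels = match(td$manifest$label[idx], td$class_names))
}

batched_probs <- function(model, h, e, chunk = 64L) {
  B <- dim(h)[4]
  out <- NULL
  for (s in seq(1L, B, by = chunk)) {
    ix <- s:min(s + chunk - 1L, B)
    fw <- model_forward(model, h[, , , ix, drop = FALSE],
                        e[, , , ix, drop = FALSE])
    out <- rbind(out, fw$probs)
  }
  out
}

#' One training iteration
#'
#' Executes the full per-iteration pipeline on an assembled batch: RGB
#' jitter, stain-view construction, independent H/E channel augmentation,
#' pseudo-labeling of unlabeled members (K augmentations, averaged and
#' sharpened; no gradient), MixUp across the shuffled labeled + unlabeled
#' pool, a forward pass, the combined loss, and one RMSprop update.
#' With `use_mixup = FALSE` samples pass through unmixed and unlabeled
#' samples contribute only through the contrastive term; with
#' `use_contrastive = FALSE` that term is dropped.
#'
#' @param model a [dual_encoder()].
#' @param opt an [rmsprop_init()] state.
#' @param td prepared training data (internal; see [fit()]).
#' @param batch output of [balanced_batch()].
#' @param config a [train_config()].
#' @param rng an [rng_stream()].
#' @param lr learning rate for this step.
#' @param lambda_u_scale multiplier in `[0, 1]` applied to the unlabeled
#'   loss weight (the ramp-up schedule; 1 = full weight).
#' @return list with updated `model`, `opt`, and `losses`
#'   (`total`, `ce`, `unlabeled`, `contrastive`).
#' @export
train_step <- function(model, opt, td, batch, config, rng, lr = config$lr,
                       lambda_u_scale = 1) {
  W <- config$weights
  W$lambda_U <- W$lambda_U * lambda_u_scale
  get_tile <- function(i) td$tiles[[td$manifest$tile_path[i]]]

  labeled <- lapply(seq_len(nrow(batch$labeled)), function(r) {
    i <- batch$labeled$idx[r]
    list(pair = tile_to_pair(get_tile(i), td$bases, config, rng),
         label = one_hot(batch$labeled$class_idx[r], config$n_classes))
  })

  n_u <- length(batch$unlabeled)
  # pure supervised ablation: unlabeled tiles play no role at all
  if (!config$use_mixup && !config$use_contrastive) n_u <- 0L
  unlabeled <- list()
  if (n_u > 0) {
    # K augmented versions of every unlabeled tile; one batched no-grad
    # forward gives the predictions to average for pseudo-labels
    K <- if (config$use_mixup) W$K else 1L
    aug_pairs <- vector("list", n_u * K)
    for (ui in seq_len(n_u)) {
      for (k in seq_len(K)) {
        aug_pairs[[(ui - 1L) * K + k]] <-
          tile_to_pair(get_tile(batch$unlabeled[ui]), td$bases, config, rng)
      }
    }
    if (config$use_mixup) {
      probs <- batched_probs(model,
                             stack_channels(lapply(aug_pairs, `[[`, "h")),
                             stack_channels(lapply(aug_pairs, `[[`, "e")))
      unlabeled <- lapply(seq_len(n_u), function(ui) {
        pm <- probs[(ui - 1L) * K + seq_len(K), , drop = FALSE]
        list(pair = aug_pairs[[(ui - 1L) * K + 1L]],
             label = label_distribution(sharpen(colMeans(pm), W$T), "pseudo"))
      })
    } else {
      unlabeled <- lapply(seq_len(n_u), function(ui)
        list(pair = aug_pairs[[ui]], label = NULL))
    }
  }

  if (config$use_mixup) {
    mx <- mixup_batch(labeled, unlabeled, alpha = W$alpha, rng = rng)
    samples <- c(mx$L_prime, mx$U_prime)
    n_l <- length(mx$L_prime)
  } else {
    samples <- c(labeled, unlabeled)
    samples <- lapply(samples, function(s)
      list(h = s$pair$h, e = s$pair$e, label = s$label))
    n_l <- length(labeled)
  }
  B <- length(samples)
  h_b <- stack_channels(lapply(samples, `[[`, "h"))
  e_b <- stack_channels(lapply(samples, `[[`, "e"))
  fw <- model_forward(model, h_b, e_b, keep_cache = TRUE)
  P <- fw$probs
  C <- config$n_classes

  Y_l <- do.call(rbind, lapply(samples[seq_len(n_l)],
                               function(s) s$label$probs))
  dZ <- matrix(0, B, C)
  dZ[seq_len(n_l), ] <- (P[seq_len(n_l), , drop = FALSE] - Y_l) / n_l

  Y_u <- NULL
  u_rows <- if (config$use_mixup && B > n_l) (n_l + 1L):B else integer(0)
  if (length(u_rows) > 0) {
    Y_u <- do.call(rbind, lapply(samples[u_rows], function(s) s$label$probs))
    P_u <- P[u_rows, , drop = FALSE]
    dP <- 2 * W$lambda_U / (C * length(u_rows)) * (P_u - Y_u)
    dZ[u_rows, ] <- P_u * (dP - rowSums(dP * P_u))
  }

  d_fH <- NULL; d_fE <- NULL; d_pH <- NULL; d_pE <- NULL
  ct_values <- NULL
  if (config$use_contrastive && B >= 2) {
    gH <- if (isTRUE(model$projection_heads)) fw$p_H else fw$f_H
    gE <- if (isTRUE(model$projection_heads)) fw$p_E else fw$f_E
    if (config$contrastive_kind == "triplet") {
      partners <- contrastive_negatives(B, rng)
      tb <- triplet_batch(gH, gE, partners, W$m)
      ct_values <- tb$loss
      wgt <- if (config$contrastive_aggregate == "mean") W$lambda_C / B else W$lambda_C
      gH_grad <- wgt * tb$g_H
      gE_grad <- wgt * tb$g_E
    } else {
      nce <- infonce_contrastive(gH, gE, temperature = W$T, grad = TRUE)
      ct_values <- nce$loss  # already a batch-level mean
      gH_grad <- W$lambda_C * nce$g_H
      gE_grad <- W$lambda_C * nce$g_E
    }
    if (isTRUE(model$projection_heads)) {
      d_pH <- gH_grad; d_pE <- gE_grad
    } else {
      d_fH <- gH_grad; d_fE <- gE_grad
    }
  }

  losses <- total_loss(Y_l, P[seq_len(n_l), , drop = FALSE],
                       Y_u, if (length(u_rows)) P[u_rows, , drop = FALSE],
                       contrastive = ct_values,
                       weights = W, n_classes = C,
                       contrastive_aggregate = config$contrastive_aggregate)
  if (!is.finite(losses$total)) {
    stop_classm(sprintf("non-finite training loss (ce=%g ul=%g ct=%g)",
                        losses$ce, losses$unlabeled, losses$contrastive),
                "classm_nonfinite_loss_error")
  }

  grads <- model_backward(model, fw, dZ, d_fH, d_fE, d_pH, d_pE)
  upd <- rmsprop_step(model, grads, opt, lr = lr)
  list(model = upd$model, opt = upd$state, losses = losses)
}

#' Train with validation-driven early stopping
#'
#' Runs epochs of `iterations_per_epoch` training steps, evaluates balanced
#' accuracy on the validation split after each epoch, keeps the best-scoring
#' model and stops when the best validation balanced accuracy has not
#' improved for `patience_epochs` epochs (or at `max_epochs`).
#'
#' @param ds dataset from [generate_dataset()] or [load_dataset()].
#' @param config a [train_config()].
#' @param model optional [dual_encoder()] to continue training; a fresh one
#'   is created from the config seed otherwise.
#' @param bases optional precomputed named list of stain bases (fitted from
#'   the data otherwise, once, before training).
#' @param out_dir optional run directory for the JSONL training log and best
#'   checkpoint.
#' @param probe_size size of the frozen probe batch used to track mean
#'   positive/negative contrastive pair distances (0 disables).
#' @return list with `model` (best checkpoint), `log` (per-epoch records),
#'   `best_balanced_accuracy`, `best_epoch`, `bases`, `probe` (distance
#'   trajectory, if enabled).
#' @export
fit <- function(ds, config, model = NULL, bases = NULL, out_dir = NULL,
                probe_size = 16) {
  t0 <- Sys.time()
  td <- prepare_training_data(ds, config, bases)
  if (length(td$val_idx) == 0 || all(lengths(td$labeled_by_class) == 0)) {
    stop_classm("need non-empty labeled training and validation splits",
                "classm_config_error")
  }
  if (is.null(model)) {
    model <- dual_encoder(config$encoder, config$feature_dim,
                          config$n_classes, seed = config$seed,
                          projection_heads = config$use_projection_heads)
  }
  opt <- rmsprop_init(model, lr = config$lr)
  rng <- rng_stream(config$seed + 1)
  val <- eval_pairs(td, td$val_idx, config)
  probe <- NULL
  if (probe_size > 0 && config$use_contrastive) {
    pi_ <- td$val_idx[seq_len(min(probe_size, length(td$val_idx)))]
    pd <- eval_pairs(td, pi_, config)
    probe <- list(h = pd$h, e = pd$e, trajectory = list())
    probe$trajectory[[1]] <- c(epoch = 0, probe_distances(model, probe))
  }

  log <- list()
  best_ba <- -Inf; best_epoch <- 0L; best_model <- model
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ep in seq_len(config$max_epochs)) {
    lr_ep <- config$lr * config$lr_decay^(ep - 1)
    acc <- c(total = 0, ce = 0, unlabeled = 0, contrastive = 0)
    for (it in seq_len(config$iterations_per_epoch)) {
      global_step <- (ep - 1) * config$iterations_per_epoch + it
      warm <- config$warmup_iters %||% 0
      ramp <- config$lambda_u_rampup_iters %||% 0
      post <- global_step - warm
      u_scale <- if (post <= 0) 0 else if (ramp > 0) min(1, post / ramp) else 1
      step_config <- config
      if (post <= 0) {  # labeled-only warm-up phase
        step_config$use_mixup <- FALSE
        step_config$use_contrastive <- FALSE
      }
      batch <- balanced_batch(td$labeled_by_class, td$unlabeled_pool,
                              step_config, rng)
      st <- train_step(model, opt, td, batch, step_config, rng, lr = lr_ep,
                       lambda_u_scale = u_scale)
      model <- st$model; opt <- st$opt
      acc <- acc + unlist(st$losses)[names(acc)]
    }
    acc <- acc / config$iterations_per_epoch
    probs <- batched_probs(model, val$h, val$e)
    ba <- balanced_accuracy_from_preds(max.col(probs, ties.method = "first"), val$labels,
                                       config$n_classes)
    if (!is.null(probe)) {
      probe$trajectory[[length(probe$trajectory) + 1L]] <-
        c(epoch = ep, probe_distances(model, probe))
    }
    rec <- list(epoch = ep, loss_total = acc[["total"]], loss_ce = acc[["ce"]],
                loss_unlabeled = acc[["unlabeled"]],
                loss_contrastive = acc[["contrastive"]], lr = lr_ep,
                val_balanced_accuracy = ba,
                wall_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")),
                seed = config$seed)
    log[[ep]] <- rec
    if (!is.null(out_dir)) {
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          sep = "", file = file.path(out_dir, "train_log.jsonl"), append = TRUE)
    }
    if (ba > best_ba) {
      best_ba <- ba; best_epoch <- ep; best_model <- model
    }
    if (ep - best_epoch >= config$patience_epochs) break
  }
  if (!is.null(out_dir)) {
    save_checkpoint(best_model, file.path(out_dir, "best"),
                    meta = list(best_val_balanced_accuracy = best_ba,
                                epoch = best_epoch, seed = config$seed,
                                config_hash = digest::digest(config)))
  }
  list(model = best_model, log = log, best_balanced_accuracy = best_ba,
       best_epoch = best_epoch, bases = td$bases, probe = probe)
}

probe_distances <- function(model, probe) {
  fw <- model_forward(model, probe$h, probe$e)
  B <- nrow(fw$f_H)
  dpos <- sqrt(rowSums((fw$f_H - fw$f_E)^2))
  dall <- as.matrix(dist(rbind(fw$f_H, fw$f_E)))[seq_len(B), B + seq_len(B)]
  dneg <- (sum(dall) - sum(diag(dall))) / (B * (B - 1))
  c(pos = mean(dpos), neg = dneg)
}

balanced_accuracy_from_preds <- function(pred, truth, n_classes) {
  recalls <- vapply(seq_len(n_classes), function(ci) {
    n <- sum(truth == ci)
    if (n == 0) NA_real_ else sum(pred == ci & truth == ci) / n
  }, numeric(1))
  mean(recalls, na.rm = TRUE)
}

#' Evaluate a model on a labeled split
#'
#' Deterministic pipeline (no jitter, center crop). Balanced accuracy is the
#' unweighted mean of per-class recalls; classes absent from the split are
#' excluded with a warning.
#'
#' @param model a [dual_encoder()].
#' @param ds dataset.
#' @param config a [train_config()].
#' @param split manifest split name (default `"test"`).
#' @param bases named list of stain bases (refitted if `NULL`).
#' @return an `eval_report`: confusion matrix (rows = truth), per-class
#'   recall / precision / F-score, balanced accuracy.
#' @export
evaluate <- function(model, ds, config, split = "test", bases = NULL) {
  td <- prepare_training_data(ds, config, bases)
  idx <- which(td$manifest$split == split)
  if (length(idx) == 0) stop_classm("split is empty", "classm_config_error")
  ev <- eval_pairs(td, idx, config)
  probs <- batched_probs(model, ev$h, ev$e)
  pred <- max.col(probs, ties.method = "first")
  cn <- td$class_names
  K <- length(cn)
  cm <- matrix(0L, K, K, dimnames = list(truth = cn, pred = cn))
  for (i in seq_along(pred)) cm[ev$labels[i], pred[i]] <- cm[ev$labels[i], pred[i]] + 1L
  eval_report_from_confusion(cm, seed = config$seed,
                             config_hash = digest::digest(config))
}

#' Build an evaluation report from a confusion matrix
#'
#' @param cm square confusion matrix, rows = truth, columns = prediction.
#' @param seed seed recorded in the report.
#' @param config_hash hash of the training configuration, for provenance.
#' @return an `eval_report` with per-class `recall`, `precision`, `f_score`,
#'   `balanced_accuracy` (= mean per-class recall over classes present) and
#'   the confusion matrix.
#' @export
eval_report_from_confusion <- function(cm, seed = NA, config_hash = NA) {
  stopifnot(is.matrix(cm), nrow(cm) == ncol(cm))
  n_true <- rowSums(cm); n_pred <- colSums(cm)
  recall <- ifelse(n_true > 0, diag(cm) / n_true, NA_real_)
  precision <- ifelse(n_pred > 0, diag(cm) / n_pred, NA_real_)
  f_score <- ifelse(!is.na(recall) & !is.na(precision) & (recall + precision) > 0,
                    2 * recall * precision / (recall + precision), NA_real_)
  if (anyNA(recall)) {
    warning("some classes are absent from the split; excluded from balanced accuracy",
            call. = FALSE)
  }
  structure(list(confusion = cm, recall = recall, precision = precision,
                 f_score = f_score,
                 balanced_accuracy = mean(recall, na.rm = TRUE),
                 seed = seed, config_hash = config_hash),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report balanced_accuracy=%.4f>\n", x$balanced_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Per-tile prediction table
#'
#' Runs the deterministic evaluation pipeline over every manifest row (or a
#' given split) and writes a CSV of tile_path, slide_id, per-class
#' probabilities and the argmax label — a flat stand-in for prediction
#' heatmaps.
#'
#' @param model a [dual_encoder()].
#' @param ds dataset.
#' @param config a [train_config()].
#' @param out_path CSV output path (optional).
#' @param split restrict to one split (default: all rows).
#' @param bases stain bases (refitted if `NULL`).
#' @return the prediction data.frame, invisibly if written.
#' @export
predict_tiles <- function(model, ds, config, out_path = NULL, split = NULL,
                          bases = NULL) {
  td <- prepare_training_data(ds, config, bases)
  idx <- if (is.null(split)) seq_len(nrow(td$manifest)) else which(td$manifest$split == split)
  missing <- setdiff(unique(td$manifest$slide_id[idx]), names(td$bases))
  if (config$view_mode == "HE" && config$use_adaptive_stains && length(missing)) {
    stop_classm(paste("missing stain basis for slide(s):",
                      paste(missing, collapse = ", ")),
                "classm_missing_basis_error")
  }
  ev <- eval_pairs(td, idx, config)
  probs <- batched_probs(model, ev$h, ev$e)
  colnames(probs) <- paste0("prob_", td$class_names)
  out <- data.frame(tile_path = td$manifest$tile_path[idx],
                    slide_id = td$manifest$slide_id[idx],
                    probs, check.names = FALSE,
                    predicted = td$class_names[max.col(probs, ties.method = "first")])
  if (!is.null(out_path)) {
    write.csv(out, out_path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
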