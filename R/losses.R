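#' Label distributions
#'
#' A label distribution is a probability vector over the `C` classes together
#' with its provenance: a true one-hot label, a pseudo-label inferred for an
#' unlabeled sample, or a MixUp-mixed label.
#'
#' @param probs non-negative numeric vector summing to 1 (within 1e-6).
#' @param provenance one of `"true"`, `"pseudo"`, `"mixed"`.
#' @return a `label_distribution`.
#' @export
label_distribution <- function(probs, provenance = c("true", "pseudo", "mixed")) {
  provenance <- match.arg(provenance)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-6) {
    stop_classm("label probabilities must be non-negative and sum to 1",
                "classm_domain_error")
  }
  structure(list(probs = probs, provenance = provenance),
            class = "label_distribution")
}

#' One-hot label distribution
#' @param class_index 1-based class index.
#' @param n_classes number of classes.
#' @export
one_hot <- function(class_index, n_classes) {
  p <- numeric(n_classes)
  p[class_index] <- 1
  label_distribution(p, "true")
}

#' Cross-stain triplet contrastive loss
#'
#' For anchor `f_H_i` (H-channel feature of sample i), positive `f_E_i`
#' (E-channel feature of the same sample) and negative `f_E_k` (E-channel
#' feature of another sample, `k != i`):
#' `max(||f_H_i - f_E_i||_2 - ||f_H_i - f_E_k||_2 + m, 0)`
#' with plain (unsquared) L2 norms and margin `m`. Zero whenever the
#' negative pair is at least `m` farther than the positive pair, so training
#' focuses on hard examples.
#'
#' @param f_H_i,f_E_i,f_E_k numeric feature vectors of equal dimension.
#' @param m non-negative margin.
#' @return non-negative scalar.
#' @export
triplet_contrastive <- function(f_H_i, f_E_i, f_E_k, m) {
  if (length(f_H_i) != length(f_E_i) || length(f_H_i) != length(f_E_k)) {
    stop_classm("feature vectors must share dimension", "classm_shape_error")
  }
  d_pos <- sqrt(sum((f_H_i - f_E_i)^2))
  d_neg <- sqrt(sum((f_H_i - f_E_k)^2))
  max(d_pos - d_neg + m, 0)
}

# Batch triplet loss and its gradients wrt f_H, f_E (B x D matrices).
# partners: index vector k(i) != i. Returns per-sample losses and gradient
# matrices (unweighted; caller applies the lambda_C / aggregation weight).
triplet_batch <- function(f_H, f_E, partners, m) {
  B <- nrow(f_H)
  dp <- f_H - f_E
  dn <- f_H - f_E[partners, , drop = FALSE]
  d_pos <- sqrt(rowSums(dp^2))
  d_neg <- sqrt(rowSums(dn^2))
  loss <- pmax(d_pos - d_neg + m, 0)
  active <- loss > 0
  g_H <- matrix(0, B, ncol(f_H)); g_E <- matrix(0, B, ncol(f_H))
  if (any(active)) {
    u_pos <- dp / pmax(d_pos, 1e-12)
    u_neg <- dn / pmax(d_neg, 1e-12)
    for (i in which(active)) {
      g_H[i, ] <- g_H[i, ] + u_pos[i, ] - u_neg[i, ]
      g_E[i, ] <- g_E[i, ] - u_pos[i, ]
      g_E[partners[i], ] <- g_E[partners[i], ] + u_neg[i, ]
    }
  }
  list(loss = loss, d_pos = d_pos, d_neg = d_neg, g_H = g_H, g_E = g_E)
}

#' InfoNCE alternative contrastive loss
#'
#' Batch-level replacement for the triplet loss: cosine similarities between
#' all H/E feature pairs are treated as logits at temperature `T`; the
#' diagonal (same-sample pair) is the positive. The loss is the mean
#' cross-entropy symmetrized over the H->E and E->H directions.
#'
#' @param f_H,f_E `B x D` feature matrices, co-indexed (`B >= 2`).
#' @param temperature positive temperature.
#' @param grad also return gradients wrt `f_H`, `f_E`.
#' @return scalar loss, or list with `loss`, `g_H`, `g_E` when `grad = TRUE`.
#' @export
infonce_contrastive <- function(f_H, f_E, temperature = 0.5, grad = FALSE) {
  stopifnot(temperature > 0)
  B <- nrow(f_H)
  if (B < 2) {
    stop_classm("InfoNCE needs at least 2 samples for negatives",
                "classm_insufficient_negatives_error")
  }
  nh <- sqrt(rowSums(f_H^2)); ne <- sqrt(rowSums(f_E^2))
  uh <- f_H / pmax(nh, 1e-12); ue <- f_E / pmax(ne, 1e-12)
  S <- uh %*% t(ue) / temperature
  P1 <- softmax_rows(S)        # H -> E direction
  P2 <- t(softmax_rows(t(S)))  # E -> H direction (softmax over columns)
  eps <- 1e-12
  loss <- -(mean(log(diag(P1) + eps)) + mean(log(diag(P2) + eps))) / 2
  if (!grad) return(loss)
  dS <- ((P1 - diag(B)) / B + (P2 - diag(B)) / B) / 2 / temperature
  g_uh <- dS %*% ue
  g_ue <- t(dS) %*% uh
  # through the normalization: d(u)/d(f) = (I - u u') / ||f||
  g_H <- (g_uh - uh * rowSums(g_uh * uh)) / pmax(nh, 1e-12)
  g_E <- (g_ue - ue * rowSums(g_ue * ue)) / pmax(ne, 1e-12)
  list(loss = loss, g_H = g_H, g_E = g_E)
}

#' Sharpen a label distribution
#'
#' Raises each class probability to the power `1/T` and renormalizes.
#' `T < 1` lowers the entropy (sharper), `T = 1` is the identity, one-hot
#' distributions are fixed points.
#'
#' @param y a [label_distribution()] or bare probability vector.
#' @param T positive temperature.
#' @return same type as `y`.
#' @export
sharpen <- function(y, T) {
  if (T <= 0) stop_classm("temperature must be positive", "classm_domain_error")
  p <- if (inherits(y, "label_distribution")) y$probs else y
  q <- p^(1 / T)
  q <- q / sum(q)
  if (inherits(y, "label_distribution")) label_distribution(q, y$provenance) else q
}

#' Pseudo-label an unlabeled sample
#'
#' Averages the model's softmax prediction over `K` independently augmented
#' versions of the sample, then sharpens with temperature `T`. Gradients do
#' not flow through pseudo-label construction (the result is a constant
#' target).
#'
#' @param predict_fn function taking an augmented sample and returning a
#'   probability vector (for the full pipeline this wraps jitter ->
#'   separation -> channel augmentation -> [model_forward()]).
#' @param x the unlabeled sample (passed to `augment_fn`).
#' @param K number of augmentations (>= 1).
#' @param T sharpening temperature.
#' @param augment_fn function `(x, rng) -> augmented sample`.
#' @param rng an [rng_stream()].
#' @return a [label_distribution()] with provenance `"pseudo"`.
#' @export
pseudo_label <- function(predict_fn, x, K, T, augment_fn = function(x, rng) x,
                         rng = rng_stream(1)) {
  stopifnot(K >= 1)
  preds <- lapply(seq_len(K), function(k) predict_fn(augment_fn(x, rng)))
  ybar <- rowMeans(do.call(cbind, preds))
  label_distribution(sharpen(ybar / sum(ybar), T), "pseudo")
}

#' Mix two channel pairs and their labels (MixUp)
#'
#' Draws `lambda ~ Beta(alpha, alpha)`, sets `lambda' = max(lambda,
#' 1 - lambda)` (so the virtual sample stays closer to its first parent,
#' whose labeled/unlabeled membership it inherits) and mixes the separated
#' H and E channel images and the labels convexly. Mixing happens on the
#' separated channels, never on RGB.
#'
#' @param x_i,x_j `channel_pair`s of equal shape.
#' @param y_i,y_j [label_distribution()]s.
#' @param alpha Beta concentration parameter.
#' @param rng an [rng_stream()].
#' @param is_labeled whether `x_i` came from the labeled set.
#' @return a `virtual_sample`: list with `h`, `e`, `label`, `lambda_prime`,
#'   `is_labeled`.
#' @export
mixup_pair <- function(x_i, y_i, x_j, y_j, alpha = 2, rng = rng_stream(1),
                       is_labeled = TRUE) {
  if (!all(dim(x_i$h) == dim(x_j$h))) {
    stop_classm("channel pairs must share shape", "classm_shape_error")
  }
  lam <- with_rng(rng, rbeta(1, alpha, alpha))
  lp <- max(lam, 1 - lam)
  yi <- if (inherits(y_i, "label_distribution")) y_i$probs else y_i
  yj <- if (inherits(y_j, "label_distribution")) y_j$probs else y_j
  structure(list(
    h = lp * x_i$h + (1 - lp) * x_j$h,
    e = lp * x_i$e + (1 - lp) * x_j$e,
    label = label_distribution(lp * yi + (1 - lp) * yj, "mixed"),
    lambda_prime = lp,
    is_labeled = is_labeled), class = "virtual_sample")
}

#' MixUp over a labeled + unlabeled batch
#'
#' Each sample `x_i` from the concatenation of the labeled set (true labels)
#' and unlabeled set (pseudo-labels) is mixed with a partner `x_j` drawn by
#' shuffling that same concatenation; virtual samples inherit the
#' labeled/unlabeled membership of `x_i`, so `|L'| = |labeled|` and
#' `|U'| = |unlabeled|`.
#'
#' @param labeled list of `list(pair = channel_pair, label = label_distribution)`.
#' @param unlabeled list of the same shape (pseudo-labels).
#' @param alpha Beta parameter.
#' @param rng an [rng_stream()].
#' @return list with `L_prime`, `U_prime` (lists of `virtual_sample`).
#' @export
mixup_batch <- function(labeled, unlabeled = list(), alpha = 2,
                        rng = rng_stream(1)) {
  all_s <- c(labeled, unlabeled)
  n <- length(all_s)
  stopifnot(n >= 1)
  perm <- with_rng(rng, sample.int(n))
  mixed <- lapply(seq_len(n), function(i) {
    j <- perm[i]
    mixup_pair(all_s[[i]]$pair, all_s[[i]]$label,
               all_s[[j]]$pair, all_s[[j]]$label,
               alpha = alpha, rng = rng,
               is_labeled = i <= length(labeled))
  })
  list(L_prime = mixed[seq_along(labeled)],
       U_prime = if (length(unlabeled)) mixed[length(labeled) + seq_along(unlabeled)] else list())
}

#' Draw negative-pair partners (derangement)
#'
#' Assigns each batch index `i` a partner `k(i) != i` for the contrastive
#' negative pair, by rejection-sampling a permutation until it has no fixed
#' point.
#'
#' @param n batch size (>= 2).
#' @param rng an [rng_stream()].
#' @return integer vector of length `n` with `k[i] != i`.
#' @export
contrastive_negatives <- function(n, rng = rng_stream(1)) {
  if (n < 2) {
    stop_classm("need at least 2 samples to form negative pairs",
                "classm_insufficient_negatives_error")
  }
  repeat {
    p <- with_rng(rng, sample.int(n))
    if (all(p != seq_len(n))) return(p)
  }
}

#' Combined training loss
#'
#' `L = mean CE over L' + lambda_U * mean over U' of ||y - yhat||^2 / C
#'    + lambda_C * aggregate of per-sample contrastive terms over L' u U'`.
#' Cross-entropy uses the natural logarithm with predictions floored at
#' 1e-8. The contrastive aggregate is the mean by default (batch-size
#' independent weighting); `contrastive_aggregate = "sum"` gives the
#' unnormalized sum.
#'
#' @param labeled_y,labeled_pred `|L'| x C` matrices of mixed labels and
#'   model predictions (rows on the simplex).
#' @param unlabeled_y,unlabeled_pred `|U'| x C` matrices (may be `NULL`).
#' @param contrastive per-sample contrastive values over `L' u U'` (may be
#'   `NULL` for none).
#' @param weights list with `lambda_U`, `lambda_C` (see [loss_weights()]).
#' @param n_classes class count `C`.
#' @param contrastive_aggregate `"mean"` or `"sum"`.
#' @return list with `total`, `ce`, `unlabeled`, `contrastive` scalars.
#' @export
total_loss <- function(labeled_y, labeled_pred, unlabeled_y = NULL,
                       unlabeled_pred = NULL, contrastive = NULL,
                       weights = loss_weights(), n_classes = ncol(labeled_y),
                       contrastive_aggregate = c("mean", "sum")) {
  contrastive_aggregate <- match.arg(contrastive_aggregate)
  if (is.null(labeled_y) || nrow(labeled_y) == 0) {
    stop_classm("labeled virtual set L' is empty; cross-entropy undefined",
                "classm_domain_error")
  }
  ce <- -mean(rowSums(labeled_y * log(pmax(labeled_pred, 1e-8))))
  ul <- if (!is.null(unlabeled_y) && nrow(unlabeled_y) > 0) {
    mean(rowSums((unlabeled_y - unlabeled_pred)^2)) / n_classes
  } else 0
  ct <- if (!is.null(contrastive) && length(contrastive) > 0) {
    if (contrastive_aggregate == "mean") mean(contrastive) else sum(contrastive)
  } else 0
  list(total = ce + weights$lambda_U * ul + weights$lambda_C * ct,
       ce = ce, unlabeled = ul, contrastive = ct)
}

#' Loss hyperparameters
#'
#' Defaults are the published operating point: unlabeled squared-loss weight
#' `lambda_U = 7.5`, contrastive weight `lambda_C = 0.1`, triplet margin
#' `m = 37`, sharpening temperature `T = 0.5`, MixUp `alpha = 2`, `K = 2`
#' augmentations for pseudo-labeling.
#'
#' @param lambda_U,lambda_C,m,T,alpha,K see description.
#' @return a `loss_weights` list.
#' @export
loss_weights <- function(lambda_U = 7.5, lambda_C = 0.1, m = 37, T = 0.5,
                         alpha = 2, K = 2) {
  stopifnot(lambda_U >= 0, lambda_C >= 0, m >= 0, T > 0, alpha > 0, K >= 1)
  structure(list(lambda_U = lambda_U, lambda_C = lambda_C, m = m, T = T,
                 alpha = alpha, K = K), class = "loss_weights")
}

#' Shannon entropy of a probability vector (nats)
#' @param p probability vector.
#' @export
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
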