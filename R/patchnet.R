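#' Tri-state mask states
#'
#' Pseudo-label masks are per-pixel grids over three states: negative (0),
#' positive (1), and ignore (2). Ignore pixels generate no loss during
#' training; they never appear in reference (ground-truth) masks, only in
#' pseudo-label masks.
#'
#' @format Integer scalars.
#' @export
TRI_NEG <- 0L

#' @rdname TRI_NEG
#' @export
TRI_POS <- 1L

#' @rdname TRI_NEG
#' @export
TRI_IGNORE <- 2L

#' Training configuration for the dual-branch patch network
#'
#' @param epochs number of epochs.
#' @param steps_per_epoch optimizer steps per epoch.
#' @param batch_size minibatch size (16 by default).
#' @param crop_size training crop side in pixels; must not exceed the image
#'   side. Inference tiles the full image with this size.
#' @param mixing_ratio labeled fraction of every minibatch when a pseudo pool
#'   is present (0.6 by default, i.e. a 0.6:0.4 labeled-to-pseudo mix).
#' @param lr Adam learning rate.
#' @param lambda_cls weight of the classification loss in the combined
#'   objective `pixel_loss + lambda_cls * classification_loss`.
#' @param channels feature channels in the two convolution layers.
#' @param image_prob_rule how a per-image probability is derived at
#'   inference: maximum of the classification-branch and pixel-map maxima
#'   (`"both"`, default), classification branch only, or pixel map only.
#' @param seed integer seed controlling initialization and data sampling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 8L, steps_per_epoch = 30L, batch_size = 16L,
                         crop_size = 32L, mixing_ratio = 0.6, lr = 0.02,
                         lambda_cls = 1, channels = 8L,
                         image_prob_rule = c("both", "class", "pixel"),
                         seed = 0L) {
  if (mixing_ratio < 0 || mixing_ratio > 1) stop("'mixing_ratio' must be in [0, 1]")
  if (batch_size < 1L) stop("'batch_size' must be >= 1")
  if (crop_size < 4L) stop("'crop_size' must be >= 4")
  structure(list(epochs = as.integer(epochs),
                 steps_per_epoch = as.integer(steps_per_epoch),
                 batch_size = as.integer(batch_size),
                 crop_size = as.integer(crop_size),
                 mixing_ratio = mixing_ratio, lr = lr,
                 lambda_cls = lambda_cls, channels = as.integer(channels),
                 image_prob_rule = match.arg(image_prob_rule),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Patch-level class label from a mask patch
#'
#' The label is 1 iff the patch contains at least one positive pixel; ignore
#' pixels carry no positive evidence and do not count.
#'
#' @param mask_patch integer matrix, binary or tri-state.
#' @return 0 or 1.
#' @export
patch_label <- function(mask_patch) {
  as.integer(any(mask_patch == TRI_POS))
}

#' Extract training or inference patches from an image
#'
#' The `"random"` sampler draws `n` uniform random crops (training); the
#' `"grid"` sampler tiles a deterministic grid with stride `crop_size`
#' covering the whole image, aligning the last row/column of tiles to the
#' image edge (inference).
#'
#' @param image numeric matrix.
#' @param mask integer matrix of the same shape, or `NULL`.
#' @param crop_size patch side; must not exceed either image dimension.
#' @param sampler `"grid"` or `"random"`.
#' @param n number of random crops (random sampler only).
#' @return List of lists with `image_patch`, `mask_patch` (or `NULL`),
#'   `patch_label` (or `NA`), and the patch origin `offset = c(row, col)`.
#' @export
extract_patches <- function(image, mask = NULL, crop_size,
                            sampler = c("grid", "random"), n = 1L) {
  sampler <- match.arg(sampler)
  nr <- nrow(image); nc <- ncol(image)
  if (crop_size > nr || crop_size > nc)
    stop("'crop_size' exceeds the image dimensions")
  offsets <- if (sampler == "grid") {
    starts <- function(total) {
      s <- seq(1L, total - crop_size + 1L, by = crop_size)
      if (s[length(s)] + crop_size - 1L < total) s <- c(s, total - crop_size + 1L)
      s
    }
    expand.grid(row = starts(nr), col = starts(nc))
  } else {
    data.frame(row = sample.int(nr - crop_size + 1L, n, replace = TRUE),
               col = sample.int(nc - crop_size + 1L, n, replace = TRUE))
  }
  lapply(seq_len(nrow(offsets)), function(i) {
    r0 <- offsets$row[i]; c0 <- offsets$col[i]
    ip <- image[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L)]
    mp <- if (!is.null(mask))
      mask[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L)] else NULL
    list(image_patch = ip, mask_patch = mp,
         patch_label = if (is.null(mp)) NA_integer_ else patch_label(mp),
         offset = c(r0, c0))
  })
}

## ---- network internals -----------------------------------------------------
## A small fully convolutional two-level encoder with a per-pixel sigmoid
## segmentation head (1x1 conv) and a global-pooled classification head.
## All convolutions are 3x3, stride 1, zero ("same") padding, so the network
## accepts any patch size. Implemented as shifted-slice matrix products.

# He-style initialization; final heads zero so an untrained model outputs 0.5.
patchnet_init <- function(channels = 8L, seed = 0L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  C <- as.integer(channels)
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  weights <- list(
    W1 = array(he(9, 9 * C), c(9, 1, C)), b1 = numeric(C),
    W2 = array(he(9 * C, 9 * C * C), c(9, C, C)), b2 = numeric(C),
    Wseg = matrix(0, C, 1), bseg = 0,
    wcls = 1, bcls = 0
  )
  structure(list(weights = weights, channels = C, seed = as.integer(seed)),
            class = "patchnet")
}

#' @export
print.patchnet <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf(
    "Dual-branch patch network: 2 conv levels x %d channels, %d parameters\n",
    x$channels, n_par))
  log <- attr(x, "train_log")
  if (!is.null(log))
    cat(sprintf("  trained %d epochs; final objective %.4f\n",
                nrow(log), log$objective[nrow(log)]))
  invisible(x)
}

# 3x3 same-padding convolution; the kernels live in src/conv3x3.cpp and use
# the same column-major (B, H, W, C) layout as the R arrays.
conv3x3_fwd <- function(x, W, b) {
  list(Z = conv3x3_fwd_cpp(x, dim(x), W, b, dim(W)[3]), x = x)
}

conv3x3_bwd <- function(dZ, x, W) {
  conv3x3_bwd_cpp(dZ, x, dim(x), W, dim(W)[3])
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# numerically stable elementwise BCE from logits
bce_from_logits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

# Full forward pass on a batch of patches.
# x: (B, H, W) array. Returns activations needed for backward.
net_forward <- function(model, x) {
  d <- dim(x); B <- d[1]; H <- d[2]; W_ <- d[3]
  C <- model$channels
  w <- model$weights
  x4 <- x; dim(x4) <- c(B, H, W_, 1L)
  c1 <- conv3x3_fwd(x4, w$W1, w$b1)
  A1 <- pmax(c1$Z, 0)
  c2 <- conv3x3_fwd(A1, w$W2, w$b2)
  A2 <- pmax(c2$Z, 0)
  A2m <- A2; dim(A2m) <- c(B * H * W_, C)
  seg_logit <- drop(A2m %*% w$Wseg) + w$bseg          # length B*H*W

  # classification head: log-sum-exp pooling of the segmentation logits
  # (a smooth "any positive pixel" readout) with an affine calibration
  S <- matrix(seg_logit, B)                           # (B, H*W); b varies fastest
  smax <- apply(S, 1, max)
  sm_exp <- exp(S - smax)                             # softmax weights cache
  lse <- smax + log(rowMeans(sm_exp))
  cls_logit <- w$wcls * lse + w$bcls
  list(B = B, H = H, W = W_, x4 = x4, c1 = c1, A1 = A1, c2 = c2, A2m = A2m,
       seg_logit = seg_logit, cls_logit = cls_logit,
       lse = lse, sm_exp = sm_exp)
}

# Backward pass. dseg: gradient wrt seg_logit (length B*H*W); dcls: wrt
# cls_logit (length B). Returns gradient list matching model$weights.
net_backward <- function(model, fwd, dseg, dcls) {
  w <- model$weights
  B <- fwd$B; H <- fwd$H; W_ <- fwd$W; C <- model$channels

  # classification head routes through the pooled segmentation logits
  dwcls <- sum(dcls * fwd$lse)
  dbcls <- sum(dcls)
  softw <- fwd$sm_exp / rowSums(fwd$sm_exp)           # (B, H*W) softmax
  dseg_total <- dseg + as.vector(softw * (dcls * w$wcls))

  dWseg <- crossprod(fwd$A2m, dseg_total)
  dbseg <- sum(dseg_total)
  dA2m <- tcrossprod(dseg_total, drop(w$Wseg))

  dA2 <- dA2m; dim(dA2) <- c(B, H, W_, C)
  dZ2 <- dA2 * (fwd$c2$Z > 0)
  g2 <- conv3x3_bwd(dZ2, fwd$c2$x, w$W2)
  dZ1 <- g2$dX * (fwd$c1$Z > 0)
  g1 <- conv3x3_bwd(dZ1, fwd$c1$x, w$W1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wseg = dWseg, bseg = dbseg, wcls = dwcls, bcls = dbcls)
}

#' Forward pass of the dual-branch network on one patch
#'
#' Deterministic (the network has no stochastic layers). An untrained model
#' has zero-initialized output heads, so it returns a class probability of
#' 0.5 and a uniform 0.5 probability map.
#'
#' @param model a `patchnet`.
#' @param image_patch numeric matrix.
#' @return List with `class_prob` (scalar in [0, 1]) and `prob_map` (matrix
#'   of the patch's shape with values in [0, 1]).
#' @export
forward <- function(model, image_patch) {
  stopifnot(inherits(model, "patchnet"), is.matrix(image_patch))
  x <- array(image_patch, c(1L, nrow(image_patch), ncol(image_patch)))
  fwd <- net_forward(model, x)
  pm <- matrix(sigmoid(fwd$seg_logit), nrow(image_patch), ncol(image_patch))
  list(class_prob = sigmoid(fwd$cls_logit[1]), prob_map = pm)
}

#' Masked binary cross-entropy over a tri-state mask
#'
#' Mean binary cross-entropy of the probability map against the mask over
#' non-ignore pixels only; ignore pixels generate no loss. If every pixel is
#' ignore, the loss is 0 by convention.
#'
#' @param prob_map numeric matrix of probabilities in [0, 1].
#' @param tri_mask integer matrix over `{TRI_NEG, TRI_POS, TRI_IGNORE}`.
#' @param eps clamp keeping `log` finite.
#' @return Nonnegative scalar.
#' @export
masked_pixel_loss <- function(prob_map, tri_mask, eps = 1e-7) {
  stopifnot(all(dim(prob_map) == dim(tri_mask)))
  valid <- tri_mask != TRI_IGNORE
  if (!any(valid)) return(0)
  p <- pmin(pmax(prob_map[valid], eps), 1 - eps)
  y <- as.numeric(tri_mask[valid] == TRI_POS)
  mean(-(y * log(p) + (1 - y) * log(1 - p)))
}

#' Binary cross-entropy of the classification branch
#'
#' @param class_prob probability in [0, 1].
#' @param label 0 or 1.
#' @param eps clamp keeping `log` finite.
#' @return Nonnegative scalar.
#' @export
classification_loss <- function(class_prob, label, eps = 1e-7) {
  if (!label %in% c(0, 1)) stop("'label' must be 0 or 1")
  p <- pmin(pmax(class_prob, eps), 1 - eps)
  -(label * log(p) + (1 - label) * log(1 - p))
}

## ---- training ---------------------------------------------------------------

# Flatten exam records (with public masks) into a pool of image-level samples.
# Pseudo datasets are already sample pools.
as_sample_pool <- function(source) {
  if (inherits(source, "pseudo_dataset")) return(source$samples)
  if (inherits(source, "exam_record")) source <- list(source)
  pool <- list()
  for (exam in source) {
    masks <- exam_masks(exam)
    for (i in seq_along(exam$images)) {
      pool[[length(pool) + 1L]] <- list(image = exam$images[[i]],
                                        mask = masks[[i]],
                                        whole_image = FALSE)
    }
  }
  pool
}

#' Compose one mixed minibatch from labeled and pseudo pools
#'
#' Draws `round(mixing_ratio * batch_size)` samples from the labeled pool and
#' the remainder from the pseudo pool, each uniformly with replacement.
#'
#' @param labeled_pool,pseudo_pool lists of samples (`pseudo_pool` may be
#'   `NULL`, in which case the whole batch is labeled).
#' @param mixing_ratio labeled fraction per minibatch.
#' @param batch_size total samples per minibatch.
#' @return List of samples; each carries a `source` field
#'   (`"labeled"`/`"pseudo"`).
#' @export
mixed_minibatch <- function(labeled_pool, pseudo_pool, mixing_ratio,
                            batch_size) {
  if (length(labeled_pool) == 0L) stop("labeled pool is empty")
  if (is.null(pseudo_pool) || mixing_ratio >= 1) {
    n_lab <- batch_size
  } else {
    if (length(pseudo_pool) == 0L) stop("pseudo pool is empty")
    if (batch_size < 2L) stop("'batch_size' must be >= 2 when mixing two pools")
    n_lab <- round(mixing_ratio * batch_size)
  }
  n_pse <- batch_size - n_lab
  batch <- vector("list", batch_size)
  if (n_lab > 0L) {
    idx <- sample.int(length(labeled_pool), n_lab, replace = TRUE)
    for (i in seq_len(n_lab)) {
      s <- labeled_pool[[idx[i]]]; s$source <- "labeled"; batch[[i]] <- s
    }
  }
  if (n_pse > 0L) {
    idx <- sample.int(length(pseudo_pool), n_pse, replace = TRUE)
    for (i in seq_len(n_pse)) {
      s <- pseudo_pool[[idx[i]]]; s$source <- "pseudo"; batch[[n_lab + i]] <- s
    }
  }
  batch
}

# Crop (and possibly augment) one sample down to the training patch.
# Half of the crops of lesion-bearing images are centered near a random
# positive pixel: at desk scale a uniform crop rarely covers the few lesion
# pixels, and the biased draw keeps the pixel-loss classes balanced enough
# to learn from in a few hundred steps.
prepare_sample <- function(s, crop_size, augment, pos_bias = 0.5) {
  if (!is.null(augment) && !isTRUE(s$whole_image)) {
    a <- augment_sample(s$image, s$mask, augment)
    s$image <- a$image; s$mask <- a$mask
  }
  if (isTRUE(s$whole_image)) return(s)
  nr <- nrow(s$image); nc <- ncol(s$image)
  if (nr > crop_size) {
    pos <- which(s$mask == TRI_POS)
    if (length(pos) && stats::runif(1) < pos_bias) {
      k <- pos[sample.int(length(pos), 1L)]
      pr <- (k - 1L) %% nr + 1L
      pc <- (k - 1L) %/% nr + 1L
      jitter <- as.integer(stats::runif(2, -crop_size / 4, crop_size / 4))
      r0 <- min(max(pr - crop_size %/% 2L + jitter[1], 1L), nr - crop_size + 1L)
      c0 <- min(max(pc - crop_size %/% 2L + jitter[2], 1L), nc - crop_size + 1L)
    } else {
      r0 <- sample.int(nr - crop_size + 1L, 1L)
      c0 <- sample.int(nc - crop_size + 1L, 1L)
    }
  } else {
    r0 <- 1L; c0 <- 1L
  }
  s$image <- s$image[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L)]
  s$mask <- s$mask[r0:(r0 + crop_size - 1L), c0:(c0 + crop_size - 1L)]
  s
}

adam_step <- function(weights, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      clip_norm = 5) {
  # global-norm gradient clipping guards the shared trunk against the
  # occasional huge max-pool gradient from the classification head
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  scale <- if (is.finite(gnorm) && gnorm > clip_norm) clip_norm / gnorm else 1
  for (nm in names(weights)) {
    g <- grads[[nm]] * scale
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(weights = weights, state = state)
}

# forward + losses + backward for one same-shaped group of samples.
# Returns grads (scaled for pooling across groups), loss terms and counts.
group_pass <- function(model, samples, lambda_cls, batch_total) {
  B <- length(samples)
  H <- nrow(samples[[1]]$image); W_ <- ncol(samples[[1]]$image)
  x <- array(0, c(B, H, W_))
  tri <- array(TRI_IGNORE, c(B, H, W_))
  y <- numeric(B)
  for (i in seq_len(B)) {
    x[i, , ] <- samples[[i]]$image
    tri[i, , ] <- samples[[i]]$mask
    y[i] <- if (!is.null(samples[[i]]$label_override))
      samples[[i]]$label_override else patch_label(samples[[i]]$mask)
  }
  fwd <- net_forward(model, x)
  triv <- as.vector(tri)
  valid <- triv != TRI_IGNORE
  n_valid <- sum(valid)
  p_seg <- sigmoid(fwd$seg_logit)
  t_seg <- as.numeric(triv == TRI_POS)
  pix_loss_sum <- if (n_valid)
    sum(bce_from_logits(fwd$seg_logit[valid], t_seg[valid])) else 0
  dseg <- numeric(length(triv))
  # gradient deferred: scaled later by the pooled 1/n_valid
  dseg[valid] <- (p_seg[valid] - t_seg[valid])

  p_cls <- sigmoid(fwd$cls_logit)
  cls_loss_sum <- sum(bce_from_logits(fwd$cls_logit, y))
  dcls <- lambda_cls * (p_cls - y) / batch_total

  # per-source pixel-term accounting (audit hook for Oracle contracts)
  src <- vapply(samples, function(s) s$source %||% "labeled", character(1))
  valid_per_sample <- rowsum(as.numeric(valid),
                             rep_len(seq_len(B), length(triv)))[, 1]
  list(fwd = fwd, dseg = dseg, dcls = dcls,
       pix_loss_sum = pix_loss_sum, n_valid = n_valid,
       cls_loss_sum = cls_loss_sum, B = B,
       pixel_terms_by_source = tapply(valid_per_sample, src, sum))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the dual-branch patch network
#'
#' Gradient-based minimization (Adam) of the combined objective
#' `masked pixel BCE + lambda_cls * classification BCE` over random crops.
#' When a pseudo pool is given, every minibatch mixes labeled and pseudo
#' samples at `config$mixing_ratio`. When `init` is given, optimization
#' starts from those weights (the student is initialized from the teacher).
#' Fully seeded and reproducible.
#'
#' @param labeled_source list of labeled `exam_record`s (or a sample pool).
#' @param pseudo_source optional `pseudo_dataset` (or sample pool).
#' @param config a [train_config()].
#' @param augment optional [augment_config()]; `NULL` disables noising.
#' @param init optional `patchnet` whose weights initialize the optimizer.
#' @return A trained `patchnet`; attribute `train_log` holds per-epoch
#'   objective values and sampling/pixel-term counts, attribute `provenance`
#'   records the init model.
#' @export
train_patchnet <- function(labeled_source, pseudo_source = NULL,
                           config = train_config(), augment = NULL,
                           init = NULL) {
  if (length(labeled_source) == 0L) stop("'labeled_source' must be non-empty")
  labeled_pool <- if (inherits(labeled_source, "exam_record") ||
                      inherits(labeled_source[[1]], "exam_record") ||
                      inherits(labeled_source, "pseudo_dataset"))
    as_sample_pool(labeled_source) else labeled_source
  pseudo_pool <- if (is.null(pseudo_source)) NULL else {
    if (inherits(pseudo_source, "pseudo_dataset")) pseudo_source$samples
    else pseudo_source
  }
  crop <- config$crop_size
  side <- nrow(labeled_pool[[1]]$image)
  if (crop > side) stop("'crop_size' exceeds the image side")

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  model <- if (is.null(init)) patchnet_init(config$channels, seed = config$seed)
           else init
  weights <- model$weights
  state <- list(m = lapply(weights, function(w) w * 0),
                v = lapply(weights, function(w) w * 0))
  t_step <- 0L
  log <- data.frame(epoch = integer(), objective = numeric(),
                    n_labeled = integer(), n_pseudo = integer(),
                    pixel_terms_labeled = numeric(),
                    pixel_terms_pseudo = numeric())

  for (epoch in seq_len(config$epochs)) {
    ep_obj <- 0; ep_lab <- 0L; ep_pse <- 0L
    ep_pix_lab <- 0; ep_pix_pse <- 0
    for (step in seq_len(config$steps_per_epoch)) {
      batch <- mixed_minibatch(labeled_pool, pseudo_pool,
                               config$mixing_ratio, config$batch_size)
      batch <- lapply(batch, prepare_sample, crop_size = crop,
                      augment = augment)
      src <- vapply(batch, function(s) s$source %||% "labeled", character(1))
      ep_lab <- ep_lab + sum(src == "labeled")
      ep_pse <- ep_pse + sum(src == "pseudo")

      # group by patch shape (Oracle image mode feeds whole-image patches)
      shapes <- vapply(batch, function(s) paste(dim(s$image), collapse = "x"),
                       character(1))
      groups <- split(batch, shapes)
      B_total <- length(batch)
      passes <- lapply(groups, group_pass, model = model,
                       lambda_cls = config$lambda_cls, batch_total = B_total)
      n_valid_total <- sum(vapply(passes, `[[`, 0, "n_valid"))
      pix_loss <- if (n_valid_total)
        sum(vapply(passes, `[[`, 0, "pix_loss_sum")) / n_valid_total else 0
      cls_loss <- sum(vapply(passes, `[[`, 0, "cls_loss_sum")) / B_total
      objective <- pix_loss + config$lambda_cls * cls_loss

      grads <- NULL
      for (ps in passes) {
        dseg <- if (n_valid_total) ps$dseg / n_valid_total else ps$dseg * 0
        g <- net_backward(model, ps$fwd, dseg, ps$dcls)
        grads <- if (is.null(grads)) g else
          Map(function(a, b) a + b, grads, g)
        terms <- ps$pixel_terms_by_source
        ep_pix_lab <- ep_pix_lab + sum(terms[names(terms) == "labeled"])
        ep_pix_pse <- ep_pix_pse + sum(terms[names(terms) != "labeled"])
      }
      t_step <- t_step + 1L
      upd <- adam_step(weights, grads, state, config$lr, t_step)
      weights <- upd$weights; state <- upd$state
      model$weights <- weights
      ep_obj <- ep_obj + objective
    }
    log <- rbind(log, data.frame(
      epoch = epoch, objective = ep_obj / config$steps_per_epoch,
      n_labeled = ep_lab, n_pseudo = ep_pse,
      pixel_terms_labeled = ep_pix_lab, pixel_terms_pseudo = ep_pix_pse))
  }
  model$config <- config
  attr(model, "train_log") <- log
  attr(model, "provenance") <- list(
    init_model = if (is.null(init)) "random" else checkpoint_id(init),
    seed = config$seed)
  model
}

# short deterministic id for a model's weights (provenance records)
checkpoint_id <- function(model) {
  v <- unlist(model$weights, use.names = FALSE)
  sprintf("patchnet-%08x", sum(as.integer(
    abs(v[seq(1, length(v), length.out = 64)]) * 1e6) %% 65536L) +
    length(v) * 131L)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the weights, the training configuration and seed,
#' and the provenance record (which model initialized training).
#'
#' @param model a `patchnet`.
#' @param path file path.
#' @return `write_checkpoint` returns `path` invisibly; `read_checkpoint`
#'   returns the `patchnet`.
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "patchnet"))
  saveRDS(list(weights = model$weights, channels = model$channels,
               config = model$config, train_log = attr(model, "train_log"),
               provenance = attr(model, "provenance")), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  model <- structure(list(weights = x$weights, channels = x$channels,
                          config = x$config, seed = x$provenance$seed),
                     class = "patchnet")
  attr(model, "train_log") <- x$train_log
  attr(model, "provenance") <- x$provenance
  model
}

## ---- inference --------------------------------------------------------------

# predict one image: stitch grid-tile probability maps (overlaps averaged),
# and derive the per-image probability per the configured rule.
predict_image <- function(model, image, crop_size, rule = "both") {
  patches <- extract_patches(image, NULL, crop_size, sampler = "grid")
  B <- length(patches)
  x <- array(0, c(B, crop_size, crop_size))
  for (i in seq_len(B)) x[i, , ] <- patches[[i]]$image_patch
  fwd <- net_forward(model, x)
  pm <- array(sigmoid(fwd$seg_logit), c(B, crop_size, crop_size))
  cls <- sigmoid(fwd$cls_logit)
  acc <- matrix(0, nrow(image), ncol(image))
  cnt <- matrix(0, nrow(image), ncol(image))
  for (i in seq_len(B)) {
    o <- patches[[i]]$offset
    rr <- o[1]:(o[1] + crop_size - 1L); cc <- o[2]:(o[2] + crop_size - 1L)
    acc[rr, cc] <- acc[rr, cc] + pm[i, , ]
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  prob_map <- acc / cnt
  image_prob <- switch(rule,
    class = max(cls),
    pixel = max(prob_map),
    both = max(max(cls), max(prob_map)))
  list(prob_map = prob_map, image_prob = image_prob, class_probs = cls)
}

#' Predict an examination
#'
#' Tiles every image with a deterministic grid of patches, stitches the
#' per-pixel probability maps (overlapping regions averaged), derives a
#' per-image probability (by default the maximum of the classification-branch
#' probabilities and the maximum pixel probability), and aggregates the
#' examination score as the maximum over per-image probabilities (the
#' any-positive-image rule).
#'
#' @param model a trained `patchnet`.
#' @param exam an `exam_record`.
#' @param crop_size tile size; defaults to the model's training crop.
#' @return An `exam_prediction`: list with `exam_id`, `image_probs`,
#'   `prob_maps`, `exam_score`.
#' @export
predict_exam <- function(model, exam,
                         crop_size = model$config$crop_size %||% 32L) {
  stopifnot(inherits(model, "patchnet"), inherits(exam, "exam_record"))
  rule <- model$config$image_prob_rule %||% "both"
  preds <- lapply(exam$images, predict_image, model = model,
                  crop_size = crop_size, rule = rule)
  image_probs <- vapply(preds, `[[`, 0, "image_prob")
  structure(list(exam_id = exam$exam_id,
                 image_probs = image_probs,
                 prob_maps = lapply(preds, `[[`, "prob_map"),
                 exam_score = max(image_probs)),
            class = "exam_prediction")
}

#' @export
predict.patchnet <- function(object, newdata, ...) {
  if (inherits(newdata, "exam_record")) return(predict_exam(object, newdata))
  lapply(newdata, predict_exam, model = object)
}

#' @export
print.exam_prediction <- function(x, ...) {
  cat(sprintf("Prediction for exam '%s': score %.3f (%d images: %s)\n",
              x$exam_id, x$exam_score, length(x$image_probs),
              paste(sprintf("%.2f", x$image_probs), collapse = ", ")))
  invisible(x)
}
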