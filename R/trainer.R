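
# Training engine: preprocessing and augmentation policy, Adam optimization
# of the MIL loss, random hyperparameter search, model selection by
# validation AUROC, and ensembling of the best models.

#' Resize, channel-replicate and normalize a raw image
#'
#' Bilinear resize to `size x size`, replication of a grayscale image across
#' 3 channels, then normalization. The default scheme standardizes by a
#' global mean/sd (the trainer computes these once on the training split and
#' stores them in the checkpoint so train and test see the same transform);
#' `"minmax"` rescales each image to \[0, 1\] independently.
#'
#' @param raw_image numeric matrix (grayscale) or `H x W x 3` array with
#'   values in \[0, 1\]; at least 8 x 8.
#' @param size output side in pixels.
#' @param norm list with `mean` and `sd` for the global scheme.
#' @param scheme `"global"`, `"minmax"` or `"none"`.
#' @return `size x size x 3` numeric array.
#' @export
preprocess <- function(raw_image, size, norm = list(mean = 0.5, sd = 0.25),
                       scheme = c("global", "minmax", "none")) {
  scheme <- match.arg(scheme)
  if (is.null(raw_image) || length(raw_image) == 0)
    stop_field("raw_image", "empty image")
  chans <- if (length(dim(raw_image)) == 3) {
    lapply(seq_len(dim(raw_image)[3]), function(c) raw_image[, , c])
  } else {
    list(as.matrix(raw_image))
  }
  if (nrow(chans[[1]]) < 8 || ncol(chans[[1]]) < 8)
    stop_field("raw_image", "must be at least 8 x 8 pixels")
  chans <- lapply(chans, function(ch) {
    if (nrow(ch) == size && ncol(ch) == size) ch
    else as.matrix(EBImage::resize(ch, w = size, h = size))
  })
  if (length(chans) == 1) chans <- rep(chans, 3)
  out <- array(0, c(size, size, 3))
  for (c in 1:3) out[, , c] <- chans[[c]]
  switch(scheme,
         global = (out - norm$mean) / norm$sd,
         minmax = {
           rng <- range(out)
           if (diff(rng) == 0) out * 0 else (out - rng[1]) / diff(rng)
         },
         none = out)
}

#' Training-time augmentation policy
#'
#' Defaults follow the standard policy for this task: horizontal flip with
#' probability 0.5, rotation within +/-45 degrees, translation up to 10% of
#' the image size in each direction, isotropic scaling in \[0.7, 1.5\] and
#' shear within +/-25 degrees.
#'
#' @param hflip_prob probability of a horizontal flip.
#' @param rotation max absolute rotation, degrees.
#' @param translation max absolute translation, fraction of image size.
#' @param scale scaling factor range.
#' @param shear max absolute shear, degrees.
#' @param vflip_prob probability of a vertical flip (0 in the standard
#'   policy; useful for synthetic data with no anatomical up-down).
#' @return an `augment_config`.
#' @export
augment_config <- function(hflip_prob = 0.5, rotation = 45,
                           translation = 0.10, scale = c(0.7, 1.5),
                           shear = 25, vflip_prob = 0) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1, rotation >= 0,
            translation >= 0, length(scale) == 2, scale[1] <= scale[2],
            scale[1] > 0, shear >= 0, vflip_prob >= 0, vflip_prob <= 1)
  structure(list(hflip_prob = hflip_prob, rotation = rotation,
                 translation = translation, scale = scale, shear = shear,
                 vflip_prob = vflip_prob),
            class = "augment_config")
}

#' Flip-only augmentation policy
#'
#' Random horizontal and vertical flips with no geometric warping: exact,
#' label- and lesion-preserving, and sufficient to break any fixed-position
#' shortcut a model might otherwise learn. The desk-scale training profile
#' uses this policy.
#'
#' @param hflip_prob,vflip_prob flip probabilities.
#' @return an `augment_config`.
#' @export
flip_augment_config <- function(hflip_prob = 0.5, vflip_prob = 0.5) {
  augment_config(hflip_prob = hflip_prob, rotation = 0, translation = 0,
                 scale = c(1, 1), shear = 0, vflip_prob = vflip_prob)
}

identity_augment_config <- function() {
  augment_config(hflip_prob = 0, rotation = 0, translation = 0,
                 scale = c(1, 1), shear = 0)
}

draw_augment_params_ <- function(config) {
  list(flip = stats::runif(1) < config$hflip_prob,
       vflip = stats::runif(1) < (config$vflip_prob %||% 0),
       theta = stats::runif(1, -config$rotation, config$rotation) * pi / 180,
       shear = stats::runif(1, -config$shear, config$shear) * pi / 180,
       scale = stats::runif(1, config$scale[1], config$scale[2]),
       trans = stats::runif(2, -config$translation, config$translation))
}

apply_affine_ <- function(image, par) {
  as_mat <- is.matrix(image)
  chans <- if (as_mat) list(image) else
    lapply(seq_len(dim(image)[3]), function(c) image[, , c])
  size <- nrow(chans[[1]])
  flip_m <- diag(c(if (par$vflip) -1 else 1, if (par$flip) -1 else 1))
  rot <- rbind(c(cos(par$theta), -sin(par$theta)),
               c(sin(par$theta), cos(par$theta)))
  shear_m <- rbind(c(1, tan(par$shear)), c(0, 1))
  A <- rot %*% shear_m %*% (par$scale * flip_m)
  # EBImage::affine works in 0-based pixel coordinates; the image center
  # about which rotation/scale/shear act is at size/2
  c0 <- c(size / 2, size / 2)
  offset <- c0 - as.vector(A %*% c0) + par$trans * size
  m <- rbind(t(A), offset)
  out <- lapply(chans, function(ch)
    as.matrix(EBImage::affine(ch, m, filter = "bilinear", bg.col = 0)))
  if (as_mat) return(out[[1]])
  arr <- array(0, dim(image))
  for (c in seq_along(out)) arr[, , c] <- out[[c]]
  arr
}

#' Randomly augment one image
#'
#' Draws flip/rotation/translation/scale/shear parameters inside the
#' configured ranges and applies them as a single bilinear affine warp
#' (background filled with 0). Deterministic under a fixed seed; with all
#' ranges collapsed (see [identity_augment_config()]) the output equals the
#' input exactly.
#'
#' @param image numeric matrix or `H x W x 3` array.
#' @param config an [augment_config()].
#' @param seed optional RNG seed.
#' @return augmented image, same shape.
#' @export
augment <- function(image, config = augment_config(), seed = NULL) {
  with_seed_(seed, {
    par <- draw_augment_params_(config)
    warped <- par$theta != 0 || par$shear != 0 || par$scale != 1 ||
      any(par$trans != 0)
    if (!warped) {
      # flips alone are exact index reversals; skip the interpolating warp
      if (par$flip) image <- if (is.matrix(image)) image[, ncol(image):1]
                            else image[, dim(image)[2]:1, , drop = FALSE]
      if (par$vflip) image <- if (is.matrix(image)) image[nrow(image):1, ]
                             else image[dim(image)[1]:1, , , drop = FALSE]
      image
    } else {
      apply_affine_(image, par)
    }
  })
}

#' Hyperparameter search space
#'
#' Log-uniform ranges (base-10 exponents) for the learning rate, saliency
#' regularization weight and weight decay, and a uniform range for the
#' pooling fraction.
#'
#' @param lr_log,beta_log,wd_log exponent intervals for learning rate
#'   (default \[-5.5, -4\]), regularization weight (\[-3, 0.5\]) and weight
#'   decay (\[-6, -3.5\]).
#' @param t_range pooling-fraction interval (default \[0.1, 0.5\]).
#' @param n_trials number of random-search trials (default 30).
#' @return a `search_space`.
#' @export
search_space <- function(lr_log = c(-5.5, -4), beta_log = c(-3, 0.5),
                         wd_log = c(-6, -3.5), t_range = c(0.1, 0.5),
                         n_trials = 30) {
  structure(list(lr_log = lr_log, beta_log = beta_log, wd_log = wd_log,
                 t_range = t_range, n_trials = as.integer(n_trials)),
            class = "search_space")
}

#' Training configuration
#'
#' @param lr Adam learning rate (> 0).
#' @param beta saliency regularization weight (>= 0).
#' @param weight_decay decoupled weight-decay coefficient (> 0).
#' @param t pooling fraction in (0, 1].
#' @param epochs training epochs.
#' @param seed RNG seed governing initialization, shuffling and augmentation.
#' @param augment an [augment_config()], or `NULL` to disable augmentation.
#' @param clip_norm global gradient-norm clip (per optimizer step); `Inf`
#'   disables clipping. Per-breast batches occasionally produce loss spikes
#'   that scramble the weights without it.
#' @param warmup_epochs representation warm-up: for this many initial epochs
#'   the saliency regularizer is off (`beta = 0`) and the pooling fraction
#'   is `t`; afterwards `beta` applies and the pooling fraction switches to
#'   `t_final`. A nonzero regularizer before features have formed drives the
#'   sigmoid saliency into saturation and training dies; dense pooling is
#'   likewise needed early so lesion cells receive gradient at all.
#' @param t_final pooling fraction after the warm-up (defaults to `t`).
#' @return a `train_config`.
#' @export
train_config <- function(lr = 1e-3, beta = 3e-3, weight_decay = 1e-5,
                         t = 0.25, epochs = 10, seed = 1,
                         augment = augment_config(), clip_norm = 5,
                         warmup_epochs = 0, t_final = NULL) {
  if (lr <= 0) stop_field("lr", "must be > 0")
  if (beta < 0) stop_field("beta", "must be >= 0")
  if (weight_decay <= 0) stop_field("weight_decay", "must be > 0")
  if (t <= 0 || t > 1) stop_field("t", "must be in (0, 1]")
  if (clip_norm <= 0) stop_field("clip_norm", "must be > 0")
  t_final <- t_final %||% t
  if (t_final <= 0 || t_final > 1) stop_field("t_final", "must be in (0, 1]")
  if (warmup_epochs < 0) stop_field("warmup_epochs", "must be >= 0")
  structure(list(lr = lr, beta = beta, weight_decay = weight_decay, t = t,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 augment = augment, clip_norm = clip_norm,
                 warmup_epochs = as.integer(warmup_epochs),
                 t_final = t_final),
            class = "train_config")
}

#' Draw a training configuration from the search space
#'
#' Log-scale parameters are uniform in the exponent; the pooling fraction is
#' uniform on its interval.
#'
#' @param space a [search_space()].
#' @param epochs epochs for the drawn configuration.
#' @param seed RNG seed (also stored in the returned config).
#' @return a [train_config()].
#' @export
sample_hyperparams <- function(space, epochs = 10, seed = NULL) {
  stopifnot(inherits(space, "search_space"))
  with_seed_(seed, {
    train_config(
      lr = 10^stats::runif(1, space$lr_log[1], space$lr_log[2]),
      beta = 10^stats::runif(1, space$beta_log[1], space$beta_log[2]),
      weight_decay = 10^stats::runif(1, space$wd_log[1], space$wd_log[2]),
      t = stats::runif(1, space$t_range[1], space$t_range[2]),
      epochs = epochs,
      seed = seed %||% sample.int(1e6, 1))
  })
}

exam_images_ <- function(exam) exam$images
exam_labels_ <- function(exam) c(y_b = exam$label_benign, y_m = exam$label_malignant)

norm_stats_ <- function(exams, size) {
  px <- unlist(lapply(exams, function(e)
    lapply(exam_images_(e), function(im)
      if (nrow(im) == size) im else as.matrix(EBImage::resize(im, size, size)))))
  list(mean = mean(px), sd = stats::sd(px))
}

preprocess_set_ <- function(images, size, norm) {
  lapply(images, preprocess, size = size, norm = norm, scheme = "global")
}

val_scores_ <- function(weights, config, norm, val_pre) {
  model <- structure(list(config = config, weights = weights, norm = norm),
                     class = "mil_model")
  vapply(val_pre, function(imgs) mil_forward(imgs, model)$y_m, numeric(1))
}

#' Train the MIL model on breast-level labels
#'
#' One Adam step per breast (the natural batch for variable-size image sets),
#' with decoupled weight decay and the augmentation policy applied to every
#' image each epoch. After each epoch the malignant-head AUROC is computed
#' on the validation set; the returned weights are from the epoch with the
#' highest validation AUROC. With `epochs = 0` the initial weights are
#' returned and the history is empty.
#'
#' @param train_set,val_set lists of exams (each with `$images`,
#'   `$label_benign`, `$label_malignant`); the validation set must contain
#'   both malignant classes.
#' @param config a [train_config()].
#' @param model_cfg a [model_config()]; its pooling fraction is overridden
#'   by `config$t`.
#' @param verbose log one line per epoch to stderr.
#' @return a `trained_model`: `model` (a [mil_model()] with the selected
#'   weights and normalization stats), `history` (data.frame: epoch, loss,
#'   val_auroc), `val_auroc` (best).
#' @export
train_model <- function(train_set, val_set, config = train_config(),
                        model_cfg = model_config(), verbose = FALSE) {
  stopifnot(length(train_set) >= 1, length(val_set) >= 1)
  val_labels <- vapply(val_set, function(e) exam_labels_(e)[["y_m"]], numeric(1))
  if (length(unique(val_labels)) < 2)
    stop_field("val_set", "validation AUROC undefined with a single class")
  size <- model_cfg$input_size
  norm <- norm_stats_(train_set, size)
  val_pre <- lapply(val_set, function(e)
    preprocess_set_(exam_images_(e), size, norm))
  labels <- lapply(train_set, exam_labels_)

  with_seed_(config$seed, {
    weights <- init_weights(model_cfg)
    skeleton <- weights
    theta <- unlist(weights)
    mom <- numeric(length(theta)); vel <- numeric(length(theta))
    step <- 0L
    history <- data.frame(epoch = integer(), loss = numeric(),
                          val_auroc = numeric(), beta = numeric(),
                          t = numeric())
    best <- list(auroc = -Inf, theta = theta, epoch = 0L, t = config$t)
    n <- length(train_set)
    for (epoch in seq_len(config$epochs)) {
      in_warmup <- epoch <= config$warmup_epochs
      beta_ep <- if (in_warmup) 0 else config$beta
      model_cfg$t <- if (in_warmup) config$t else config$t_final
      order_idx <- sample.int(n)
      losses <- numeric(n)
      for (ii in seq_along(order_idx)) {
        e <- train_set[[order_idx[ii]]]
        imgs <- exam_images_(e)
        if (!is.null(config$augment))
          imgs <- lapply(imgs, augment, config = config$augment)
        imgs <- preprocess_set_(imgs, size, norm)
        mdl <- structure(list(config = model_cfg,
                              weights = relist_like_(theta, skeleton),
                              norm = norm), class = "mil_model")
        lg <- mil_loss_grad(imgs, labels[[order_idx[ii]]], mdl, beta_ep)
        losses[ii] <- lg$loss
        g <- unlist(lg$grads)
        if (is.finite(config$clip_norm)) {
          gn <- sqrt(sum(g^2))
          if (gn > config$clip_norm) g <- g * (config$clip_norm / gn)
        }
        step <- step + 1L
        mom <- 0.9 * mom + 0.1 * g
        vel <- 0.999 * vel + 0.001 * g^2
        mhat <- mom / (1 - 0.9^step)
        vhat <- vel / (1 - 0.999^step)
        theta <- theta - config$lr * (mhat / (sqrt(vhat) + 1e-8)) -
          config$lr * config$weight_decay * theta
      }
      w_now <- relist_like_(theta, skeleton)
      scores <- val_scores_(w_now, model_cfg, norm, val_pre)
      va <- auroc(scores, val_labels)
      history <- rbind(history, data.frame(epoch = epoch,
                                           loss = mean(losses),
                                           val_auroc = va, beta = beta_ep,
                                           t = model_cfg$t))
      if (va > best$auroc)
        best <- list(auroc = va, theta = theta, epoch = epoch, t = model_cfg$t)
      if (verbose)
        log_msg("epoch %d/%d  loss %.4f  val AUROC %.4f", epoch,
                config$epochs, mean(losses), va)
    }
    final_w <- relist_like_(best$theta, skeleton)
    class(final_w) <- "mil_weights"
    model_cfg$t <- best$t     # pooling fraction active at the best epoch
    structure(list(
      model = structure(list(config = model_cfg, weights = final_w,
                             norm = norm), class = "mil_model"),
      history = history,
      val_auroc = if (is.finite(best$auroc)) best$auroc else NA_real_,
      best_epoch = best$epoch,
      train_config = config),
      class = "trained_model")
  })
}

#' Random hyperparameter search
#'
#' Trains `n_trials` models with configurations drawn from `space` and
#' returns them with their validation AUROCs.
#'
#' @inheritParams train_model
#' @param space a [search_space()].
#' @param n_trials number of trials (defaults to `space$n_trials`).
#' @param epochs epochs per trial.
#' @param seed master seed; each trial gets a derived seed.
#' @return list of `trained_model` objects.
#' @export
run_random_search <- function(train_set, val_set, space = search_space(),
                              n_trials = space$n_trials, epochs = 10,
                              model_cfg = model_config(), seed = 1,
                              verbose = FALSE) {
  lapply(seq_len(n_trials), function(i) {
    cfg <- sample_hyperparams(space, epochs = epochs,
                              seed = derive_seed(seed, paste0("trial", i)))
    if (verbose) log_msg("trial %d/%d: lr=%.2e beta=%.2e wd=%.2e t=%.3f",
                         i, n_trials, cfg$lr, cfg$beta, cfg$weight_decay, cfg$t)
    train_model(train_set, val_set, cfg, model_cfg, verbose = verbose)
  })
}

#' Ensemble of the top-k models by validation AUROC
#'
#' Keeps the `k` models with the highest validation AUROC; the ensemble
#' prediction is the arithmetic mean of the members' breast-level
#' probabilities.
#'
#' @param trained list of `trained_model` objects (length >= k).
#' @param k ensemble size (default 3).
#' @return a `mil_ensemble`.
#' @export
select_ensemble <- function(trained, k = 3) {
  if (length(trained) < k)
    stop_field("trained", sprintf("need at least k=%d models, got %d",
                                  k, length(trained)))
  aurocs <- vapply(trained, `[[`, numeric(1), "val_auroc")
  top <- order(aurocs, decreasing = TRUE)[seq_len(k)]
  structure(list(members = lapply(trained[top], `[[`, "model"),
                 val_aurocs = aurocs[top]),
            class = "mil_ensemble")
}
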