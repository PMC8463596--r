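
# The multiple-instance model: per-image feature maps, benign/malignant
# saliency maps (1x1 conv + sigmoid), gated attention over the image set,
# top-t fraction saliency pooling, and the attention-weighted breast-level
# prediction, together with the training loss and its analytic gradient.

#' Model configuration
#'
#' The backbone is a strided CNN emitting an `h x w x C` feature map from an
#' `input_size^2` RGB image; `input_size / h` must be a power of 2 (one
#' stride-2 block per halving). The `tiny` backbone (4 blocks at 64 px,
#' `C = 32`, `L = 16`) is the desk-scale default; the `deep` backbone with
#' `input_size = 256`, `h = w = 8`, `C = 512`, `L = 128` is the full-scale
#' profile.
#'
#' @param input_size input image side H = W in pixels.
#' @param h,w spatial size of the feature map and saliency maps.
#' @param C feature channels; also the attention input width M.
#' @param L attention hidden width.
#' @param t pooling fraction in (0, 1]: the saliency map is aggregated by
#'   averaging its `ceiling(t * h * w)` largest values.
#' @param backbone `"tiny"`, `"tiny2"` or `"deep"`.
#' @param pad_mode convolution padding, `"zero"` (default) or `"replicate"`.
#' @return a `model_config`.
#' @export
model_config <- function(input_size = 64, h = 4, w = 4, C = 32, L = 16,
                         t = 0.25, backbone = "tiny",
                         pad_mode = c("zero", "replicate")) {
  pad_mode <- match.arg(pad_mode)
  if (h != w) stop_field("w", "square feature maps only (h == w)")
  ratio <- input_size / h
  n_blocks <- round(log2(ratio))
  if (!isTRUE(all.equal(2^n_blocks, ratio)) || n_blocks < 1)
    stop_field("h", "input_size / h must be a power of 2 (stride-2 blocks)")
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t > 1)
    stop_field("t", "pooling fraction must be in (0, 1]")
  if (ceiling(t * h * w) < 1) stop_field("t", "ceiling(t*h*w) must be >= 1")
  plan <- backbone_plan_(backbone, n_blocks, C)
  structure(list(input_size = as.integer(input_size), h = as.integer(h),
                 w = as.integer(w), C = as.integer(C), L = as.integer(L),
                 t = t, backbone = backbone, channels = plan$channels,
                 strides = plan$strides, pad_mode = pad_mode),
            class = "model_config")
}

#' Initialize model weights
#'
#' He-normal initialization for the conv stack; small-variance normal for the
#' saliency head and gated-attention parameters. The saliency-head bias is
#' initialized at `qlogis(0.3)` so the initial breast-level probabilities sit
#' near a realistic positive-class prevalence rather than 0.5, which removes
#' the early training phase otherwise spent learning the base rate.
#'
#' @param config a [model_config()].
#' @param seed RNG seed.
#' @return a `mil_weights` list: `conv` (per layer `W`, `b`, `stride`),
#'   `head` (`W` C x 2, `b` length 2), `attn` (`V`, `U` L x M and `w` L x 2).
#' @export
init_weights <- function(config, seed = NULL) {
  with_seed_(seed, {
    chans <- c(3L, config$channels)
    conv <- lapply(seq_len(length(chans) - 1L), function(l) {
      ci <- chans[l]; co <- chans[l + 1]
      list(W = array(stats::rnorm(3 * 3 * ci * co, 0, sqrt(2 / (9 * ci))),
                     c(3, 3, ci, co)),
           b = numeric(co))
    })
    C <- config$C; L <- config$L
    weights <- list(
      conv = conv,
      head = list(W = matrix(stats::rnorm(C * 2, 0, 0.1 / sqrt(C)), C, 2),
                  b = rep(stats::qlogis(0.3), 2)),
      attn = list(V = matrix(stats::rnorm(L * C, 0, 1 / sqrt(C)), L, C),
                  U = matrix(stats::rnorm(L * C, 0, 1 / sqrt(C)), L, C),
                  w = matrix(stats::rnorm(L * 2, 0, 1 / sqrt(L)), L, 2)))
    class(weights) <- "mil_weights"
    weights
  })
}

check_image_ <- function(image, config) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3 ||
      d[1] != config$input_size || d[2] != config$input_size) {
    stop_field("image", sprintf(
      "expected %d x %d x 3, got %s", config$input_size, config$input_size,
      paste(d, collapse = " x ")))
  }
  if (!all(is.finite(image))) stop_field("image", "non-finite pixel values")
}

#' Extract the per-image feature map
#'
#' @param image `H x W x 3` numeric array (preprocessed).
#' @param config a [model_config()].
#' @param weights a `mil_weights` object (see [init_weights()]).
#' @return `h x w x C` feature map.
#' @export
extract_features <- function(image, config, weights) {
  check_image_(image, config)
  backbone_forward_(image, weights$conv, config$strides,
                    config$pad_mode %||% "zero")$out
}

#' Benign/malignant saliency maps from a feature map
#'
#' A 1x1 convolution with two output channels followed by a sigmoid; one
#' shared head produces both pre-activations.
#'
#' @param features `h x w x C` feature map.
#' @param head_weights list with `W` (C x 2) and `b` (length 2).
#' @return a `saliency_pair`: list of `benign` and `malignant` `h x w`
#'   matrices with entries in (0, 1).
#' @export
compute_saliency <- function(features, head_weights) {
  if (!all(is.finite(features))) stop_field("features", "non-finite values")
  d <- dim(features)
  fmat <- matrix(features, d[1] * d[2], d[3])
  s <- sweep(fmat %*% head_weights$W, 2L, head_weights$b, "+")
  a <- stats::plogis(s)
  structure(list(benign = matrix(a[, 1], d[1], d[2]),
                 malignant = matrix(a[, 2], d[1], d[2])),
            class = "saliency_pair")
}

#' Global max pooling of a feature map
#'
#' @param features `h x w x C` array.
#' @return length-C vector of per-channel spatial maxima.
#' @export
global_max_pool <- function(features) {
  d <- dim(features)
  m <- matrix(features, d[1] * d[2], d[3])
  apply(m, 2, max)
}

softmax_col_ <- function(e) {
  # columnwise softmax with max subtraction
  apply(e, 2, function(col) {
    z <- exp(col - max(col))
    z / sum(z)
  })
}

#' Gated attention over an image set
#'
#' For each image's pooled feature vector `v_k`, an attention logit per class
#' is `w^T (tanh(V v_k) * sigm(U v_k))`; the benign and malignant logits are
#' each softmax-normalized independently across the K images, so each class
#' column of the result sums to 1.
#'
#' @param vectors list of K length-M vectors (or a K x M matrix).
#' @param params list with `V`, `U` (L x M) and `w` (L x 2).
#' @return K x 2 matrix of attention weights, columns `benign`, `malignant`.
#' @export
gated_attention <- function(vectors, params) {
  if (is.list(vectors)) {
    if (length(vectors) == 0) stop_field("vectors", "empty image set")
    vectors <- do.call(rbind, vectors)
  }
  if (is.null(dim(vectors))) vectors <- matrix(vectors, nrow = 1)
  K <- nrow(vectors)
  if (ncol(vectors) != ncol(params$V))
    stop_field("vectors", sprintf("feature width %d != attention width M=%d",
                                  ncol(vectors), ncol(params$V)))
  vm <- t(vectors)                         # M x K
  tv <- tanh(params$V %*% vm)              # L x K
  sv <- stats::plogis(params$U %*% vm)     # L x K
  e <- t(crossprod(params$w, tv * sv))     # K x 2
  alpha <- softmax_col_(e)
  alpha <- matrix(alpha, K, 2)
  colnames(alpha) <- c("benign", "malignant")
  alpha
}

#' Top-t fraction pooling of a saliency map
#'
#' Returns the mean of the `n = ceiling(t * h * w)` largest entries of the
#' map (at least one). `t` is a fraction, not a percentage; ties at the
#' cutoff do not affect the mean of the selected values.
#'
#' @param map numeric matrix (saliency map).
#' @param t pooling fraction in (0, 1].
#' @return scalar in the range of `map`'s entries.
#' @export
top_t_pool <- function(map, t) {
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t > 1)
    stop_field("t", "pooling fraction must be in (0, 1]")
  v <- as.vector(map)
  if (length(v) == 0) stop_field("map", "empty grid")
  n <- max(1L, as.integer(ceiling(t * length(v))))
  mean(sort(v, decreasing = TRUE)[seq_len(n)])
}

#' Image-level predictions from a saliency pair
#'
#' Applies [top_t_pool()] to the benign and malignant maps independently.
#'
#' @param saliency a `saliency_pair`.
#' @param t pooling fraction.
#' @return named vector `c(benign = , malignant = )` in \[0, 1\].
#' @export
image_level_pred <- function(saliency, t) {
  c(benign = top_t_pool(saliency$benign, t),
    malignant = top_t_pool(saliency$malignant, t))
}

#' Breast-level prediction from image-level predictions and attention
#'
#' The breast probability for each class is the attention-weighted average
#' of the image-level probabilities, a convex combination.
#'
#' @param image_preds K x 2 matrix (columns benign, malignant) of
#'   image-level predictions.
#' @param attention K x 2 attention matrix whose columns each sum to 1
#'   (tolerance 1e-6).
#' @return a `breast_prediction`: list with `y_b`, `y_m`.
#' @export
breast_pred <- function(image_preds, attention) {
  image_preds <- matrix(image_preds, ncol = 2)
  attention <- matrix(attention, ncol = 2)
  if (nrow(image_preds) != nrow(attention))
    stop_field("attention", "length mismatch with image_preds")
  if (nrow(image_preds) < 1) stop_field("image_preds", "empty image set")
  sums <- colSums(attention)
  if (any(abs(sums - 1) > 1e-6))
    stop_field("attention", sprintf("columns must sum to 1 (got %s)",
                                    paste(signif(sums, 6), collapse = ", ")))
  y <- colSums(attention * image_preds)
  structure(list(y_b = y[1], y_m = y[2]), class = "breast_prediction")
}

#' @export
print.breast_prediction <- function(x, ...) {
  cat(sprintf("breast prediction: P(benign lesion)=%.4f  P(malignant)=%.4f\n",
              x$y_b, x$y_m))
  invisible(x)
}

#' Construct a model object from config and weights
#'
#' @param config a [model_config()].
#' @param weights a `mil_weights`; freshly initialized if `NULL`.
#' @param norm list with `mean`, `sd` used to standardize raw images at
#'   prediction time (set by the trainer).
#' @param seed seed for weight initialization when `weights` is `NULL`.
#' @return a `mil_model`.
#' @export
mil_model <- function(config = model_config(), weights = NULL, norm = NULL,
                      seed = NULL) {
  structure(list(config = config,
                 weights = weights %||% init_weights(config, seed = seed),
                 norm = norm %||% list(mean = 0.5, sd = 0.25)),
            class = "mil_model")
}

# Forward pass over an image set keeping every intermediate needed by the
# backward pass.
forward_cache_ <- function(image_set, weights, config) {
  K <- length(image_set)
  if (K < 1) stop_field("image_set", "empty image set")
  hw <- config$h * config$w
  n_top <- max(1L, as.integer(ceiling(config$t * hw)))
  per <- vector("list", K)
  vmat <- matrix(0, K, config$C)
  for (k in seq_len(K)) {
    check_image_(image_set[[k]], config)
    bb <- backbone_forward_(image_set[[k]], weights$conv, config$strides,
                            config$pad_mode %||% "zero")
    f <- bb$out
    fmat <- matrix(f, hw, config$C)
    smat <- sweep(fmat %*% weights$head$W, 2L, weights$head$b, "+")
    amat <- stats::plogis(smat)                      # hw x 2
    argmax <- max.col(t(fmat), ties.method = "first")
    v <- fmat[cbind(argmax, seq_len(config$C))]
    vmat[k, ] <- v
    top_idx <- matrix(vapply(1:2, function(cc)
      order(amat[, cc], decreasing = TRUE)[seq_len(n_top)],
      integer(n_top)), n_top, 2)
    y_img <- c(mean(amat[top_idx[, 1], 1]), mean(amat[top_idx[, 2], 2]))
    per[[k]] <- list(bb = bb, fmat = fmat, amat = amat, argmax = argmax,
                     top_idx = top_idx, y_img = y_img)
  }
  vm <- t(vmat)                                      # C x K
  tv <- tanh(weights$attn$V %*% vm)
  sv <- stats::plogis(weights$attn$U %*% vm)
  gates <- tv * sv                                   # L x K
  e <- t(crossprod(weights$attn$w, gates))           # K x 2
  alpha <- matrix(softmax_col_(e), K, 2)
  preds <- do.call(rbind, lapply(per, `[[`, "y_img"))
  y <- colSums(alpha * preds)
  list(per = per, vmat = vmat, tv = tv, sv = sv, alpha = alpha,
       preds = preds, y = y, n_top = n_top, K = K)
}

#' Full forward pass over one breast's image set
#'
#' Composes feature extraction, saliency, gated attention, top-t pooling and
#' the attention-weighted breast prediction. The result is invariant (to
#' floating tolerance) to permuting or duplicating the images in the set.
#'
#' @param image_set list of preprocessed `H x W x 3` arrays.
#' @param model a [mil_model()].
#' @return a `breast_prediction` with `y_b`, `y_m`, and attached `attention`
#'   (K x 2), `image_preds` (K x 2) and `saliency` (list of `saliency_pair`).
#' @export
mil_forward <- function(image_set, model) {
  fc <- forward_cache_(image_set, model$weights, model$config)
  sal <- lapply(fc$per, function(p) {
    structure(list(benign = matrix(p$amat[, 1], model$config$h, model$config$w),
                   malignant = matrix(p$amat[, 2], model$config$h, model$config$w)),
              class = "saliency_pair")
  })
  structure(list(y_b = fc$y[1], y_m = fc$y[2], attention = fc$alpha,
                 image_preds = fc$preds, saliency = sal),
            class = "breast_prediction")
}

#' Saliency regularization term
#'
#' Sum of absolute saliency values over both maps of a pair; penalizes the
#' model for highlighting irrelevant regions. Saliency values are
#' nonnegative, so this equals the plain sum.
#'
#' @param saliency a `saliency_pair`.
#' @return scalar.
#' @export
saliency_reg <- function(saliency) {
  sum(abs(saliency$benign)) + sum(abs(saliency$malignant))
}

bce_ <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' Training loss for one breast
#'
#' Binary cross-entropy on the benign and malignant breast-level predictions
#' plus `beta` times the saliency regularizer summed over images and both
#' classes. Probabilities are clipped to `[1e-7, 1 - 1e-7]` so the loss is
#' always finite.
#'
#' @param y named vector `c(y_b = , y_m = )` of binary labels.
#' @param pred a `breast_prediction`.
#' @param saliencies list of K `saliency_pair` objects.
#' @param beta nonnegative saliency regularization weight.
#' @return scalar loss.
#' @export
total_loss <- function(y, pred, saliencies, beta) {
  if (!all(y %in% c(0, 1))) stop_field("y", "labels must be binary")
  if (beta < 0) stop_field("beta", "must be >= 0")
  bce <- bce_(y[["y_b"]], pred$y_b) + bce_(y[["y_m"]], pred$y_m)
  reg <- if (length(saliencies)) sum(vapply(saliencies, saliency_reg, numeric(1))) else 0
  bce + beta * reg
}

#' Loss and analytic gradient for one breast
#'
#' Runs the forward pass and backpropagates the training loss through the
#' attention, pooling, saliency head and conv stack. Used by the trainer;
#' exposed so the gradient can be verified against finite differences.
#'
#' @param image_set list of preprocessed `H x W x 3` arrays.
#' @param y named binary labels `c(y_b = , y_m = )`.
#' @param model a [mil_model()].
#' @param beta saliency regularization weight.
#' @return list with `loss` and `grads` (same shape as `model$weights`).
#' @export
mil_loss_grad <- function(image_set, y, model, beta) {
  if (!all(y %in% c(0, 1))) stop_field("y", "labels must be binary")
  weights <- model$weights; config <- model$config
  fc <- forward_cache_(image_set, weights, config)
  eps <- 1e-7
  yv <- c(y[["y_b"]], y[["y_m"]])
  p <- pmin(pmax(fc$y, eps), 1 - eps)
  loss <- sum(-(yv * log(p) + (1 - yv) * log(1 - p))) +
    beta * sum(vapply(fc$per, function(pk) sum(pk$amat), numeric(1)))

  dy <- (p - yv) / (p * (1 - p))                     # dBCE/dy_hat, length 2
  dpreds <- sweep(fc$alpha, 2L, dy, "*")             # K x 2
  dalpha <- sweep(fc$preds, 2L, dy, "*")             # K x 2
  # softmax backward per class column
  de <- fc$alpha * (dalpha - matrix(rep(colSums(fc$alpha * dalpha), each = fc$K),
                                    fc$K, 2))
  gates <- fc$tv * fc$sv                             # L x K
  dw_attn <- gates %*% de                            # L x 2
  dgates <- weights$attn$w %*% t(de)                 # L x K
  dtv <- dgates * fc$sv
  dsv <- dgates * fc$tv
  dpreV <- dtv * (1 - fc$tv^2)
  dpreU <- dsv * fc$sv * (1 - fc$sv)
  vm <- t(fc$vmat)                                   # C x K
  dV <- dpreV %*% t(vm)
  dU <- dpreU %*% t(vm)
  dvmat <- t(crossprod(weights$attn$V, dpreV) +
             crossprod(weights$attn$U, dpreU))       # K x C

  conv_g <- NULL
  dheadW <- matrix(0, config$C, 2)
  dheadb <- numeric(2)
  hw <- config$h * config$w
  for (k in seq_len(fc$K)) {
    pk <- fc$per[[k]]
    damat <- matrix(beta, hw, 2)                     # reg: d|A|/dA = 1, A > 0
    for (cc in 1:2) {
      damat[pk$top_idx[, cc], cc] <- damat[pk$top_idx[, cc], cc] +
        dpreds[k, cc] / fc$n_top
    }
    dsmat <- damat * pk$amat * (1 - pk$amat)
    dheadW <- dheadW + crossprod(pk$fmat, dsmat)
    dheadb <- dheadb + colSums(dsmat)
    dfmat <- dsmat %*% t(weights$head$W)             # hw x C
    dfmat[cbind(pk$argmax, seq_len(config$C))] <-
      dfmat[cbind(pk$argmax, seq_len(config$C))] + dvmat[k, ]
    df <- array(dfmat, c(config$h, config$w, config$C))
    bk <- backbone_backward_(df, pk$bb$caches)
    if (is.null(conv_g)) {
      conv_g <- bk$grads
    } else {
      for (l in seq_along(conv_g)) {
        conv_g[[l]]$W <- conv_g[[l]]$W + bk$grads[[l]]$W
        conv_g[[l]]$b <- conv_g[[l]]$b + bk$grads[[l]]$b
      }
    }
  }
  grads <- list(conv = conv_g,
                head = list(W = dheadW, b = dheadb),
                attn = list(V = dV, U = dU, w = dw_attn))
  list(loss = loss, grads = grads, pred = fc$y)
}
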