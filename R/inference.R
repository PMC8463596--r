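
# Inference: breast-level prediction from trained models and ensembles,
# test-time augmentation, saliency-map export and weakly supervised
# localization scoring.

#' Test-time augmentation configuration
#'
#' @param n_reps number of augmented repetitions to average (default 20).
#' @param hflip_prob,vflip_prob flip probabilities (default 0.5 each).
#' @param factor_range brightness/contrast factor interval, a subset of
#'   (0, Inf) (default \[0.9, 1.1\]).
#' @return a `tta_config`.
#' @export
tta_config <- function(n_reps = 20, hflip_prob = 0.5, vflip_prob = 0.5,
                       factor_range = c(0.9, 1.1)) {
  if (n_reps < 1) stop_field("n_reps", "must be >= 1")
  if (length(factor_range) != 2 || any(factor_range <= 0) ||
      factor_range[1] > factor_range[2])
    stop_field("factor_range", "must be an increasing positive interval")
  structure(list(n_reps = as.integer(n_reps), hflip_prob = hflip_prob,
                 vflip_prob = vflip_prob, factor_range = factor_range),
            class = "tta_config")
}

resolve_model_ <- function(object) {
  if (inherits(object, "trained_model")) return(list(object$model))
  if (inherits(object, "mil_model")) return(list(object))
  if (inherits(object, "mil_ensemble")) return(object$members)
  stop_field("object", "expected a mil_model, trained_model or mil_ensemble")
}

#' Breast-level prediction for an image set
#'
#' Preprocesses the raw images with the model's stored normalization and runs
#' the full forward pass; for an ensemble, the members' probabilities are
#' averaged. Deterministic.
#'
#' @param object a `mil_model`, `trained_model` or `mil_ensemble`.
#' @param image_set list of raw grayscale matrices (or `H x W x 3` arrays)
#'   with values in \[0, 1\].
#' @return a `breast_prediction` with `y_b` and `y_m`; for a single model
#'   the attention, image-level predictions and saliency maps are attached.
#' @export
predict_breast <- function(object, image_set) {
  if (length(image_set) < 1) stop_field("image_set", "empty image set")
  members <- resolve_model_(object)
  preds <- lapply(members, function(m) {
    pre <- preprocess_set_(image_set, m$config$input_size, m$norm)
    mil_forward(pre, m)
  })
  if (length(preds) == 1) return(preds[[1]])
  structure(list(y_b = mean(vapply(preds, `[[`, numeric(1), "y_b")),
                 y_m = mean(vapply(preds, `[[`, numeric(1), "y_m")),
                 member_preds = preds),
            class = "breast_prediction")
}

tta_augment_one_ <- function(image, config) {
  if (stats::runif(1) < config$hflip_prob) image <- image[, ncol(image):1]
  if (stats::runif(1) < config$vflip_prob) image <- image[nrow(image):1, ]
  fc <- stats::runif(1, config$factor_range[1], config$factor_range[2])
  fb <- stats::runif(1, config$factor_range[1], config$factor_range[2])
  m <- mean(image)
  pmin(pmax(((image - m) * fc + m) * fb, 0), 1)
}

#' Prediction with test-time augmentation
#'
#' For each repetition every image is randomly flipped (horizontal and
#' vertical) and its brightness/contrast jittered (contrast scales about the
#' image mean, brightness scales the result); the breast-level prediction is
#' computed on the augmented set, and the final prediction is the mean over
#' repetitions. Seeded-deterministic; with flip probabilities 0 and factor
#' range \[1, 1\] it equals [predict_breast()] exactly.
#'
#' @param object model or ensemble as in [predict_breast()].
#' @param image_set list of raw grayscale matrices.
#' @param config a [tta_config()].
#' @param seed RNG seed.
#' @return a `breast_prediction` with `y_b`, `y_m`.
#' @export
tta_predict <- function(object, image_set, config = tta_config(), seed = NULL) {
  stopifnot(inherits(config, "tta_config"))
  with_seed_(seed, {
    reps <- lapply(seq_len(config$n_reps), function(r) {
      aug <- lapply(image_set, tta_augment_one_, config = config)
      p <- predict_breast(object, aug)
      c(p$y_b, p$y_m)
    })
    avg <- Reduce(`+`, reps) / length(reps)
    structure(list(y_b = avg[1], y_m = avg[2]), class = "breast_prediction")
  })
}

# Upsample a saliency grid to image resolution respecting the conv-grid
# anchoring: with 3x3 kernels, padding 1 and stride-2 stacks, feature cell i
# is centered on input pixel (i-1)*stride + 1, not on the center of the
# i-th tile. Interpolating at those true cell centers keeps the upsampled
# map spatially aligned with the image (a uniform tile-based resize would
# shift everything by about half a cell).
upsample_map_ <- function(map, size, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(map); w <- ncol(map)
  u_of <- function(n_cells) (seq_len(size) - 1) / (size / n_cells) + 1
  interp_idx <- function(u, n_cells) {
    if (method == "nearest") {
      i0 <- pmin(pmax(round(u), 1), n_cells)
      list(lo = i0, hi = i0, wt = rep(0, length(u)))
    } else {
      lo <- pmin(pmax(floor(u), 1), n_cells)
      hi <- pmin(lo + 1, n_cells)
      list(lo = lo, hi = hi, wt = pmin(pmax(u - lo, 0), 1))
    }
  }
  ri <- interp_idx(u_of(h), h)
  ci <- interp_idx(u_of(w), w)
  top <- map[ri$lo, ci$lo, drop = FALSE] * (1 - ci$wt[col(matrix(0, size, size))]) +
         map[ri$lo, ci$hi, drop = FALSE] * ci$wt[col(matrix(0, size, size))]
  bot <- map[ri$hi, ci$lo, drop = FALSE] * (1 - ci$wt[col(matrix(0, size, size))]) +
         map[ri$hi, ci$hi, drop = FALSE] * ci$wt[col(matrix(0, size, size))]
  wr <- ri$wt[row(matrix(0, size, size))]
  top * (1 - wr) + bot * wr
}

#' Export saliency heatmaps and attention scores for an image set
#'
#' Writes, per image, the benign and malignant saliency maps upsampled to the
#' model's input resolution as grayscale PNGs, plus one JSON sidecar with the
#' attention scores and image-level predictions.
#'
#' @param object a `mil_model` or `trained_model`.
#' @param image_set list of raw grayscale matrices.
#' @param out_dir output directory (created if missing).
#' @param upsample `"bilinear"` (default) or `"nearest"`.
#' @return character vector of file paths (2K heatmaps + 1 JSON).
#' @export
export_saliency <- function(object, image_set, out_dir,
                            upsample = c("bilinear", "nearest")) {
  upsample <- match.arg(upsample)
  model <- resolve_model_(object)[[1]]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_field("out_dir", "cannot create directory")
  pred <- predict_breast(model, image_set)
  size <- model$config$input_size
  paths <- character()
  for (k in seq_along(image_set)) {
    for (cls in c("benign", "malignant")) {
      p <- file.path(out_dir, sprintf("%03d_%s.png", k, cls))
      png::writePNG(upsample_map_(pred$saliency[[k]][[cls]], size, upsample), p)
      paths <- c(paths, p)
    }
  }
  sidecar <- file.path(out_dir, "attention.json")
  jsonlite::write_json(list(
    y_b = pred$y_b, y_m = pred$y_m,
    attention = list(benign = pred$attention[, 1],
                     malignant = pred$attention[, 2]),
    image_preds = list(benign = pred$image_preds[, 1],
                       malignant = pred$image_preds[, 2]),
    upsample = upsample), sidecar, auto_unbox = TRUE, digits = NA)
  c(paths, sidecar)
}

#' Pointing-game localization score on phantom exams
#'
#' For every lesion-bearing image of the malignant exams whose breast-level
#' malignant probability reaches `min_score`, checks whether the argmax of
#' the bilinearly upsampled malignant saliency map falls inside the planted
#' lesion's ground-truth mask. Under weak supervision this measures whether
#' the saliency maps localize lesions no pixel label ever identified; chance
#' level is about the lesion's area fraction.
#'
#' @param object model or ensemble.
#' @param exams list of `phantom_exam` objects (ground-truth masks required).
#' @param min_score breast-level score gate for counting an exam as a true
#'   positive. `NULL` (default) derives it as the threshold at which the
#'   model's specificity over `exams` reaches 0.9 -- raw probabilities are
#'   not calibrated, so an absolute gate would be arbitrary.
#' @return list: `hit_rate`, `n_images`, `n_hits`, `n_exams_scored`,
#'   `min_score`.
#' @export
saliency_pointing_game <- function(object, exams, min_score = NULL) {
  members <- resolve_model_(object)
  if (is.null(min_score)) {
    scores <- vapply(exams, function(e)
      predict_breast(object, e$images)$y_m, numeric(1))
    labels <- vapply(exams, function(e)
      as.numeric(e$label_malignant), numeric(1))
    min_score <- operating_point_at(scores, labels, 0.9,
                                    "specificity")$threshold
  }
  hits <- 0L; total <- 0L; scored <- 0L
  for (exam in exams) {
    if (!inherits(exam, "phantom_exam") || exam$label_malignant != 1L) next
    preds <- lapply(members, function(m) predict_breast(m, exam$images))
    y_m <- mean(vapply(preds, `[[`, numeric(1), "y_m"))
    if (y_m < min_score) next
    scored <- scored + 1L
    for (k in seq_along(exam$images)) {
      mask <- exam$truth_masks[[k]]$malignant
      if (sum(mask) == 0) next
      size <- nrow(exam$images[[k]])
      # ensemble saliency: mean of the members' maps
      A <- Reduce(`+`, lapply(preds, function(p) p$saliency[[k]]$malignant)) /
        length(preds)
      up <- upsample_map_(A, size, "bilinear")
      pos <- arrayInd(which.max(up), dim(up))
      total <- total + 1L
      if (mask[pos[1], pos[2]] > 0) hits <- hits + 1L
    }
  }
  list(hit_rate = if (total > 0) hits / total else NA_real_,
       n_images = total, n_hits = hits, n_exams_scored = scored,
       min_score = min_score)
}
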