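
# Synthetic breast-ultrasound phantoms: speckle-textured tissue background
# with planted hypoechoic lesions. Benign lesions are smooth-margin ovals;
# malignant lesions are spiculated irregular shapes. Only a subset of a
# positive exam's images shows the lesion, so breast-level labels are weak
# supervision for the per-image localization task.

#' Phantom generator specification
#'
#' Defaults are the study conditions used throughout the package's tests:
#' 64 px images, 4-12 images per exam, lesions visible in 40% of a positive
#' exam's images (at least 2), multiplicative Rayleigh-like speckle, lesion
#' interiors at 45% of background brightness (hypoechoic), lesion radii
#' 6-11 px (about 3-10% of image area at 64 px).
#'
#' @param image_size square image side in pixels (64 for tests, up to 256).
#' @param k_range integer interval `c(min, max)` of images per exam.
#' @param lesion_prob_visible fraction of a positive exam's images containing
#'   the lesion; at least 2 images always show it.
#' @param speckle_scale multiplicative speckle amplitude in \[0, 1\].
#' @param lesion_contrast lesion interior intensity relative to background;
#'   must be < 1 so lesions are hypoechoic.
#' @param lesion_radius radius range in pixels at `image_size = 64`
#'   (scaled proportionally for other sizes).
#' @param benign_morphology list: `axis_ratio` range, `margin_smoothness`
#'   (soft-edge width, px).
#' @param malignant_morphology list: `spiculations` count range,
#'   `margin_blur` (px), `irregularity` amplitude range.
#' @param class_mix named probabilities over
#'   `c(negative, benign, malignant)`; must sum to 1.
#' @param both_labels_prob probability that a malignant exam also carries a
#'   benign lesion (exercises the multi-label case).
#' @param seed default RNG seed used when an operation is not given one.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64,
                         k_range = c(4, 12),
                         lesion_prob_visible = 0.4,
                         speckle_scale = 0.35,
                         lesion_contrast = 0.45,
                         lesion_radius = c(6, 11),
                         benign_morphology = list(axis_ratio = c(0.55, 0.9),
                                                  margin_smoothness = 1.6),
                         malignant_morphology = list(spiculations = c(5, 12),
                                                     margin_blur = 0.6,
                                                     irregularity = c(0.25, 0.45)),
                         class_mix = c(negative = 0.4, benign = 0.3,
                                       malignant = 0.3),
                         both_labels_prob = 0.08,
                         seed = 1L) {
  if (!is.numeric(image_size) || image_size < 16)
    stop_field("image_size", "must be >= 16 pixels")
  if (length(k_range) != 2 || k_range[1] < 1 || k_range[2] < k_range[1])
    stop_field("k_range", "must be an increasing integer interval with min >= 1")
  if (lesion_prob_visible <= 0 || lesion_prob_visible > 1)
    stop_field("lesion_prob_visible", "must be in (0, 1]")
  if (speckle_scale < 0 || speckle_scale > 1)
    stop_field("speckle_scale", "must be in [0, 1]")
  if (lesion_contrast >= 1 || lesion_contrast <= 0)
    stop_field("lesion_contrast",
               "must be in (0, 1): lesion interiors are hypoechoic (darker)")
  if (length(class_mix) != 3 ||
      !setequal(names(class_mix), c("negative", "benign", "malignant")))
    stop_field("class_mix", "needs probabilities named negative, benign, malignant")
  if (abs(sum(class_mix) - 1) > 1e-8)
    stop_field("class_mix", "must sum to 1")
  if (any(class_mix < 0)) stop_field("class_mix", "probabilities must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 k_range = as.integer(k_range),
                 lesion_prob_visible = lesion_prob_visible,
                 speckle_scale = speckle_scale,
                 lesion_contrast = lesion_contrast,
                 lesion_radius = lesion_radius,
                 benign_morphology = benign_morphology,
                 malignant_morphology = malignant_morphology,
                 class_mix = class_mix[c("negative", "benign", "malignant")],
                 both_labels_prob = both_labels_prob,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth random field: coarse uniform grid bilinearly upsampled.
smooth_field_ <- function(size, coarse = 8, amplitude = 1) {
  g <- matrix(stats::runif(coarse * coarse, -1, 1), coarse, coarse)
  amplitude * as.matrix(EBImage::resize(g, w = size, h = size))
}

# Rayleigh-magnitude speckle, spatially correlated, normalized to mean 1.
speckle_field_ <- function(size) {
  half <- max(8L, size %/% 2L)
  u <- matrix(stats::runif(half * half), half, half)
  r <- sqrt(-2 * log(pmax(u, 1e-12))) / sqrt(pi / 2)
  as.matrix(EBImage::resize(r, w = size, h = size))
}

# Soft [0,1] membership mask of a lesion; boundary radius varies with angle.
lesion_mask_ <- function(size, lesion) {
  j <- matrix(rep(seq_len(size), each = size), size)   # column = x
  i <- matrix(rep(seq_len(size), times = size), size)  # row = y
  u <- j - lesion$cx
  v <- i - lesion$cy
  ca <- cos(lesion$angle); sa <- sin(lesion$angle)
  ur <- ca * u + sa * v
  vr <- (-sa * u + ca * v) / lesion$axis_ratio
  rr <- sqrt(ur^2 + vr^2)
  th <- atan2(vr, ur)
  shape <- if (lesion$type == "malignant") {
    1 + lesion$irregularity * (0.55 * cos(lesion$spiculations * th + lesion$phase1) +
                               0.45 * cos((lesion$spiculations + 3) * th + lesion$phase2))
  } else {
    1 + 0.04 * cos(2 * th + lesion$phase1)
  }
  bound <- lesion$r0 * pmax(shape, 0.25)
  stats::plogis((bound - rr) / lesion$edge)
}

draw_lesion_ <- function(spec, type) {
  size <- spec$image_size
  scale <- size / 64
  r <- stats::runif(1, spec$lesion_radius[1], spec$lesion_radius[2]) * scale
  margin <- r * 1.8 + 2
  les <- list(
    type = type,
    cx = stats::runif(1, margin, size - margin),
    cy = stats::runif(1, margin, size - margin),
    r0 = r,
    angle = stats::runif(1, 0, pi))
  if (type == "malignant") {
    mm <- spec$malignant_morphology
    les$axis_ratio <- stats::runif(1, 0.7, 1)
    les$spiculations <- sample(mm$spiculations[1]:mm$spiculations[2], 1)
    les$irregularity <- stats::runif(1, mm$irregularity[1], mm$irregularity[2])
    les$edge <- mm$margin_blur * scale
    les$phase1 <- stats::runif(1, 0, 2 * pi)
    les$phase2 <- stats::runif(1, 0, 2 * pi)
  } else {
    bm <- spec$benign_morphology
    les$axis_ratio <- stats::runif(1, bm$axis_ratio[1], bm$axis_ratio[2])
    les$edge <- bm$margin_smoothness * scale
    les$phase1 <- stats::runif(1, 0, 2 * pi)
  }
  les
}

# Re-draw of the same lesion for another image of the exam ("another view"):
# small jitter in position and apparent size, same morphology.
jitter_lesion_ <- function(lesion, size) {
  lesion$cx <- min(max(lesion$cx + stats::rnorm(1, 0, 1.5), lesion$r0 + 2),
                   size - lesion$r0 - 2)
  lesion$cy <- min(max(lesion$cy + stats::rnorm(1, 0, 1.5), lesion$r0 + 2),
                   size - lesion$r0 - 2)
  lesion$r0 <- lesion$r0 * stats::runif(1, 0.9, 1.1)
  lesion
}

render_image_ <- function(spec, lesions) {
  size <- spec$image_size
  base <- 0.55 + smooth_field_(size, amplitude = 0.1)
  s <- spec$speckle_scale
  img <- base * ((1 - s) + s * speckle_field_(size))
  masks <- list(benign = matrix(0, size, size),
                malignant = matrix(0, size, size))
  for (les in lesions) {
    m <- lesion_mask_(size, les)
    img <- img * (1 - m * (1 - spec$lesion_contrast))
    masks[[les$type]] <- pmax(masks[[les$type]], m)
  }
  # quantize to the 8-bit grid: real US images are 8-bit, and PNG bundle
  # round trips stay lossless
  img <- round(pmin(pmax(img, 0.01), 1) * 255) / 255
  list(image = img,
       benign_mask = (masks$benign > 0.5) * 1L,
       malignant_mask = (masks$malignant > 0.5) * 1L)
}

mask_bbox_ <- function(mask) {
  w <- which(mask > 0, arr.ind = TRUE)
  if (nrow(w) == 0) return(c(NA_integer_, NA_integer_, NA_integer_, NA_integer_))
  c(min(w[, 2]), min(w[, 1]), max(w[, 2]), max(w[, 1]))  # x0, y0, x1, y1
}

#' Generate one synthetic breast-exam image set
#'
#' Draws K images (K uniform over `k_range`); for a positive class the lesion
#' is planted in `max(2, round(lesion_prob_visible * K))` of them with small
#' view-to-view jitter, and the remaining images are lesion-free speckle.
#' Ground-truth binary masks are carried for evaluation only -- the training
#' interface ([training_view()]) never exposes them.
#'
#' @param spec a [phantom_spec()].
#' @param class_label `"negative"`, `"benign"` or `"malignant"`.
#' @param seed RNG seed; identical (spec, class_label, seed) yields
#'   byte-identical exams.
#' @param exam_id,breast_id identifiers.
#' @return a `phantom_exam`: `images` (list of \[0,1\] matrices),
#'   `label_benign`, `label_malignant`, `truth_masks` (per image, binary
#'   `benign`/`malignant` masks), identifiers.
#' @export
gen_exam <- function(spec, class_label = c("negative", "benign", "malignant"),
                     seed = NULL, exam_id = "exam1", breast_id = "breast1") {
  stopifnot(inherits(spec, "phantom_spec"))
  class_label <- match.arg(class_label)
  with_seed_(seed %||% spec$seed, {
    k <- sample(spec$k_range[1]:spec$k_range[2], 1)
    lesion_types <- switch(class_label,
                           negative = character(),
                           benign = "benign",
                           malignant = "malignant")
    if (class_label == "malignant" &&
        stats::runif(1) < spec$both_labels_prob) {
      lesion_types <- c(lesion_types, "benign")
    }
    per_image <- replicate(k, list(), simplify = FALSE)
    for (type in lesion_types) {
      les <- draw_lesion_(spec, type)
      n_vis <- min(k, max(2L, round(spec$lesion_prob_visible * k)))
      vis <- sample.int(k, n_vis)
      for (idx in vis) {
        per_image[[idx]] <- c(per_image[[idx]],
                              list(jitter_lesion_(les, spec$image_size)))
      }
    }
    rendered <- lapply(per_image, function(lesions) render_image_(spec, lesions))
    structure(list(
      exam_id = exam_id, breast_id = breast_id,
      class_label = class_label,
      images = lapply(rendered, `[[`, "image"),
      label_benign = as.integer("benign" %in% lesion_types),
      label_malignant = as.integer("malignant" %in% lesion_types),
      truth_masks = lapply(rendered, function(r)
        list(benign = r$benign_mask, malignant = r$malignant_mask))),
      class = "phantom_exam")
  })
}

#' @export
print.phantom_exam <- function(x, ...) {
  cat(sprintf("phantom exam %s/%s: %d images %dpx, y_b=%d y_m=%d\n",
              x$exam_id, x$breast_id, length(x$images), nrow(x$images[[1]]),
              x$label_benign, x$label_malignant))
  invisible(x)
}

#' Training-facing view of a phantom exam
#'
#' Returns only what weak supervision permits: the image set and the two
#' breast-level labels. Ground-truth lesion masks are deliberately absent.
#'
#' @param exam a `phantom_exam`.
#' @return list with `images`, `label_benign`, `label_malignant`,
#'   `exam_id`, `breast_id`.
#' @export
training_view <- function(exam) {
  stopifnot(inherits(exam, "phantom_exam"))
  exam[c("exam_id", "breast_id", "images", "label_benign", "label_malignant")]
}

#' Generate a seeded cohort of phantom exams
#'
#' Class assignments are drawn from `spec$class_mix`; each exam gets an
#' independent derived seed so cohorts are reproducible end to end.
#'
#' @param spec a [phantom_spec()].
#' @param n_exams number of breasts to generate (>= 1).
#' @param seed RNG seed.
#' @return list with `exams` (list of `phantom_exam`), `truth` (data.frame,
#'   one row per exam: ids, class, labels, image count) and `boxes`
#'   (data.frame of per-image lesion bounding boxes: `exam_id`,
#'   `image_index`, `type`, `x0`, `y0`, `x1`, `y1`).
#' @export
gen_cohort <- function(spec, n_exams, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(n_exams) || n_exams < 1)
    stop_field("n_exams", "must be >= 1")
  n_exams <- as.integer(n_exams)
  seed <- seed %||% spec$seed
  classes <- with_seed_(seed, {
    sample(c("negative", "benign", "malignant"), n_exams, replace = TRUE,
           prob = spec$class_mix)
  })
  exams <- lapply(seq_len(n_exams), function(i) {
    gen_exam(spec, classes[i], seed = derive_seed(seed, paste0("exam", i)),
             exam_id = sprintf("E%05d", i), breast_id = sprintf("B%05d", i))
  })
  truth <- do.call(rbind, lapply(exams, function(e) {
    data.frame(exam_id = e$exam_id, breast_id = e$breast_id,
               class = e$class_label, y_b = e$label_benign,
               y_m = e$label_malignant, k = length(e$images),
               stringsAsFactors = FALSE)
  }))
  boxes <- do.call(rbind, lapply(exams, function(e) {
    rows <- lapply(seq_along(e$truth_masks), function(i) {
      out <- NULL
      for (type in c("benign", "malignant")) {
        bb <- mask_bbox_(e$truth_masks[[i]][[type]])
        if (!is.na(bb[1])) {
          out <- rbind(out, data.frame(
            exam_id = e$exam_id, image_index = i, type = type,
            x0 = bb[1], y0 = bb[2], x1 = bb[3], y1 = bb[4],
            stringsAsFactors = FALSE))
        }
      }
      out
    })
    do.call(rbind, rows)
  }))
  if (is.null(boxes)) {
    boxes <- data.frame(exam_id = character(), image_index = integer(),
                        type = character(), x0 = integer(), y0 = integer(),
                        x1 = integer(), y1 = integer(), stringsAsFactors = FALSE)
  }
  list(exams = exams, truth = truth, boxes = boxes)
}
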