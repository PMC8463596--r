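
# Exam-bundle and checkpoint IO. A bundle is one directory per breast:
# images/NNN.png + manifest.json, with ground-truth masks in a sibling
# truth/ directory that the training loader never touches.

#' Write a phantom exam as an image bundle
#'
#' Layout: `dir/images/NNN.png`, `dir/manifest.json` (exam/breast ids,
#' laterality, image count, labels) and, unless `write_truth = FALSE`,
#' `dir/truth/NNN_benign.png` / `NNN_malignant.png` evaluation-only masks.
#'
#' @param exam a `phantom_exam`.
#' @param dir bundle directory (created).
#' @param write_truth write ground-truth masks under `truth/`.
#' @param laterality recorded in the manifest.
#' @return invisibly, `dir`.
#' @export
write_exam_bundle <- function(exam, dir, write_truth = TRUE,
                              laterality = "left") {
  stopifnot(inherits(exam, "phantom_exam"))
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (k in seq_along(exam$images)) {
    png::writePNG(exam$images[[k]], file.path(img_dir, sprintf("%03d.png", k)))
  }
  jsonlite::write_json(list(
    exam_id = exam$exam_id, breast_id = exam$breast_id,
    laterality = laterality, k = length(exam$images),
    label_benign = exam$label_benign, label_malignant = exam$label_malignant),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  if (write_truth) {
    truth_dir <- file.path(dir, "truth")
    dir.create(truth_dir, showWarnings = FALSE)
    for (k in seq_along(exam$truth_masks)) {
      for (cls in c("benign", "malignant")) {
        png::writePNG(exam$truth_masks[[k]][[cls]] * 1.0,
                      file.path(truth_dir, sprintf("%03d_%s.png", k, cls)))
      }
    }
  }
  invisible(dir)
}

#' Read an exam bundle (training view)
#'
#' Loads the images in manifest order plus the labels. The `truth/`
#' directory is outside this loader's search path by contract: ground-truth
#' masks are only reachable through [read_truth_masks()].
#'
#' @param dir bundle directory containing `manifest.json` and `images/`.
#' @return list with `exam_id`, `breast_id`, `laterality`, `images`
#'   (list of matrices), `label_benign`, `label_malignant`.
#' @export
read_exam_bundle <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop_field("dir", sprintf("missing manifest.json in %s", dir))
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  img_dir <- file.path(dir, "images")
  files <- file.path(img_dir, sprintf("%03d.png", seq_len(man$k)))
  missing <- !file.exists(files)
  if (any(missing))
    stop_field("dir", sprintf("manifest lists %d images but %d missing (e.g. %s)",
                              man$k, sum(missing), basename(files[missing][1])))
  images <- lapply(files, function(f) {
    im <- png::readPNG(f)
    if (length(dim(im)) == 3) im <- im[, , 1]
    im
  })
  list(exam_id = man$exam_id, breast_id = man$breast_id,
       laterality = man$laterality, images = images,
       label_benign = man$label_benign %||% NA_integer_,
       label_malignant = man$label_malignant %||% NA_integer_)
}

#' Read evaluation-only ground-truth masks of a bundle
#'
#' @param dir bundle directory with a `truth/` subdirectory.
#' @return list (per image) of lists with binary `benign`/`malignant`
#'   matrices.
#' @export
read_truth_masks <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  truth_dir <- file.path(dir, "truth")
  if (!dir.exists(truth_dir)) stop_field("dir", "no truth/ directory")
  lapply(seq_len(man$k), function(k) {
    lapply(stats::setNames(c("benign", "malignant"), c("benign", "malignant")),
           function(cls) {
             m <- png::readPNG(file.path(truth_dir, sprintf("%03d_%s.png", k, cls)))
             if (length(dim(m)) == 3) m <- m[, , 1]
             (m > 0.5) * 1L
           })
  })
}

#' Write a cohort of exams as bundles under a root directory
#'
#' One subdirectory per breast, named by `breast_id`, plus `truth_table.csv`
#' and `boxes.csv` at the root.
#'
#' @param cohort result of [gen_cohort()].
#' @param root output directory.
#' @param write_truth include ground-truth masks.
#' @return invisibly, `root`.
#' @export
write_cohort_bundles <- function(cohort, root, write_truth = TRUE) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  for (exam in cohort$exams) {
    write_exam_bundle(exam, file.path(root, exam$breast_id),
                      write_truth = write_truth)
  }
  utils::write.csv(cohort$truth, file.path(root, "truth_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$boxes, file.path(root, "boxes.csv"),
                   row.names = FALSE)
  invisible(root)
}

#' Read all exam bundles under a root directory
#'
#' @param root directory of bundle subdirectories.
#' @return list of training-view exams (see [read_exam_bundle()]).
#' @export
read_cohort_bundles <- function(root) {
  dirs <- list.dirs(root, recursive = FALSE)
  dirs <- dirs[file.exists(file.path(dirs, "manifest.json"))]
  if (length(dirs) == 0) stop_field("root", "no exam bundles found")
  lapply(dirs, read_exam_bundle)
}

#' Save a model or ensemble checkpoint
#'
#' A single RDS file whose payload embeds the model configuration (also as a
#' JSON header string) and the normalization statistics, so a checkpoint is
#' self-describing.
#'
#' @param object a `mil_model`, `trained_model` or `mil_ensemble`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
save_checkpoint <- function(object, path) {
  members <- resolve_model_(object)
  header <- jsonlite::toJSON(list(
    package = "sonomil", format = 1L, n_members = length(members),
    config = unclass(members[[1]]$config)), auto_unbox = TRUE)
  payload <- list(header = as.character(header), object = object)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file path.
#' @return the stored model or ensemble.
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  if (is.null(payload$header) || is.null(payload$object))
    stop_field("path", "not a sonomil checkpoint")
  payload$object
}
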