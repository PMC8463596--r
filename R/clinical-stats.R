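
# Reader-study evaluation statistics: BI-RADS ordinal coding, AUROC/AUPRC,
# matched operating points, hybrid reader-AI fusion, bootstrap CIs,
# one-tailed permutation tests, triage thresholds, subgroup metrics.

.birads_levels <- c("1", "2", "3", "4A", "4B", "4C", "5")
.birads_ordinal <- c("1" = 0, "2" = 0, "3" = 1, "4A" = 2, "4B" = 3, "4C" = 4, "5" = 5)

#' Convert BI-RADS scores to a 6-point ordinal index of suspicion
#'
#' Scores 1 and 2 collapse into the lowest level of suspicion (0); 3, 4A, 4B,
#' 4C and 5 are treated as increasing levels 1 through 5. A score of 0
#' (incomplete) or 6 (known cancer) is rejected: neither is a diagnostic
#' assessment of suspicion and reader studies in this setting do not permit
#' them. Any order-preserving recoding of these levels yields the same AUROC,
#' so the particular integer values carry no meaning beyond their order.
#'
#' @param score character or numeric vector of BI-RADS values
#'   (`1,2,3,4A,4B,4C,5`).
#' @return integer vector of suspicion levels in 0..5.
#' @export
#' @examples
#' birads_to_ordinal(c("1", "2", "4B"))
birads_to_ordinal <- function(score) {
  s <- toupper(trimws(as.character(score)))
  bad <- !(s %in% .birads_levels)
  if (any(bad)) {
    stop_field("score", sprintf(
      "BI-RADS value(s) %s not permitted; allowed: %s",
      paste(unique(s[bad]), collapse = ", "),
      paste(.birads_levels, collapse = ", ")))
  }
  unname(.birads_ordinal[s])
}

#' Dichotomize BI-RADS scores at the biopsy threshold
#'
#' BI-RADS 4A and above is a positive (biopsy-recommended) assessment;
#' 1-3 is negative.
#'
#' @inheritParams birads_to_ordinal
#' @return character vector `"positive"`/`"negative"`.
#' @export
dichotomize_birads <- function(score) {
  ord <- birads_to_ordinal(score)
  ifelse(ord >= 2, "positive", "negative")
}

check_labels_ <- function(labels) {
  if (!all(labels %in% c(0, 1))) stop_field("labels", "must be binary 0/1")
  labels <- as.integer(labels)
  labels
}

#' Area under the ROC curve
#'
#' Computed by the rank (Mann-Whitney) formula, equal to the probability that
#' a random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores numeric vector of predicted scores (higher = more suspicious).
#' @param labels binary 0/1 truth vector of the same length.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  labels <- check_labels_(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop_field("labels", "AUROC requires at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: precision is evaluated at every distinct score
#' threshold (ties grouped) and integrated over recall without interpolation.
#' With all scores equal this reduces to the prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  labels <- check_labels_(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop_field("labels", "AUPRC requires at least one positive")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  # group ties: cut points are the last index of each distinct score
  cuts <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[cuts]
  n_called <- cuts
  prec <- tp / n_called
  dtp <- diff(c(0, tp))
  sum(dtp * prec) / n_pos
}

confusion_at_ <- function(scores, labels, threshold) {
  pos_call <- scores >= threshold
  tp <- sum(pos_call & labels == 1L)
  fp <- sum(pos_call & labels == 0L)
  fn <- sum(!pos_call & labels == 1L)
  tn <- sum(!pos_call & labels == 0L)
  n <- length(labels)
  list(
    threshold = threshold,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    biopsy_rate = (tp + fp) / n,
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

candidate_thresholds_ <- function(scores) {
  # calling positive at score >= threshold; +Inf = call nobody
  c(sort(unique(scores)), Inf)
}

new_operating_point_ <- function(cm) {
  structure(cm[c("threshold", "sensitivity", "specificity",
                 "ppv", "npv", "biopsy_rate", "tp", "fp", "fn", "tn")],
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "operating point @ threshold %.6g\n  sens %.4f  spec %.4f  PPV %.4f  NPV %.4f  biopsy rate %.4f\n",
    x$threshold, x$sensitivity, x$specificity, x$ppv, x$npv, x$biopsy_rate))
  invisible(x)
}

#' Operating point matched to a target sensitivity or specificity
#'
#' Sweeps all achievable thresholds (predicting positive at score >= threshold)
#' and selects the one whose matched rate is the smallest value at or above
#' `target`; exact ties prefer the threshold maximizing the complementary rate.
#' No interpolation between thresholds is performed. PPV here is PPV2: cancers
#' recommended for biopsy divided by biopsies recommended.
#'
#' @inheritParams auroc
#' @param target target value for the matched rate, in \[0, 1\].
#' @param match `"sensitivity"` or `"specificity"`.
#' @return an `operating_point`: threshold, sensitivity, specificity, ppv
#'   (PPV2), npv, biopsy_rate, and confusion counts.
#' @export
operating_point_at <- function(scores, labels, target,
                               match = c("sensitivity", "specificity")) {
  match <- match.arg(match)
  labels <- check_labels_(labels)
  stopifnot(length(scores) == length(labels))
  if (!is.numeric(target) || length(target) != 1L || target < 0 || target > 1)
    stop_field("target", "must be a single value in [0, 1]")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop_field("labels", "requires both classes")
  cms <- lapply(candidate_thresholds_(scores), confusion_at_,
                scores = scores, labels = labels)
  matched <- vapply(cms, `[[`, numeric(1), match)
  other <- vapply(cms, `[[`, numeric(1),
                  if (match == "sensitivity") "specificity" else "sensitivity")
  ok <- which(matched >= target)
  if (length(ok) == 0L) {
    stop_field("target", sprintf("unreachable %s %.4f; best achievable is %.4f",
                                 match, target, max(matched)))
  }
  best_rate <- min(matched[ok])
  cand <- ok[matched[ok] == best_rate]
  pick <- cand[which.max(other[cand])]
  new_operating_point_(cms[[pick]])
}

#' Triage operating points for auto-dismissal or escalation
#'
#' `dismiss` mode finds the highest threshold whose NPV (among cases below the
#' threshold) meets `target` and reports the specificity attained there --
#' the fraction of benign/negative breasts that could be ruled out. `escalate`
#' mode finds the lowest threshold whose PPV meets `target` and reports the
#' sensitivity attained -- the fraction of cancers that would be fast-tracked.
#'
#' @inheritParams auroc
#' @param mode `"dismiss"` or `"escalate"`.
#' @param target minimum NPV (dismiss) or PPV (escalate) required.
#' @return an `operating_point`.
#' @export
triage_points <- function(scores, labels, mode = c("dismiss", "escalate"),
                          target) {
  mode <- match.arg(mode)
  labels <- check_labels_(labels)
  if (!is.numeric(target) || length(target) != 1L || target < 0 || target > 1)
    stop_field("target", "must be a single value in [0, 1]")
  if (sum(labels == 1L) == 0L || sum(labels == 0L) == 0L)
    stop_field("labels", "requires both classes")
  cms <- lapply(candidate_thresholds_(scores), confusion_at_,
                scores = scores, labels = labels)
  key <- if (mode == "dismiss") "npv" else "ppv"
  val <- vapply(cms, function(cm) cm[[key]] %||% NA_real_, numeric(1))
  thr <- vapply(cms, `[[`, numeric(1), "threshold")
  # a triage point must actually triage someone
  active <- if (mode == "dismiss") {
    vapply(cms, function(cm) cm$tn + cm$fn > 0, logical(1))
  } else {
    vapply(cms, function(cm) cm$tp + cm$fp > 0, logical(1))
  }
  ok <- which(active & !is.na(val) & val >= target)
  if (length(ok) == 0L) {
    stop_field("target", sprintf(
      "unreachable %s %.4f in %s mode; best achievable is %.4f",
      toupper(key), target, mode, max(val[active], na.rm = TRUE)))
  }
  pick <- if (mode == "dismiss") ok[which.max(thr[ok])] else ok[which.min(thr[ok])]
  new_operating_point_(cms[[pick]])
}

#' Fuse standardized reader and AI scores
#'
#' Each score vector is standardized to zero mean and unit variance over the
#' evaluation table, then combined as
#' `lambda * reader + (1 - lambda) * ai`. With `lambda` 0 or 1 the fused
#' ranking reproduces the single-source ranking exactly (standardization is a
#' monotone transform). A zero-variance input standardizes to all zeros with
#' a warning.
#'
#' @param reader_scores numeric vector, typically the ordinal BI-RADS
#'   suspicion index (see [birads_to_ordinal()]).
#' @param ai_scores numeric vector of model probabilities.
#' @param lambda fusion weight on the reader, in \[0, 1\]; default 0.5.
#' @return numeric vector of fused scores.
#' @export
hybrid_scores <- function(reader_scores, ai_scores, lambda = 0.5) {
  if (length(reader_scores) != length(ai_scores))
    stop_field("ai_scores", "reader and AI score vectors must have equal length")
  if (length(reader_scores) < 2L)
    stop_field("reader_scores", "need at least 2 rows to standardize")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1)
    stop_field("lambda", "must be a single value in [0, 1]")
  z <- function(x, what) {
    s <- stats::sd(x)
    if (s == 0) {
      warning(sprintf("%s scores have zero variance; standardized to zeros", what),
              call. = FALSE)
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  lambda * z(reader_scores, "reader") + (1 - lambda) * z(ai_scores, "AI")
}

#' Percentile bootstrap confidence interval for a table metric
#'
#' Resamples rows (breasts) with replacement and reports the percentile 2.5
#' and 97.5 quantiles of the metric across resamples. Resamples on which the
#' metric is undefined (for example a single-class resample for AUROC) are
#' redrawn; if more than half of the attempted resamples are undefined the
#' computation aborts.
#'
#' @param metric_fn function taking a data.frame (one resample of `table`)
#'   and returning a single number.
#' @param table data.frame of per-breast rows.
#' @param n_boot number of bootstrap iterations (default 1000).
#' @param seed RNG seed; the interval is deterministic given the seed.
#' @return a `ci_result`: `estimate`, `lower95`, `upper95`, `n_boot`.
#' @export
bootstrap_ci <- function(metric_fn, table, n_boot = 1000, seed = NULL) {
  stopifnot(is.function(metric_fn), is.data.frame(table), n_boot >= 1)
  n <- nrow(table)
  estimate <- metric_fn(table)
  stats_vec <- with_seed_(seed, {
    out <- numeric(n_boot)
    failures <- 0L
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(metric_fn(table[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
        if (!is.na(val)) { out[b] <- val; break }
        failures <- failures + 1L
        if (failures > n_boot / 2)
          stop("metric undefined on more than half of bootstrap resamples",
               call. = FALSE)
      }
    }
    out
  })
  q <- unname(stats::quantile(stats_vec, c(0.025, 0.975)))
  structure(list(estimate = estimate, lower95 = q[1], upper95 = q[2],
                 n_boot = as.integer(n_boot)),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  cat(sprintf("%.4f (95%% CI %.4f-%.4f; %d bootstrap iterations)\n",
              x$estimate, x$lower95, x$upper95, x$n_boot))
  invisible(x)
}

#' One-tailed paired permutation test between two score vectors
#'
#' Tests whether model `a` exceeds model `b` on `metric_fn`. The observed
#' statistic is `metric_fn(a) - metric_fn(b)`. Under the null each case's two
#' scores are exchangeable, so every trial independently swaps `a[i]` and
#' `b[i]` with probability 1/2 and recomputes the difference. The one-sided
#' p-value uses add-one smoothing, `(1 + #\{null >= observed\}) / (1 + n_trials)`,
#' and is therefore always in (0, 1\].
#'
#' @param metric_fn function of `(scores, labels)` returning a single number,
#'   e.g. [auroc()].
#' @param labels binary truth vector.
#' @param scores_a,scores_b equal-length score vectors for the two models.
#' @param n_trials number of permutation trials (default 10000).
#' @param seed RNG seed.
#' @return list with `p_value`, `observed`, `n_trials`.
#' @export
permutation_test <- function(metric_fn, labels, scores_a, scores_b,
                             n_trials = 10000, seed = NULL) {
  stopifnot(is.function(metric_fn))
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels))
    stop_field("scores_b", "labels, scores_a, scores_b must have equal length")
  if (n_trials < 1) stop_field("n_trials", "must be >= 1")
  observed <- metric_fn(scores_a, labels) - metric_fn(scores_b, labels)
  n <- length(labels)
  null_stats <- with_seed_(seed, {
    vapply(seq_len(n_trials), function(i) {
      swap <- stats::runif(n) < 0.5
      a <- ifelse(swap, scores_b, scores_a)
      b <- ifelse(swap, scores_a, scores_b)
      metric_fn(a, labels) - metric_fn(b, labels)
    }, numeric(1))
  })
  p <- (1 + sum(null_stats >= observed)) / (1 + n_trials)
  list(p_value = p, observed = observed, n_trials = as.integer(n_trials))
}

#' Per-subgroup metric with bootstrap confidence intervals
#'
#' Splits the table by `group_column` and computes `metric_fn` with a
#' bootstrap CI inside every subgroup containing both classes; single-class
#' subgroups are reported as undefined rather than propagating NaN.
#'
#' @inheritParams bootstrap_ci
#' @param group_column name of the stratification column in `table`.
#' @param label_column name of the binary truth column (default `"label"`).
#' @return data.frame with one row per group: `group`, `n`, `estimate`,
#'   `lower95`, `upper95`, `defined`.
#' @export
subgroup_eval <- function(table, group_column, metric_fn,
                          n_boot = 1000, seed = NULL, label_column = "label") {
  if (!group_column %in% names(table))
    stop_field("group_column", sprintf("column '%s' not found", group_column))
  groups <- split(table, table[[group_column]], drop = TRUE)
  rows <- lapply(names(groups), function(g) {
    sub <- groups[[g]]
    both <- length(unique(sub[[label_column]])) == 2L
    if (!both) {
      return(data.frame(group = g, n = nrow(sub), estimate = NA_real_,
                        lower95 = NA_real_, upper95 = NA_real_,
                        defined = FALSE, stringsAsFactors = FALSE))
    }
    ci <- bootstrap_ci(metric_fn, sub, n_boot = n_boot,
                       seed = if (is.null(seed)) NULL else derive_seed(seed, g))
    data.frame(group = g, n = nrow(sub), estimate = ci$estimate,
               lower95 = ci$lower95, upper95 = ci$upper95, defined = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
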