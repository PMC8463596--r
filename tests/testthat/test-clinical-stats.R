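
test_that("BI-RADS ordinal coding collapses 1-2 and rejects 0/6", {
  expect_equal(birads_to_ordinal(c("1", "2")), c(0, 0))
  expect_equal(birads_to_ordinal(c("3", "4A", "4B", "4C", "5")), 1:5)
  expect_error(birads_to_ordinal("0"), "not permitted")
  expect_error(birads_to_ordinal("6"), "not permitted")
  expect_equal(dichotomize_birads(c("3", "4A", "5")),
               c("negative", "positive", "positive"))
})

test_that("auroc equals the exhaustive pairwise oracle on random tables", {
  for (seed in 1:100) {
    tb <- random_prediction_table(sample(6:20, 1), seed)
    expect_equal(auroc(tb$scores, tb$labels),
                 auroc_pairwise_oracle(tb$scores, tb$labels),
                 tolerance = 1e-12)
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.3, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("auroc is invariant under strictly monotone score transforms", {
  tb <- random_prediction_table(15, 42)
  base <- auroc(tb$scores, tb$labels)
  expect_equal(auroc(exp(3 * tb$scores), tb$labels), base)
  expect_equal(auroc(rank(tb$scores, ties.method = "average"), tb$labels), base)
  # ordinal BI-RADS recoding: any order-preserving integer coding agrees
  br <- sample(c("1", "2", "3", "4A", "4B", "4C", "5"), 12, replace = TRUE)
  labels <- c(rep(1, 5), rep(0, 7))
  ord1 <- birads_to_ordinal(br)
  ord2 <- c(0, 0, 10, 20, 21, 22, 40)[match(br, c("1", "2", "3", "4A", "4B", "4C", "5"))]
  expect_equal(auroc(ord1, labels), auroc(ord2, labels))
})

test_that("auprc equals the threshold-sweep oracle and handles ties", {
  for (seed in 1:100) {
    tb <- random_prediction_table(sample(5:20, 1), seed + 500)
    expect_equal(auprc(tb$scores, tb$labels),
                 auprc_sweep_oracle(tb$scores, tb$labels),
                 tolerance = 1e-12)
  }
  expect_equal(auprc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  labels <- c(1, 0, 0, 1, 0)
  expect_equal(auprc(rep(0.7, 5), labels), mean(labels))
  expect_error(auprc(1:3, c(0, 0, 0)), "at least one positive")
})

test_that("operating_point_at matches exhaustive enumeration and identities", {
  for (seed in 1:100) {
    tb <- random_prediction_table(sample(8:20, 1), seed + 900)
    sweep <- sweep_rates_oracle(tb$scores, tb$labels)
    target <- runif(1, 0, 0.9)
    ok <- which(sweep$sens >= target)
    if (length(ok) == 0) {
      expect_error(operating_point_at(tb$scores, tb$labels, target, "sensitivity"),
                   "unreachable")
      next
    }
    op <- operating_point_at(tb$scores, tb$labels, target, "sensitivity")
    best_sens <- min(sweep$sens[ok])
    cand <- ok[sweep$sens[ok] == best_sens]
    expect_equal(op$sensitivity, best_sens, tolerance = 1e-12)
    expect_equal(op$specificity, max(sweep$spec[cand]), tolerance = 1e-12)
    # confusion-matrix identities
    n <- length(tb$labels)
    expect_equal(op$biopsy_rate, (op$tp + op$fp) / n)
    expect_equal(op$sensitivity, op$tp / (op$tp + op$fn))
    if (op$tp + op$fp > 0) {
      expect_equal(op$ppv * op$biopsy_rate * n, op$tp, tolerance = 1e-9)
    }
  }
})

test_that("operating point degenerate targets behave as expected", {
  scores <- c(0.1, 0.2, 0.6, 0.9)
  labels <- c(0, 0, 1, 1)
  op0 <- operating_point_at(scores, labels, 0, "sensitivity")
  expect_equal(op0$sensitivity, 0)
  expect_equal(op0$specificity, 1)
  expect_equal(op0$biopsy_rate, 0)
  op1 <- operating_point_at(scores, labels, 1, "sensitivity")
  expect_equal(op1$sensitivity, 1)
  expect_equal(op1$specificity, 1)  # separable scores
})

test_that("triage points match the sweep oracle in both modes", {
  for (seed in 1:50) {
    tb <- random_prediction_table(sample(10:20, 1), seed + 2000)
    sweep <- sweep_rates_oracle(tb$scores, tb$labels)
    # dismiss: highest threshold with NPV >= target among thresholds that
    # actually dismiss someone
    tgt <- 0.7
    ok <- which(!is.na(sweep$npv) & sweep$npv >= tgt)
    if (length(ok) > 0) {
      tp <- triage_points(tb$scores, tb$labels, "dismiss", tgt)
      expect_equal(tp$threshold, max(sweep$threshold[ok]))
    } else {
      expect_error(triage_points(tb$scores, tb$labels, "dismiss", tgt),
                   "unreachable")
    }
    ok2 <- which(!is.na(sweep$ppv) & sweep$ppv >= 0.6)
    if (length(ok2) > 0) {
      tp2 <- triage_points(tb$scores, tb$labels, "escalate", 0.6)
      expect_equal(tp2$threshold, min(sweep$threshold[ok2]))
    } else {
      expect_error(triage_points(tb$scores, tb$labels, "escalate", 0.6),
                   "unreachable")
    }
  }
  # separable scores: perfect NPV reachable with full specificity
  tp <- triage_points(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), "dismiss", 1.0)
  expect_equal(tp$specificity, 1)
  # escalate with PPV target at prevalence: threshold below all scores works
  tp2 <- triage_points(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), "escalate", 0.5)
  expect_equal(tp2$sensitivity, 1)
})

test_that("hybrid fusion endpoints reproduce single-source rankings exactly", {
  tb <- random_prediction_table(30, 77)
  reader <- sample(0:5, 30, replace = TRUE)
  expect_equal(auroc(hybrid_scores(reader, tb$scores, 1), tb$labels),
               auroc(reader, tb$labels))
  expect_equal(auroc(hybrid_scores(reader, tb$scores, 0), tb$labels),
               auroc(tb$scores, tb$labels))
  # hand-computed 6-row fusion at lambda 0.5
  r <- c(0, 1, 2, 5, 3, 1)
  a <- c(0.1, 0.2, 0.4, 0.9, 0.6, 0.15)
  zr <- (r - mean(r)) / sd(r)
  za <- (a - mean(a)) / sd(a)
  expect_equal(hybrid_scores(r, a, 0.5), 0.5 * zr + 0.5 * za)
  expect_warning(hybrid_scores(rep(2, 6), a), "zero variance")
})

test_that("bootstrap CI is seeded-deterministic with sane structure", {
  tb <- random_prediction_table(60, 5)
  tab <- data.frame(score = tb$scores, label = tb$labels)
  f <- function(d) auroc(d$score, d$label)
  ci1 <- bootstrap_ci(f, tab, n_boot = 200, seed = 9)
  ci2 <- bootstrap_ci(f, tab, n_boot = 200, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower95, ci1$upper95)
  expect_equal(ci1$estimate, f(tab))
  # constant metric gives a zero-width interval
  cic <- bootstrap_ci(function(d) 1, tab, n_boot = 50, seed = 1)
  expect_equal(cic$lower95, cic$upper95)
})

test_that("permutation test has add-one smoothing and null behavior", {
  tb <- random_prediction_table(40, 11)
  # identical score vectors: observed 0, all null stats 0, p = 1
  res <- permutation_test(auroc, tb$labels, tb$scores, tb$scores,
                          n_trials = 100, seed = 3)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1)
  # p always in (0, 1]
  other <- runif(40)
  res2 <- permutation_test(auroc, tb$labels, tb$scores, other,
                           n_trials = 200, seed = 4)
  expect_gt(res2$p_value, 0)
  expect_lte(res2$p_value, 1)
  res3 <- permutation_test(auroc, tb$labels, tb$scores, other,
                           n_trials = 200, seed = 4)
  expect_identical(res2, res3)
  expect_error(permutation_test(auroc, tb$labels, tb$scores, other,
                                n_trials = 0), "n_trials")
})

test_that("subgroup evaluation reports undefined groups without NaN", {
  tab <- data.frame(
    score = c(0.9, 0.2, 0.8, 0.4, 0.7, 0.6),
    label = c(1, 0, 1, 0, 1, 1),
    density = c("A", "A", "A", "A", "B", "B"))
  res <- subgroup_eval(tab, "density",
                       function(d) auroc(d$score, d$label),
                       n_boot = 50, seed = 2)
  expect_equal(nrow(res), 2)
  expect_true(res$defined[res$group == "A"])
  expect_false(res$defined[res$group == "B"])  # all-positive group
  expect_true(is.na(res$estimate[res$group == "B"]))
  expect_error(subgroup_eval(tab, "nope", function(d) 1), "not found")
  # single group equals the overall metric
  tab$one <- "g"
  res1 <- subgroup_eval(tab, "one", function(d) auroc(d$score, d$label),
                        n_boot = 20, seed = 2)
  expect_equal(res1$estimate, auroc(tab$score, tab$label))
})

test_that("auroc agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  for (seed in c(3, 14, 15)) {
    tb <- random_prediction_table(50, seed)
    ref <- as.numeric(pROC::auc(pROC::roc(tb$labels, tb$scores,
                                          quiet = TRUE, direction = "<")))
    expect_equal(auroc(tb$scores, tb$labels), ref, tolerance = 1e-12)
  }
})
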