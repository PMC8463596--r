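
mk_record <- function(birads = "1", biopsied = FALSE, pe = NULL, fu = NULL,
                      exam_date = "2016-03-01") {
  exam_record(exam_id = "E1", exam_date = exam_date, birads = birads,
              biopsied = biopsied, pathology_events = pe, followups = fu)
}

pe_row <- function(day, cat, guidance = "US", concordant = TRUE,
                   base = as.Date("2016-03-01")) {
  data.frame(date = base + day, finding_category = cat, guidance = guidance,
             concordant = concordant, stringsAsFactors = FALSE)
}

fu_row <- function(day, birads, base = as.Date("2016-03-01")) {
  data.frame(date = base + day, birads = birads, stringsAsFactors = FALSE)
}

test_that("label assignment uses the -30/+120 day window inclusively", {
  mal <- "invasive ductal carcinoma"
  ben <- "fibroadenoma"
  expect_equal(assign_labels(mk_record(pe = pe_row(60, mal)))[["y_m"]], 1L)
  expect_equal(assign_labels(mk_record(pe = pe_row(-45, mal)))[["y_m"]], 0L)
  # inclusive boundary days
  expect_equal(assign_labels(mk_record(pe = pe_row(-30, mal)))[["y_m"]], 1L)
  expect_equal(assign_labels(mk_record(pe = pe_row(-31, mal)))[["y_m"]], 0L)
  expect_equal(assign_labels(mk_record(pe = pe_row(120, mal)))[["y_m"]], 1L)
  expect_equal(assign_labels(mk_record(pe = pe_row(121, mal)))[["y_m"]], 0L)
  # both labels when both lesion types fall in the window
  both <- rbind(pe_row(10, ben), pe_row(100, mal))
  expect_equal(unname(assign_labels(mk_record(pe = both))), c(1L, 1L))
  expect_error(assign_labels(mk_record(pe = pe_row(10, "weird finding"))),
               "weird finding")
})

test_that("finding vocabulary sets are disjoint", {
  expect_length(intersect(finding_vocabulary$malignant,
                          finding_vocabulary$benign), 0)
})

test_that("negative/benign eligibility follows the 6-24 month follow-up rule", {
  # follow-up BI-RADS 2 at ~12 months, no malignancy: include
  v <- eligible_negative(mk_record(fu = fu_row(365, "2")))
  expect_equal(v$decision, "include")
  # only follow-up at ~30 months: exclude
  v2 <- eligible_negative(mk_record(fu = fu_row(913, "1")))
  expect_equal(v2$decision, "exclude")
  # malignancy at ~10 months: exclude even with a good follow-up
  mal <- pe_row(304, "ductal carcinoma in situ")
  v3 <- eligible_negative(mk_record(pe = mal, fu = fu_row(365, "2")))
  expect_equal(v3$decision, "exclude")
  expect_equal(v3$rule_id, "neg_malignancy_0_15")
  # inclusive boundaries: 6 months = day 183, 24 months = day 731
  expect_equal(eligible_negative(mk_record(fu = fu_row(183, "2")))$decision,
               "include")
  expect_equal(eligible_negative(mk_record(fu = fu_row(182, "2")))$decision,
               "exclude")
  expect_equal(eligible_negative(mk_record(fu = fu_row(731, "1")))$decision,
               "include")
  expect_equal(eligible_negative(mk_record(fu = fu_row(732, "1")))$decision,
               "exclude")
  # malignancy bar inclusive at 15 months = day 457
  mal457 <- pe_row(457, "lymphoma")
  expect_equal(eligible_negative(mk_record(pe = mal457,
                                           fu = fu_row(365, "2")))$decision,
               "exclude")
  mal458 <- pe_row(458, "lymphoma")
  expect_equal(eligible_negative(mk_record(pe = mal458,
                                           fu = fu_row(365, "2")))$decision,
               "include")
  # suspicious follow-up does not qualify
  expect_equal(eligible_negative(mk_record(fu = fu_row(365, "4A")))$decision,
               "exclude")
  expect_error(eligible_negative(mk_record(birads = "3")), "non-biopsied")
})

test_that("BI-RADS 3 eligibility implements both inclusion branches", {
  b3 <- function(...) mk_record(birads = "3", ...)
  # branch 1: all follow-ups in 4-36 months are BI-RADS 1-2
  v <- eligible_probably_benign(b3(fu = rbind(fu_row(244, "2"), fu_row(609, "1"))))
  expect_equal(v$decision, "include")
  expect_equal(v$rule_id, "b3_all_clear_4_36")
  # branch 2: single BI-RADS 3 follow-up at ~30 months
  v2 <- eligible_probably_benign(b3(fu = fu_row(913, "3")))
  expect_equal(v2$decision, "include")
  expect_equal(v2$rule_id, "b3_late_followup_24_36")
  # single BI-RADS 3 follow-up at ~12 months satisfies neither branch
  expect_equal(eligible_probably_benign(b3(fu = fu_row(365, "3")))$decision,
               "exclude")
  # boundaries: 4 months = day 122, 24 months = 731, 36 months = 1096
  expect_equal(eligible_probably_benign(b3(fu = fu_row(122, "2")))$decision,
               "include")
  expect_equal(eligible_probably_benign(b3(fu = fu_row(1096, "1")))$decision,
               "include")
  expect_equal(eligible_probably_benign(b3(fu = fu_row(731, "3")))$decision,
               "include")
  expect_equal(eligible_probably_benign(b3(fu = fu_row(730, "3")))$decision,
               "exclude")
  # no follow-up at all: the vacuous reading of branch 1 is rejected
  expect_equal(eligible_probably_benign(b3())$decision, "exclude")
  # a BI-RADS 3 follow-up inside 4-36 months spoils branch 1 even with a
  # clean later follow-up below 24 months
  v3 <- eligible_probably_benign(b3(fu = rbind(fu_row(300, "3"), fu_row(500, "2"))))
  expect_equal(v3$decision, "exclude")
  # malignancy within 15 months excludes
  expect_equal(eligible_probably_benign(
    b3(pe = pe_row(300, "phyllodes"), fu = fu_row(365, "2")))$decision,
    "exclude")
})

test_that("discordant benign biopsies need resolution within 6 months", {
  disc <- pe_row(10, "fibroadenoma", concordant = FALSE)
  surg <- function(day) pe_row(day, "scar", guidance = "surgery")
  reb <- function(day) pe_row(day, "cyst", concordant = TRUE)
  expect_equal(resolve_discordant(mk_record(biopsied = TRUE,
    pe = rbind(disc, surg(100))))$decision, "include")
  expect_equal(resolve_discordant(mk_record(biopsied = TRUE,
    pe = rbind(disc, reb(150))))$decision, "include")
  expect_equal(resolve_discordant(mk_record(biopsied = TRUE,
    pe = disc))$decision, "exclude")
  # second discordant biopsy does not resolve
  disc2 <- pe_row(80, "papilloma", concordant = FALSE)
  expect_equal(resolve_discordant(mk_record(biopsied = TRUE,
    pe = rbind(disc, disc2)))$decision, "exclude")
  # 6-month boundary (183 days from the discordant biopsy), inclusive
  expect_equal(resolve_discordant(mk_record(biopsied = TRUE,
    pe = rbind(disc, surg(10 + 183))))$decision, "include")
  expect_equal(resolve_discordant(mk_record(biopsied = TRUE,
    pe = rbind(disc, surg(10 + 184))))$decision, "exclude")
  expect_error(resolve_discordant(mk_record()), "discordant")
})

test_that("cancer visibility filter routes by BI-RADS and biopsy guidance", {
  mal <- function(guidance) pe_row(30, "invasive lobular carcinoma",
                                   guidance = guidance)
  rec <- function(birads, pe) mk_record(birads = birads, biopsied = TRUE, pe = pe)
  expect_equal(cancer_visibility_filter(rec("2", mal("US")))$decision, "exclude")
  v <- cancer_visibility_filter(rec("4B", mal("US")))
  expect_equal(v$decision, "include")
  expect_equal(cancer_visibility_filter(rec("4B", mal("stereotactic")))$decision,
               "exclude")
  expect_equal(cancer_visibility_filter(rec("5", mal("MRI")))$decision,
               "exclude")
  multi <- rbind(mal("US"), mal("stereotactic"))
  expect_equal(cancer_visibility_filter(rec("4B", multi))$decision,
               "manual_review")
  for (b in c("0", "3", "6")) {
    expect_equal(cancer_visibility_filter(rec(b, mal("US")))$decision,
                 "manual_review")
  }
  expect_error(cancer_visibility_filter(mk_record()), "malignant")
})

test_that("build_test_set routes the 200-record generator fixture exactly", {
  records <- gen_exam_records(200, seed = 31)
  res <- build_test_set(records)
  expect_equal(nrow(res$audit), 200)
  intended <- vapply(records, `[[`, character(1), "intended_verdict")
  agree <- res$audit$decision == intended
  if (!all(agree)) {
    bad <- which(!agree)[1]
    info <- sprintf("first disagreement: branch=%s intended=%s got=%s (%s)",
                    records[[bad]]$branch, intended[bad],
                    res$audit$decision[bad], res$audit$rule_id[bad])
  } else info <- NULL
  expect_true(all(agree), info = info)
  # every branch represented at least 5 times at n = 200
  branches <- vapply(records, `[[`, character(1), "branch")
  expect_gte(min(table(branches)), 5)
  # verdict field values and audit partition
  expect_true(all(intended %in% c("include", "exclude", "manual_review")))
  expect_setequal(unique(res$audit$decision),
                  c("include", "exclude", "manual_review"))
  inc_ids <- vapply(res$included, `[[`, character(1), "exam_id")
  expect_setequal(inc_ids, res$audit$exam_id[res$audit$decision == "include"])
  # every exclude/manual_review verdict carries a rule id
  not_inc <- res$audit$decision != "include"
  expect_true(all(nzchar(res$audit$rule_id[not_inc])))
})

test_that("build_test_set is total and handles edge inputs", {
  empty <- build_test_set(list())
  expect_equal(nrow(empty$audit), 0)
  expect_length(empty$included, 0)
  unk <- mk_record(birads = "unknown")
  res <- build_test_set(list(unk))
  expect_equal(res$audit$decision, "exclude")
  expect_equal(res$audit$rule_id, "unroutable")
  # non-biopsied suspicious exam with no pathology has no truth rule
  res2 <- build_test_set(list(mk_record(birads = "4A")))
  expect_equal(res2$audit$rule_id, "unroutable")
})

test_that("exam records survive a CSV round trip", {
  records <- gen_exam_records(20, seed = 7)
  tmp <- withr::local_tempdir()
  paths <- file.path(tmp, c("records.csv", "pathology.csv", "followups.csv"))
  write_exam_records(records, paths[1], paths[2], paths[3])
  back <- read_exam_records(paths[1], paths[2], paths[3])
  expect_length(back, 20)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$exam_id, records[[i]]$exam_id)
    expect_equal(back[[i]]$birads, records[[i]]$birads)
    expect_equal(back[[i]]$exam_date, records[[i]]$exam_date)
    expect_equal(nrow(back[[i]]$pathology_events),
                 nrow(records[[i]]$pathology_events))
    expect_equal(nrow(back[[i]]$followups), nrow(records[[i]]$followups))
  }
  # routing decisions identical after the round trip
  expect_equal(build_test_set(back)$audit$decision,
               build_test_set(records)$audit$decision)
})

test_that("gen_exam_records is seeded-deterministic", {
  r1 <- gen_exam_records(30, seed = 5)
  r2 <- gen_exam_records(30, seed = 5)
  expect_identical(r1, r2)
  r3 <- gen_exam_records(30, seed = 6)
  expect_false(identical(r1, r3))
})
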