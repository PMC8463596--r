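
# Cohort construction: breast-level label assignment from pathology windows
# and test-set eligibility rules, with a per-record audit trail.

#' Controlled vocabularies for pathology finding categories
#'
#' Malignant findings cover primary breast cancers (invasive ductal/lobular,
#' special-type invasive, inflammatory, intraductal papillary, microinvasive
#' carcinoma, DCIS) and non-primary cancers (lymphoma, phyllodes). Benign
#' findings cover the common biopsy-proven benign diagnoses. The two sets are
#' disjoint; any other term is rejected by [assign_labels()].
#'
#' @format list with character vectors `malignant` and `benign`.
#' @export
finding_vocabulary <- list(
  malignant = c(
    "invasive ductal carcinoma", "invasive lobular carcinoma",
    "special-type invasive carcinoma", "inflammatory carcinoma",
    "intraductal papillary carcinoma", "microinvasive carcinoma",
    "ductal carcinoma in situ", "lymphoma", "phyllodes"),
  benign = c(
    "cyst", "fibroadenoma", "scar", "sclerosing adenosis",
    "lobular carcinoma in situ", "columnar cell changes",
    "atypical lobular hyperplasia", "atypical ductal hyperplasia",
    "papilloma", "periductal mastitis", "usual ductal hyperplasia")
)

# Calendar convention: a "month" is a 30.44-day multiple rounded to whole
# days; all window endpoints are inclusive on both ends.
months_to_days <- function(m) round(30.44 * m)

#' Construct an exam metadata record
#'
#' @param exam_id,patient_id identifiers.
#' @param laterality `"left"` or `"right"`.
#' @param exam_date exam date (`Date` or ISO-8601 string).
#' @param birads BI-RADS assessment of the exam: one of
#'   `0,1,2,3,4A,4B,4C,5,6,unknown`.
#' @param biopsied whether the breast underwent biopsy.
#' @param pathology_events data.frame with columns `date`,
#'   `finding_category` (see [finding_vocabulary]), `guidance`
#'   (`US`, `stereotactic`, `MRI`, `surgery`) and `concordant` (logical).
#' @param followups data.frame with columns `date` and `birads`.
#' @return an `exam_record`.
#' @export
exam_record <- function(exam_id, patient_id = exam_id, laterality = "left",
                        exam_date, birads, biopsied = FALSE,
                        pathology_events = NULL, followups = NULL) {
  birads <- toupper(trimws(as.character(birads)))
  if (identical(birads, "UNKNOWN")) birads <- "unknown"
  allowed <- c("0", "1", "2", "3", "4A", "4B", "4C", "5", "6", "unknown")
  if (!birads %in% allowed)
    stop_field("birads", sprintf("'%s' not in {%s}", birads,
                                 paste(allowed, collapse = ",")))
  exam_date <- as.Date(exam_date)
  if (is.na(exam_date)) stop_field("exam_date", "not a valid date")
  empty_path <- data.frame(date = as.Date(character()),
                           finding_category = character(),
                           guidance = character(), concordant = logical(),
                           stringsAsFactors = FALSE)
  empty_fu <- data.frame(date = as.Date(character()), birads = character(),
                         stringsAsFactors = FALSE)
  pe <- pathology_events %||% empty_path
  fu <- followups %||% empty_fu
  pe$date <- as.Date(pe$date)
  if (nrow(pe) > 0) {
    bad_guid <- !pe$guidance %in% c("US", "stereotactic", "MRI", "surgery")
    if (any(bad_guid))
      stop_field("pathology_events$guidance",
                 paste(unique(pe$guidance[bad_guid]), collapse = ", "))
  }
  fu$date <- as.Date(fu$date)
  fu$birads <- toupper(trimws(as.character(fu$birads)))
  structure(list(exam_id = as.character(exam_id),
                 patient_id = as.character(patient_id),
                 laterality = laterality, exam_date = exam_date,
                 birads = birads, biopsied = isTRUE(biopsied),
                 pathology_events = pe, followups = fu),
            class = "exam_record")
}

events_in_window_ <- function(record, category_set, from_days, to_days) {
  pe <- record$pathology_events
  if (nrow(pe) == 0) return(pe[0, ])
  unknown <- !pe$finding_category %in%
    c(finding_vocabulary$malignant, finding_vocabulary$benign)
  if (any(unknown))
    stop_field("finding_category",
               paste(unique(pe$finding_category[unknown]), collapse = ", "))
  d <- as.numeric(pe$date - record$exam_date)
  pe[pe$finding_category %in% category_set & d >= from_days & d <= to_days, ,
     drop = FALSE]
}

#' Assign breast-level benign/malignant labels from pathology windows
#'
#' A breast is labeled malignant if any pathology event with a malignant
#' finding is dated within 30 days prior through 120 days after the exam
#' (endpoints inclusive); the benign label is analogous. A breast with both
#' lesion types in the window carries both labels.
#'
#' @param record an [exam_record()].
#' @return named integer vector `c(y_b = , y_m = )`.
#' @export
assign_labels <- function(record) {
  stopifnot(inherits(record, "exam_record"))
  y_m <- nrow(events_in_window_(record, finding_vocabulary$malignant,
                                -30, 120)) > 0
  y_b <- nrow(events_in_window_(record, finding_vocabulary$benign,
                                -30, 120)) > 0
  c(y_b = as.integer(y_b), y_m = as.integer(y_m))
}

verdict_ <- function(decision, rule_id, note = "") {
  structure(list(decision = decision, rule_id = rule_id, note = note),
            class = "eligibility_verdict")
}

#' @export
print.eligibility_verdict <- function(x, ...) {
  cat(sprintf("%s [%s]%s\n", x$decision, x$rule_id,
              if (nzchar(x$note)) paste0(" - ", x$note) else ""))
  invisible(x)
}

# malignant pathology bar shared by the non-biopsied rules: no malignant
# finding 0-15 months (inclusive) after the exam
has_malignancy_0_15_ <- function(record) {
  nrow(events_in_window_(record, finding_vocabulary$malignant,
                         0, months_to_days(15))) > 0
}

followup_days_ <- function(record) {
  as.numeric(record$followups$date - record$exam_date)
}

#' Eligibility of a non-biopsied negative/benign (BI-RADS 1-2) exam
#'
#' Included only if no malignant pathology occurred within 0-15 months after
#' the exam and at least one follow-up between 6 and 24 months (inclusive)
#' was assessed BI-RADS 1-2.
#'
#' @param record an [exam_record()] with `biopsied = FALSE` and BI-RADS 1-2.
#' @return an `eligibility_verdict`.
#' @export
eligible_negative <- function(record) {
  stopifnot(inherits(record, "exam_record"))
  if (record$biopsied || !record$birads %in% c("1", "2"))
    stop_field("record", "eligible_negative applies to non-biopsied BI-RADS 1-2 exams")
  if (has_malignancy_0_15_(record))
    return(verdict_("exclude", "neg_malignancy_0_15",
                    "malignant pathology within 0-15 months"))
  d <- followup_days_(record)
  ok <- d >= months_to_days(6) & d <= months_to_days(24) &
    record$followups$birads %in% c("1", "2")
  if (any(ok)) {
    verdict_("include", "neg_followup_ok")
  } else {
    verdict_("exclude", "neg_no_followup_6_24",
             "no BI-RADS 1-2 follow-up in 6-24 months")
  }
}

#' Eligibility of a non-biopsied probably-benign (BI-RADS 3) exam
#'
#' Included only if no malignant pathology occurred within 0-15 months and
#' either (a) there is at least one follow-up in 4-36 months and every
#' follow-up in that window is BI-RADS 1-2, or (b) at least one follow-up in
#' 24-36 months is BI-RADS 1-3. All windows inclusive.
#'
#' @param record an [exam_record()] with `biopsied = FALSE` and BI-RADS 3.
#' @return an `eligibility_verdict`.
#' @export
eligible_probably_benign <- function(record) {
  stopifnot(inherits(record, "exam_record"))
  if (record$biopsied || record$birads != "3")
    stop_field("record", "eligible_probably_benign applies to non-biopsied BI-RADS 3 exams")
  if (has_malignancy_0_15_(record))
    return(verdict_("exclude", "b3_malignancy_0_15",
                    "malignant pathology within 0-15 months"))
  d <- followup_days_(record)
  fu <- record$followups$birads
  in_4_36 <- d >= months_to_days(4) & d <= months_to_days(36)
  branch1 <- any(in_4_36) && all(fu[in_4_36] %in% c("1", "2"))
  in_24_36 <- d >= months_to_days(24) & d <= months_to_days(36)
  branch2 <- any(in_24_36 & fu %in% c("1", "2", "3"))
  if (branch1) {
    verdict_("include", "b3_all_clear_4_36")
  } else if (branch2) {
    verdict_("include", "b3_late_followup_24_36")
  } else {
    verdict_("exclude", "b3_no_qualifying_followup",
             "neither follow-up branch satisfied")
  }
}

#' Resolution of a discordant benign biopsy
#'
#' A breast whose biopsy confirmed a benign finding judged discordant with
#' its imaging appearance is included only if a subsequent non-discordant
#' biopsy or breast surgery occurred within 6 months (inclusive) of the
#' discordant biopsy.
#'
#' @param record an [exam_record()] with at least one benign pathology event
#'   flagged discordant.
#' @return an `eligibility_verdict`.
#' @export
resolve_discordant <- function(record) {
  stopifnot(inherits(record, "exam_record"))
  pe <- record$pathology_events
  disc <- pe$finding_category %in% finding_vocabulary$benign & !pe$concordant
  if (!any(disc))
    stop_field("record", "resolve_discordant requires a discordant benign pathology event")
  disc_date <- min(pe$date[disc])
  rel <- as.numeric(pe$date - disc_date)
  resolving <- (pe$guidance == "surgery" | pe$concordant) &
    rel >= 0 & rel <= months_to_days(6)
  if (any(resolving)) {
    verdict_("include", "discordant_resolved")
  } else {
    verdict_("exclude", "discordant_unresolved",
             "no non-discordant biopsy or surgery within 6 months")
  }
}

#' Visibility filter for pathology-proven cancers
#'
#' Ultrasound fields of view are small, so a cancer proven by pathology may
#' not appear in any image of the exam. Malignant breasts assessed BI-RADS
#' 1-2 are excluded (such exams typically do not image the cancer), as are
#' breasts with no US-guided pathology at all (cancers diagnosed purely by
#' MRI or stereotactic guidance are usually sonographically occult). BI-RADS
#' 0, 3 or 6, or pathology under multi-modal guidance, route to manual
#' review; BI-RADS 4A-5 with exclusively US-guided pathology is presumed
#' visible and included.
#'
#' @param record an [exam_record()] whose malignant label is 1
#'   (see [assign_labels()]).
#' @return an `eligibility_verdict`.
#' @export
cancer_visibility_filter <- function(record) {
  stopifnot(inherits(record, "exam_record"))
  labels <- assign_labels(record)
  if (labels[["y_m"]] != 1L)
    stop_field("record", "cancer_visibility_filter applies to malignant-labeled breasts")
  if (record$birads %in% c("1", "2"))
    return(verdict_("exclude", "vis_birads_low",
                    "malignant label with BI-RADS 1-2: cancer not imaged"))
  guid <- unique(record$pathology_events$guidance)
  guid <- setdiff(guid, "surgery")
  if (!"US" %in% guid)
    return(verdict_("exclude", "vis_no_us_guidance",
                    "no US-guided pathology; presumed sonographically occult"))
  multimodal <- length(intersect(guid, c("stereotactic", "MRI"))) > 0
  if (record$birads %in% c("0", "3", "6") || multimodal)
    return(verdict_("manual_review", "vis_manual_review",
                    "visibility cannot be presumed; needs case review"))
  verdict_("include", "vis_us_guided")
}

route_record_ <- function(record) {
  if (record$birads == "unknown")
    return(verdict_("exclude", "unroutable", "BI-RADS unknown"))
  labels <- assign_labels(record)
  pe <- record$pathology_events
  if (labels[["y_m"]] == 1L) return(cancer_visibility_filter(record))
  disc <- nrow(pe) > 0 &&
    any(pe$finding_category %in% finding_vocabulary$benign & !pe$concordant)
  if (disc) return(resolve_discordant(record))
  if (labels[["y_b"]] == 1L)
    return(verdict_("include", "benign_concordant"))
  if (!record$biopsied && record$birads %in% c("1", "2"))
    return(eligible_negative(record))
  if (!record$biopsied && record$birads == "3")
    return(eligible_probably_benign(record))
  verdict_("exclude", "unroutable",
           sprintf("non-biopsied BI-RADS %s has no truth rule", record$birads))
}

#' Build an evaluation cohort with an audit trail
#'
#' Labels every record via [assign_labels()], routes it to the applicable
#' eligibility rule by label, BI-RADS and biopsy status, and returns the
#' included records together with a one-row-per-record audit log. Included,
#' excluded and manual-review records partition the input; records no rule
#' covers are excluded with rule id `"unroutable"`.
#'
#' @param records list of [exam_record()] objects.
#' @return list with `included` (list of records), `audit` (data.frame:
#'   `exam_id`, `y_b`, `y_m`, `decision`, `rule_id`, `note`).
#' @export
build_test_set <- function(records) {
  stopifnot(is.list(records))
  if (length(records) == 0) {
    return(list(included = list(),
                audit = data.frame(exam_id = character(), y_b = integer(),
                                   y_m = integer(), decision = character(),
                                   rule_id = character(), note = character(),
                                   stringsAsFactors = FALSE)))
  }
  rows <- vector("list", length(records))
  keep <- logical(length(records))
  for (i in seq_along(records)) {
    rec <- records[[i]]
    labels <- tryCatch(assign_labels(rec), error = function(e) c(y_b = NA_integer_, y_m = NA_integer_))
    v <- route_record_(rec)
    keep[i] <- v$decision == "include"
    rows[[i]] <- data.frame(exam_id = rec$exam_id, y_b = labels[["y_b"]],
                            y_m = labels[["y_m"]], decision = v$decision,
                            rule_id = v$rule_id, note = v$note,
                            stringsAsFactors = FALSE)
  }
  list(included = records[keep], audit = do.call(rbind, rows))
}

#' Read exam records from relational CSV tables
#'
#' `records_csv` has one row per breast-exam (`exam_id`, `patient_id`,
#' `laterality`, `exam_date`, `birads`, `biopsied`); `pathology_csv`
#' (`exam_id`, `date`, `finding_category`, `guidance`, `concordant`) and
#' `followups_csv` (`exam_id`, `date`, `birads`) attach nested events by
#' `exam_id`. Dates are ISO-8601.
#'
#' @param records_csv,pathology_csv,followups_csv file paths; the latter two
#'   optional.
#' @return list of [exam_record()] objects.
#' @export
read_exam_records <- function(records_csv, pathology_csv = NULL,
                              followups_csv = NULL) {
  main <- utils::read.csv(records_csv, stringsAsFactors = FALSE,
                          colClasses = c(exam_id = "character"))
  pe <- if (!is.null(pathology_csv))
    utils::read.csv(pathology_csv, stringsAsFactors = FALSE,
                    colClasses = c(exam_id = "character")) else NULL
  fu <- if (!is.null(followups_csv))
    utils::read.csv(followups_csv, stringsAsFactors = FALSE,
                    colClasses = c(exam_id = "character")) else NULL
  lapply(seq_len(nrow(main)), function(i) {
    row <- main[i, ]
    sub_pe <- if (!is.null(pe)) pe[pe$exam_id == row$exam_id,
                                   c("date", "finding_category", "guidance",
                                     "concordant"), drop = FALSE] else NULL
    if (!is.null(sub_pe) && nrow(sub_pe) == 0) sub_pe <- NULL
    if (!is.null(sub_pe)) sub_pe$concordant <- as.logical(sub_pe$concordant)
    sub_fu <- if (!is.null(fu)) fu[fu$exam_id == row$exam_id,
                                   c("date", "birads"), drop = FALSE] else NULL
    if (!is.null(sub_fu) && nrow(sub_fu) == 0) sub_fu <- NULL
    exam_record(exam_id = row$exam_id, patient_id = row$patient_id,
                laterality = row$laterality, exam_date = row$exam_date,
                birads = row$birads, biopsied = as.logical(row$biopsied),
                pathology_events = sub_pe, followups = sub_fu)
  })
}

#' Write exam records to relational CSV tables
#'
#' Inverse of [read_exam_records()].
#'
#' @param records list of [exam_record()] objects.
#' @param records_csv,pathology_csv,followups_csv output paths.
#' @return invisibly, the three paths.
#' @export
write_exam_records <- function(records, records_csv, pathology_csv,
                               followups_csv) {
  main <- do.call(rbind, lapply(records, function(r) {
    data.frame(exam_id = r$exam_id, patient_id = r$patient_id,
               laterality = r$laterality,
               exam_date = format(r$exam_date), birads = r$birads,
               biopsied = r$biopsied, stringsAsFactors = FALSE)
  }))
  pe <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$pathology_events) == 0) return(NULL)
    cbind(data.frame(exam_id = r$exam_id, stringsAsFactors = FALSE),
          transform(r$pathology_events, date = format(date)))
  }))
  fu <- do.call(rbind, lapply(records, function(r) {
    if (nrow(r$followups) == 0) return(NULL)
    cbind(data.frame(exam_id = r$exam_id, stringsAsFactors = FALSE),
          transform(r$followups, date = format(date)))
  }))
  utils::write.csv(main, records_csv, row.names = FALSE)
  utils::write.csv(pe %||% data.frame(exam_id = character(), date = character(),
                                      finding_category = character(),
                                      guidance = character(),
                                      concordant = logical()),
                   pathology_csv, row.names = FALSE)
  utils::write.csv(fu %||% data.frame(exam_id = character(), date = character(),
                                      birads = character()),
                   followups_csv, row.names = FALSE)
  invisible(c(records_csv, pathology_csv, followups_csv))
}
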