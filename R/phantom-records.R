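
# Synthetic exam-metadata records spanning every cohort-rule branch, each
# carrying the branch's intended verdict (derived from the clinical rules'
# written windows, independently of the rules engine implementation).

rec_day_ <- function(base, day) base + day

# One branch = name, intended decision, and a builder that draws a record
# with randomized-but-safe dates inside the branch's window.
record_branches_ <- function() {
  ben <- function() sample(finding_vocabulary$benign, 1)
  mal <- function() sample(finding_vocabulary$malignant, 1)
  pe <- function(base, day, cat, guidance = "US", concordant = TRUE) {
    data.frame(date = rec_day_(base, day), finding_category = cat,
               guidance = guidance, concordant = concordant,
               stringsAsFactors = FALSE)
  }
  fu <- function(base, day, birads) {
    data.frame(date = rec_day_(base, day), birads = as.character(birads),
               stringsAsFactors = FALSE)
  }
  b <- list()
  add <- function(name, intended, build) {
    b[[length(b) + 1]] <<- list(name = name, intended = intended, build = build)
  }

  # --- non-biopsied BI-RADS 1-2: follow-up 6-24 months, malignancy bar 0-15
  add("neg_fu_ok", "include", function(d)
    list(birads = sample(c("1", "2"), 1), biopsied = FALSE,
         followups = fu(d, sample(184:730, 1), sample(c("1", "2"), 1))))
  add("neg_fu_boundary_6mo", "include", function(d)
    list(birads = "1", biopsied = FALSE, followups = fu(d, 183, "2")))
  add("neg_fu_boundary_24mo", "include", function(d)
    list(birads = "2", biopsied = FALSE, followups = fu(d, 731, "1")))
  add("neg_fu_late", "exclude", function(d)
    list(birads = "1", biopsied = FALSE,
         followups = fu(d, sample(732:900, 1), "1")))
  add("neg_fu_early", "exclude", function(d)
    list(birads = "2", biopsied = FALSE,
         followups = fu(d, sample(30:182, 1), "1")))
  add("neg_fu_suspicious", "exclude", function(d)
    list(birads = "1", biopsied = FALSE,
         followups = fu(d, sample(184:730, 1), sample(c("3", "4A"), 1))))
  add("neg_malignancy_15mo", "exclude", function(d)
    list(birads = "1", biopsied = FALSE,
         pathology_events = pe(d, sample(150:456, 1), mal()),
         followups = fu(d, 400, "2")))
  add("neg_malignancy_boundary_457d", "exclude", function(d)
    list(birads = "2", biopsied = FALSE,
         pathology_events = pe(d, 457, mal()),
         followups = fu(d, 300, "1")))
  add("neg_malignancy_past_15mo", "include", function(d)
    list(birads = "1", biopsied = FALSE,
         pathology_events = pe(d, sample(458:600, 1), mal()),
         followups = fu(d, sample(184:730, 1), "2")))

  # --- non-biopsied BI-RADS 3: two inclusion branches
  add("b3_all_clear", "include", function(d)
    list(birads = "3", biopsied = FALSE,
         followups = do.call(rbind, lapply(
           sort(sample(123:1095, sample(1:3, 1))), function(day)
             fu(d, day, sample(c("1", "2"), 1))))))
  add("b3_all_clear_boundary_4mo", "include", function(d)
    list(birads = "3", biopsied = FALSE, followups = fu(d, 122, "2")))
  add("b3_all_clear_boundary_36mo", "include", function(d)
    list(birads = "3", biopsied = FALSE, followups = fu(d, 1096, "1")))
  add("b3_late_birads3", "include", function(d)
    list(birads = "3", biopsied = FALSE,
         followups = fu(d, sample(732:1095, 1), "3")))
  add("b3_late_boundary_24mo", "include", function(d)
    list(birads = "3", biopsied = FALSE, followups = fu(d, 731, "3")))
  add("b3_early_birads3", "exclude", function(d)
    list(birads = "3", biopsied = FALSE,
         followups = fu(d, sample(123:730, 1), "3")))
  add("b3_mixed_fail", "exclude", function(d)
    list(birads = "3", biopsied = FALSE,
         followups = rbind(fu(d, 300, "3"),
                           fu(d, sample(400:700, 1), "2"))))
  add("b3_no_followup", "exclude", function(d)
    list(birads = "3", biopsied = FALSE))
  add("b3_malignancy_15mo", "exclude", function(d)
    list(birads = "3", biopsied = FALSE,
         pathology_events = pe(d, sample(150:456, 1), mal()),
         followups = fu(d, 300, "2")))

  # --- discordant benign biopsies: resolution within 6 months
  add("disc_resolved_surgery", "include", function(d)
    list(birads = "4A", biopsied = TRUE,
         pathology_events = rbind(
           pe(d, 10, ben(), concordant = FALSE),
           pe(d, 10 + sample(30:180, 1), ben(), guidance = "surgery"))))
  add("disc_resolved_boundary_6mo", "include", function(d)
    list(birads = "4A", biopsied = TRUE,
         pathology_events = rbind(
           pe(d, 10, ben(), concordant = FALSE),
           pe(d, 10 + 183, ben(), guidance = "surgery"))))
  add("disc_resolved_too_late", "exclude", function(d)
    list(birads = "4B", biopsied = TRUE,
         pathology_events = rbind(
           pe(d, 10, ben(), concordant = FALSE),
           pe(d, 10 + sample(184:300, 1), ben(), guidance = "surgery"))))
  add("disc_rebiopsy_concordant", "include", function(d)
    list(birads = "4A", biopsied = TRUE,
         pathology_events = rbind(
           pe(d, 5, ben(), concordant = FALSE),
           pe(d, 5 + sample(30:180, 1), ben()))))
  add("disc_unresolved", "exclude", function(d)
    list(birads = "4A", biopsied = TRUE,
         pathology_events = pe(d, 8, ben(), concordant = FALSE)))
  add("disc_second_discordant", "exclude", function(d)
    list(birads = "4B", biopsied = TRUE,
         pathology_events = rbind(
           pe(d, 8, ben(), concordant = FALSE),
           pe(d, 8 + sample(30:180, 1), ben(), concordant = FALSE))))

  # --- biopsy-proven concordant benign
  add("benign_concordant", "include", function(d)
    list(birads = sample(c("4A", "4B"), 1), biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), ben())))

  # --- malignant label window boundaries (30 days prior / 120 days after)
  add("mal_visible", "include", function(d)
    list(birads = sample(c("4A", "4B", "4C", "5"), 1), biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal())))
  add("mal_window_boundary_minus30", "include", function(d)
    list(birads = "4C", biopsied = TRUE,
         pathology_events = pe(d, -30, mal())))
  add("mal_window_outside_minus31", "exclude", function(d)
    list(birads = "4C", biopsied = TRUE,
         pathology_events = pe(d, -31, mal())))
  add("mal_window_boundary_plus120", "include", function(d)
    list(birads = "4B", biopsied = TRUE,
         pathology_events = pe(d, 120, mal())))
  add("mal_window_outside_plus121", "exclude", function(d)
    list(birads = "4B", biopsied = TRUE,
         pathology_events = pe(d, 121, mal())))

  # --- cancer visibility filter
  add("mal_low_birads", "exclude", function(d)
    list(birads = sample(c("1", "2"), 1), biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal())))
  add("mal_stereotactic_only", "exclude", function(d)
    list(birads = "4B", biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal(),
                               guidance = "stereotactic")))
  add("mal_mri_only", "exclude", function(d)
    list(birads = "5", biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal(), guidance = "MRI")))
  add("mal_multimodal_review", "manual_review", function(d)
    list(birads = "4B", biopsied = TRUE,
         pathology_events = rbind(
           pe(d, 20, mal()),
           pe(d, 35, mal(), guidance = sample(c("stereotactic", "MRI"), 1)))))
  add("mal_birads0_review", "manual_review", function(d)
    list(birads = "0", biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal())))
  add("mal_birads3_review", "manual_review", function(d)
    list(birads = "3", biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal())))
  add("mal_birads6_review", "manual_review", function(d)
    list(birads = "6", biopsied = TRUE,
         pathology_events = pe(d, sample(0:120, 1), mal())))

  # --- unroutable
  add("birads_unknown", "exclude", function(d)
    list(birads = "unknown", biopsied = FALSE))
  b
}

#' Generate synthetic exam-metadata records spanning all cohort-rule branches
#'
#' Builds `n` records round-robin over a fixed set of branch templates, each
#' covering one path through the eligibility rules (including the inclusive
#' boundary days of every window: -30/+120 days for labels, 4/6/15/24/36
#' months for follow-ups and malignancy bars). Every record carries the
#' generator's intended verdict in `$intended_verdict` and its template name
#' in `$branch`, so the rules engine can be tested against construction-time
#' truth.
#'
#' @param n number of records (>= 1); with `n = 200` every branch appears at
#'   least 5 times.
#' @param seed RNG seed.
#' @return list of [exam_record()] objects with `intended_verdict` and
#'   `branch` fields attached.
#' @export
gen_exam_records <- function(n, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop_field("n", "must be >= 1")
  n <- as.integer(n)
  branches <- record_branches_()
  with_seed_(seed, {
    idx <- rep(seq_along(branches), length.out = n)
    lapply(seq_len(n), function(i) {
      br <- branches[[idx[i]]]
      base <- as.Date("2015-01-01") + sample(0:1460, 1)
      spec <- br$build(base)
      rec <- exam_record(
        exam_id = sprintf("R%05d", i),
        patient_id = sprintf("P%05d", i),
        laterality = sample(c("left", "right"), 1),
        exam_date = base,
        birads = spec$birads,
        biopsied = spec$biopsied,
        pathology_events = spec$pathology_events,
        followups = spec$followups)
      rec$intended_verdict <- br$intended
      rec$branch <- br$name
      rec
    })
  })
}
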