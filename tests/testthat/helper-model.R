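# Shared fixtures for the end-to-end weak-supervision checks. The trained
# model is computed once per test run and reused (training dominates the
# suite's runtime).

.acceptance_cache <- new.env(parent = emptyenv())

acceptance_conditions <- function() {
  prof <- pipeline_profile("tiny")
  cfg <- prof$train
  cfg$epochs <- 15L
  cfg$seed <- 11L
  list(spec = phantom_spec(), model = prof$model, train = cfg,
       n_train = 200, n_heldout = 100, seed_train = 101, seed_heldout = 202)
}

get_acceptance_fit <- function() {
  if (!is.null(.acceptance_cache$fit)) return(.acceptance_cache$fit)
  cond <- acceptance_conditions()
  train <- gen_cohort(cond$spec, cond$n_train, seed = cond$seed_train)
  heldout <- gen_cohort(cond$spec, cond$n_heldout, seed = cond$seed_heldout)
  tm <- train_model(train$exams, heldout$exams, cond$train, cond$model)
  scores <- vapply(heldout$exams, function(e)
    predict_breast(tm, e$images)$y_m, numeric(1))
  .acceptance_cache$fit <- list(tm = tm, heldout = heldout,
                                scores = scores,
                                labels = heldout$truth$y_m)
  .acceptance_cache$fit
}
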