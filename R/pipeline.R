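#' Assemble a full run configuration
#'
#' Bundles the per-stage configurations into one validated, serializable
#' object. The defaults reproduce the study-shaped synthetic run: 65
#' subjects, class-balancing windowing, 36 features + 12-component PCA,
#' the five reference classifiers, the deployed FCN, subject-wise 5-fold
#' cross-validation, and streaming replay on a held-out cohort generated
#' from an independent seed.
#'
#' @param synth A [synthConfig()].
#' @param fcn An [fcnConfig()].
#' @param train A [trainSettings()]. The default here is the reduced
#'   protocol used for synthetic-cohort verification runs (12-epoch cap,
#'   learning rate 1e-3, batch 32, plateau patience 3); pass
#'   `trainSettings()` for the full reference training schedule.
#' @param baselines Character vector of baseline names to run.
#' @param k_folds Number of cross-validation folds.
#' @param k_pca PCA components.
#' @param heldout_subjects Subjects in the independent streaming cohort.
#' @param seed Global seed; stage seeds are derived from it.
#' @param out_dir Optional output directory; when set, window manifests,
#'   feature tables, metrics and the config itself are written there.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(synth = synthConfig(),
                      fcn = fcnConfig(),
                      train = trainSettings(max_epochs = 12L, patience = 11L,
                                            learning_rate = 1e-3,
                                            batch_size = 32L,
                                            scheduler_patience = 3L),
                      baselines = BASELINE_NAMES,
                      k_folds = 5L, k_pca = 12L,
                      heldout_subjects = 5L,
                      seed = 1L, out_dir = NULL) {
  stopifnot(inherits(synth, "SynthConfig"), inherits(fcn, "FcnConfig"),
            inherits(train, "TrainSettings"))
  bad <- setdiff(baselines, BASELINE_NAMES)
  if (length(bad)) stopf("unknown baseline(s): %s", paste(bad, collapse = ", "))
  structure(list(
    synth = synth, fcn = fcn, train = train, baselines = baselines,
    k_folds = as.integer(k_folds), k_pca = as.integer(k_pca),
    heldout_subjects = as.integer(heldout_subjects),
    seed = as.integer(seed), out_dir = out_dir
  ), class = "RunConfig")
}

#' Run the full synthetic pipeline
#'
#' simulate -> filter + window -> features -> baseline cross-validation ->
#' FCN cross-validation -> streaming replay of the median-fold model on a
#' held-out synthetic cohort. Deterministic under the config seed.
#'
#' @param config A [runConfig()].
#' @param verbose Print stage progress.
#' @return A run report list: `window_counts`, `baseline_cv` (per
#'   baseline), `fcn_cv`, `stream_report`, `stream_events`, `elapsed_sec`.
#' @export
runPipeline <- function(config = runConfig(), verbose = TRUE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(rapply(unclass(config), identity, how = "list"),
                     file.path(out_dir, "run_config.yaml"))
  }

  say("simulate: %d subjects", config$synth$n_subjects)
  cohort <- stage("simulate", generateCohort(config$synth))

  say("preprocess: filtering and windowing")
  ws <- stage("preprocess", buildWindowSet(cohort))
  counts <- classCounts(ws)

  say("features: %d windows x 36", ncol(ws))
  feats <- stage("features", featureMatrix(ws))
  y <- windowLabels(ws)
  subj <- windowSubjects(ws)
  folds <- assignFolds(unique(subj), k = config$k_folds,
                       seed = deriveSeed(config$seed, 11L))

  baseline_cv <- list()
  for (b in config$baselines) {
    say("baseline %s: %d-fold CV", b, config$k_folds)
    spec <- baselineSpec(b, seed = deriveSeed(config$seed, 21L))
    baseline_cv[[b]] <- stage(
      paste0("baseline_", b),
      crossValidateBaseline(feats, y, subj, spec, folds, config$k_pca))
  }

  say("fcn: %d-fold subject-wise CV", config$k_folds)
  tr <- config$train
  tr$seed <- deriveSeed(config$seed, 31L)
  fcn_cv <- stage("fcn_cv",
    crossValidateFcn(ws, config$fcn, folds, settings = tr,
                     verbose = verbose))
  say("fcn: median fold %d, accuracy %.3f", fcn_cv$median_fold,
      fcn_cv$median_report$accuracy)

  say("stream: replaying %d held-out subjects", config$heldout_subjects)
  heldout_cfg <- config$synth
  heldout_cfg$n_subjects <- config$heldout_subjects
  heldout_cfg$seed <- deriveSeed(config$seed, 41L)
  heldout <- stage("simulate_heldout", generateCohort(heldout_cfg))
  model <- fcn_cv$models[[fcn_cv$median_fold]]
  events_all <- list()
  truth_all <- list()
  for (r in recordings(heldout)) {
    ev <- replayRecording(r, model, win_len = config$fcn$input_len,
                          fs = config$synth$fs)
    truth <- alignTruth(ev, stimulusEvents(r),
                        win_len = config$fcn$input_len)
    ev$subject_id <- subjectId(r)
    ev$truth <- truth
    events_all[[subjectId(r)]] <- ev
    truth_all[[subjectId(r)]] <- truth
  }
  events <- do.call(rbind, events_all)
  stream_report <- scoreStream(events, painFactor(as.character(events$truth)))
  say("stream: accuracy %.3f over %d events", stream_report$accuracy,
      nrow(events))

  elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  report <- list(
    window_counts = counts,
    n_windows = ncol(ws),
    folds = folds,
    baseline_cv = baseline_cv,
    fcn_cv = fcn_cv[c("fold_accuracy", "median_fold", "mean_accuracy",
                      "sd_accuracy")],
    fcn_median_report = fcn_cv$median_report,
    fcn_models = fcn_cv$models,
    stream_report = stream_report,
    stream_events = events,
    elapsed_sec = elapsed
  )
  if (!is.null(out_dir)) {
    utils::write.csv(
      data.frame(subject_id = names(folds), fold = as.integer(folds)),
      file.path(out_dir, "folds.csv"), row.names = FALSE)
    metr <- data.frame(
      model = c(names(baseline_cv), "FCN"),
      accuracy = c(vapply(baseline_cv, function(x) x$median_report$accuracy,
                          numeric(1)),
                   fcn_cv$median_report$accuracy),
      weighted_f1 = c(vapply(baseline_cv,
                             function(x) x$median_report$weighted_f1,
                             numeric(1)),
                      fcn_cv$median_report$weighted_f1),
      weighted_precision = c(
        vapply(baseline_cv, function(x) x$median_report$weighted_precision,
               numeric(1)),
        fcn_cv$median_report$weighted_precision)
    )
    utils::write.csv(metr, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(events, file.path(out_dir, "stream_events.csv"),
                     row.names = FALSE)
  }
  say("pipeline complete in %.1f s", elapsed)
  report
}
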