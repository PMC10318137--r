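#' End-to-end pipeline configuration
#'
#' Bundles the per-stage configurations. A single top-level `seed`
#' deterministically derives every stage seed via [derive_seed()], so the
#' whole run is reproducible and adding a stage never perturbs earlier
#' stages' randomness.
#'
#' @param seed top-level integer seed.
#' @param cohort list of [cohort_config()] arguments (or a ready config).
#' @param synthesis list of [synthesis_config()] arguments (or a config);
#'   its `n_rows` should be even so the halves match.
#' @param ensemble list: `tune` (logical; default `FALSE`, using
#'   [selected_hyperparameters()]), `folds`, `features`.
#' @param evaluation list: `bootstrap_iterations` (0 disables the
#'   bootstrap comparison), `kfold` (0 disables the overfitting check),
#'   `base_rate` (`NULL`: observed hit fraction), `first_minute` (also
#'   featurize the first-minute window).
#' @param out_dir optional directory; when set, every artifact (cohort
#'   CSVs, feature tables, synthetic table, report JSON) is written there.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = list(), synthesis = list(),
                            ensemble = list(), evaluation = list(),
                            out_dir = NULL) {
  if (!inherits(cohort, "cohort_config")) {
    cohort$seed <- cohort$seed %||% derive_seed(seed, "cohort")
    cohort <- do.call(cohort_config, cohort)
  }
  if (!inherits(synthesis, "synthesis_config")) {
    synthesis$seed <- synthesis$seed %||% derive_seed(seed, "synthesis")
    synthesis <- do.call(synthesis_config, synthesis)
  }
  ensemble <- utils::modifyList(
    list(tune = FALSE, folds = 5L, features = c("avg_immersion", "retreat")),
    ensemble)
  evaluation <- utils::modifyList(
    list(bootstrap_iterations = 0L, bootstrap_train_n = NULL,
         bootstrap_test_n = NULL, kfold = 0L, base_rate = NULL,
         first_minute = TRUE, min_participants = 2L),
    evaluation)
  structure(list(seed = as.integer(seed), cohort = cohort,
                 synthesis = synthesis, ensemble = ensemble,
                 evaluation = evaluation, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full neuroforecasting pipeline
#'
#' simulate (or load) -> featurize (full window, optionally first minute)
#' -> synthesize -> split in half -> train the ensemble -> evaluate:
#' confusion metrics and exact binomial tests on the synthetic test half
#' and on the observed song table, optional bootstrap comparison against
#' the logistic baseline, and optional k-fold overfitting check. Rerunning
#' with the same configuration reproduces every number.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort (list of tables); when `NULL`
#'   one is simulated from `config$cohort`.
#' @return a `run_report` list with a section per stage.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- c()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  if (is.null(cohort)) {
    cohort <- run_stage("synthetic_cohort", simulate_cohort(config$cohort))
  }
  tick("simulate")

  ev <- config$evaluation
  feats <- run_stage("features", featurize(
    cohort$traces, cohort$surveys, cohort$songs, window = "full",
    min_participants = ev$min_participants))
  feats_1min <- if (isTRUE(ev$first_minute)) {
    run_stage("features", featurize(
      cohort$traces, cohort$surveys, cohort$songs, window = "first_minute",
      min_participants = ev$min_participants))
  }
  tick("featurize")

  synth <- run_stage("augmentation",
                     synthesize_table(feats, config$synthesis))
  halves <- run_stage("augmentation",
                      split_half(synth, derive_seed(config$seed, "split")))
  fidelity <- validate_synthesis(feats[, config$synthesis$visit_order,
                                       with = FALSE], synth)
  tick("synthesize")

  en <- config$ensemble
  model <- run_stage("ensemble", fit_ensemble(
    halves$train, features = en$features, tune = isTRUE(en$tune),
    folds = en$folds, seed = derive_seed(config$seed, "ensemble")))
  tick("train")

  base_rate <- ev$base_rate %||% mean(normalize_label(feats$label) == "hit")
  test_truth <- normalize_label(halves$test$label)
  test_pred <- predict(model, halves$test, type = "class")
  test_conf <- confusion_metrics(test_truth, test_pred)
  test_binom <- exact_binomial_test(sum(test_pred == test_truth),
                                    length(test_truth), base_rate)
  obs_pred <- predict(model, feats, type = "class")
  obs_conf <- confusion_metrics(feats$label, obs_pred)
  obs_binom <- exact_binomial_test(sum(obs_pred == normalize_label(feats$label)),
                                   nrow(feats), base_rate)
  baseline <- run_stage("evaluation", logistic_baseline(feats, "model2"))
  baseline_synth <- run_stage("evaluation",
                              logistic_baseline(halves$train, "model2"))
  baseline_test_pred <- predict(baseline_synth, halves$test, type = "class")
  baseline_test_conf <- confusion_metrics(test_truth, baseline_test_pred)

  boot <- NULL
  if (ev$bootstrap_iterations >= 2L) {
    n_tr <- ev$bootstrap_train_n %||% nrow(halves$train)
    n_te <- ev$bootstrap_test_n %||% nrow(halves$test)
    boot <- run_stage("evaluation", bootstrap_compare(
      function(tr) logistic_baseline(tr, "model2"),
      function(tr) fit_ensemble(tr, features = en$features, tune = FALSE,
                                folds = en$folds,
                                seed = derive_seed(config$seed, "boot_fit")),
      synth, iterations = ev$bootstrap_iterations, train_n = n_tr,
      test_n = n_te, seed = derive_seed(config$seed, "bootstrap")))
  }
  kfold <- NULL
  if (ev$kfold >= 2L) {
    kfold <- run_stage("evaluation", kfold_overfit_check(
      function(tr) fit_ensemble(tr, features = en$features, tune = FALSE,
                                folds = en$folds,
                                seed = derive_seed(config$seed, "kfold_fit")),
      halves$train, feats, k = ev$kfold,
      seed = derive_seed(config$seed, "kfold")))
  }
  tick("evaluate")

  report <- structure(list(
    package_version = as.character(utils::packageVersion("neuroforecast")),
    config = config,
    timings_sec = timings,
    features = feats,
    features_first_minute = feats_1min,
    feature_digest = table_digest(feats),
    fidelity = fidelity,
    ensemble = list(beta = model$beta, cv_risk = model$cv_risk,
                    ensemble_risk = model$ensemble_risk,
                    hypers = model$hypers),
    evaluation = list(
      base_rate = base_rate,
      synthetic_test = test_conf, synthetic_test_binomial = test_binom,
      observed = obs_conf, observed_binomial = obs_binom,
      logistic_baseline = baseline,
      logistic_synthetic_test = baseline_test_conf,
      bootstrap = boot, kfold = kfold)),
    class = "run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort_tables(cohort, config$out_dir)
    data.table::fwrite(feats, file.path(config$out_dir, "features.csv"))
    if (!is.null(feats_1min)) {
      data.table::fwrite(feats_1min,
                         file.path(config$out_dir, "features_first_minute.csv"))
    }
    data.table::fwrite(synth, file.path(config$out_dir, "synthetic.csv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

# flatten a run_report into JSON-friendly primitives
report_to_json <- function(report) {
  conf_list <- function(cm) {
    if (is.null(cm)) return(NULL)
    list(accuracy = cm$accuracy, sensitivity = cm$sensitivity,
         specificity = cm$specificity, counts = as.list(cm$counts))
  }
  binom_list <- function(bt) {
    if (is.null(bt)) return(NULL)
    list(successes = bt$successes, n = bt$n, p0 = bt$p0,
         p_value = bt$p_value)
  }
  ev <- report$evaluation
  boot <- if (!is.null(ev$bootstrap)) {
    lapply(ev$bootstrap$comparison, function(r) {
      list(mean_logistic = r$mean_a, mean_ensemble = r$mean_b,
           ci_logistic = r$ci_a, ci_ensemble = r$ci_b,
           t = r$t, df = r$df, p_value = r$p_value)
    })
  }
  kf <- if (!is.null(ev$kfold)) {
    list(means = as.list(ev$kfold$means), sds = as.list(ev$kfold$sds),
         consistent = ev$kfold$consistent)
  }
  list(
    package_version = report$package_version,
    seed = report$config$seed,
    timings_sec = as.list(report$timings_sec),
    feature_digest = report$feature_digest,
    fidelity_pass = report$fidelity$pass,
    ensemble = list(beta = as.list(report$ensemble$beta),
                    cv_risk = as.list(report$ensemble$cv_risk),
                    ensemble_risk = report$ensemble$ensemble_risk),
    evaluation = list(
      base_rate = ev$base_rate,
      synthetic_test = conf_list(ev$synthetic_test),
      synthetic_test_binomial = binom_list(ev$synthetic_test_binomial),
      observed = conf_list(ev$observed),
      observed_binomial = binom_list(ev$observed_binomial),
      logistic_baseline = list(
        accuracy = ev$logistic_baseline$confusion$accuracy,
        sensitivity = ev$logistic_baseline$confusion$sensitivity,
        specificity = ev$logistic_baseline$confusion$specificity,
        lr_chisq = ev$logistic_baseline$lr_chisq,
        lr_p = ev$logistic_baseline$lr_p,
        vif = as.list(ev$logistic_baseline$vif)),
      logistic_synthetic_test = conf_list(ev$logistic_synthetic_test),
      bootstrap = boot,
      kfold = kf))
}

#' @export
print.run_report <- function(x, ...) {
  ev <- x$evaluation
  cat("<run_report> seed", x$config$seed, "\n")
  cat(sprintf("  %d songs featurized; synthesis fidelity pass: %s\n",
              nrow(x$features), x$fidelity$pass))
  cat("  ensemble beta:", paste(sprintf("%s=%.3f", names(x$ensemble$beta),
                                        x$ensemble$beta), collapse = " "), "\n")
  cat(sprintf("  synthetic test accuracy %.3f (binomial p = %.3g vs base %.3f)\n",
              ev$synthetic_test$accuracy, ev$synthetic_test_binomial$p_value,
              ev$base_rate))
  cat(sprintf("  observed accuracy %.3f; logistic baseline %.3f\n",
              ev$observed$accuracy, ev$logistic_baseline$confusion$accuracy))
  invisible(x)
}
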