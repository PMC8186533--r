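#' Assemble a run configuration
#'
#' A flat list of every knob needed for one reproducible end-to-end run.
#' The seed is mandatory: there is no silent nondeterminism. Unknown keys
#' are rejected by name.
#'
#' @param seed master integer seed (required).
#' @param n_per_group subjects per group.
#' @param effect_preset `"default"` (planted contrasts) or `"null"`.
#' @param n_subtests,n_items roster dimensions (default 5 x 5).
#' @param min_points segmentation threshold.
#' @param n_hidden hidden-layer size.
#' @param learning_rate,epochs training settings.
#' @param k,repetitions cross-validation settings.
#' @param split_mode,scope see [cross_validate()].
#' @param ablation run the backward-elimination stage?
#' @param out_dir output directory for artifacts.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, n_per_group = 30, effect_preset = "default",
                       n_subtests = 5, n_items = 5, min_points = 2,
                       n_hidden = 5, learning_rate = 0.01, epochs = 500,
                       k = 10, repetitions = 5, split_mode = "sample",
                       scope = "global", ablation = TRUE, out_dir = ".") {
  if (missing(seed) || is.null(seed)) tk_stop("touchkin_config_error", "seed is required")
  if (!effect_preset %in% c("default", "null")) {
    tk_stop("touchkin_config_error", "unknown effect preset '%s'", effect_preset)
  }
  cfg <- list(seed = as.integer(seed), n_per_group = n_per_group,
              effect_preset = effect_preset, n_subtests = n_subtests,
              n_items = n_items, min_points = min_points, n_hidden = n_hidden,
              learning_rate = learning_rate, epochs = epochs, k = k,
              repetitions = repetitions, split_mode = split_mode, scope = scope,
              ablation = as.logical(ablation), out_dir = out_dir)
  structure(cfg, class = "run_config")
}

config_roster <- function(cfg) {
  roster <- list()
  for (s in seq_len(cfg$n_subtests)) for (i in seq_len(cfg$n_items)) {
    roster[[length(roster) + 1L]] <- task_spec(s, i)
  }
  roster
}

#' Run the full pipeline and write its artifacts
#'
#' Simulates a cohort, segments and featurizes it, fits the scaler, runs
#' repeated k-fold cross-validation, optionally runs backward ablation on
#' the best fold-model's held-out data, and writes every artifact plus a
#' manifest with the config hash, the seed, per-stage counts and MD5
#' checksums of each file. Re-running with an identical config reproduces
#' identical checksums.
#'
#' Artifacts (all plain text): `touch_log.csv`, `feature_table.csv`,
#' `scaler.txt`, `cv_metrics.json`, `roc.csv`, `training_trace.csv`,
#' `ablation.csv` (if enabled), `manifest.json`.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress progress messages.
#' @return the manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  if (!inherits(cfg, "run_config")) tk_stop("touchkin_config_error", "cfg must be a run_config")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(cfg$out_dir, 2) != 0) {
    tk_stop("touchkin_io_error", "output directory not writable: %s", cfg$out_dir)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  path <- function(f) file.path(cfg$out_dir, f)

  say("simulating cohort (%d + %d subjects, %d tasks, preset '%s')",
      cfg$n_per_group, cfg$n_per_group, cfg$n_subtests * cfg$n_items, cfg$effect_preset)
  log <- generate_cohort(cfg$n_per_group, cfg$effect_preset, config_roster(cfg),
                         seed = derive_seed(cfg$seed, "cohort"))
  write_touch_log(log, path("touch_log.csv"))
  say("  %d touch samples in %d streams", nrow(log),
      nrow(unique(log[, c("subject_id", "subtest_id", "item_id")])))

  trajs <- segment_touch_log(log, cfg$min_points)
  disc <- attr(trajs, "discard")
  say("  %d finite trajectories (%d short episodes with %d samples discarded)",
      length(trajs), disc$episodes, disc$samples)

  table <- featurize_cohort(log, cfg$min_points)
  write_feature_table(table, path("feature_table.csv"))
  say("  feature table: %d rows x %d input features", nrow(table), length(feature_columns()))

  scaler <- standardize(table, "fit")$params
  write_scaler(scaler, path("scaler.txt"))

  say("cross-validating (%d-fold x %d repetitions, H = %d, %d epochs)",
      cfg$k, cfg$repetitions, cfg$n_hidden, cfg$epochs)
  cv <- cross_validate(table, k = cfg$k, repetitions = cfg$repetitions,
                       n_hidden = cfg$n_hidden,
                       cfg = train_config(cfg$learning_rate, cfg$epochs,
                                          seed = derive_seed(cfg$seed, "train")),
                       split_mode = cfg$split_mode, scope = cfg$scope,
                       seed = derive_seed(cfg$seed, "cv"))
  say("  mean CV accuracy %.3f +/- %.3f", cv$mean_accuracy, cv$sd_accuracy)

  jsonlite::write_json(list(
    mean_accuracy = cv$mean_accuracy, sd_accuracy = cv$sd_accuracy,
    sd_accuracy_folds = cv$sd_accuracy_folds,
    best = list(repetition = cv$best$repetition, fold = cv$best$fold,
                accuracy = cv$best$metrics$accuracy,
                sensitivity = cv$best$metrics$sensitivity,
                specificity = cv$best$metrics$specificity,
                auc = cv$best$metrics$auc),
    folds = cv$folds
  ), path("cv_metrics.json"), auto_unbox = TRUE, digits = NA, dataframe = "columns")
  data.table::fwrite(cv$best$metrics$roc, path("roc.csv"))
  data.table::fwrite(cv$epoch_trace, path("training_trace.csv"))

  artifacts <- c("touch_log.csv", "feature_table.csv", "scaler.txt",
                 "cv_metrics.json", "roc.csv", "training_trace.csv")
  if (cfg$ablation) {
    say("backward input ablation on the best fold-model's held-out fold")
    curve <- backward_elimination(cv$best$model, cv$best$test_table)
    write_ablation_curve(curve, path("ablation.csv"))
    artifacts <- c(artifacts, "ablation.csv")
  }

  manifest <- list(
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    counts = list(touch_samples = nrow(log), streams = 2 * cfg$n_per_group *
                    cfg$n_subtests * cfg$n_items,
                  trajectories = length(trajs),
                  discarded_episodes = disc$episodes,
                  discarded_samples = disc$samples,
                  feature_rows = nrow(table)),
    artifacts = as.list(tools::md5sum(vapply(artifacts, path, "")))
  )
  names(manifest$artifacts) <- artifacts
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE, digits = NA)
  say("manifest written: %s", path("manifest.json"))
  invisible(manifest)
}

# Stable hash of the run configuration (output directory excluded: it does
# not affect results).
config_hash <- function(cfg) {
  c2 <- unclass(cfg)
  c2$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(c2), vapply(c2, function(v) format(v, digits = 17), ""),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Load a run configuration from a key-value file
#'
#' @param path config file path in the [read_config()] dialect; keys match
#'   [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  kv <- read_config(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(kv), known)
  if (length(unknown)) {
    tk_stop("touchkin_config_error", "unknown config key(s): %s",
            paste(unknown, collapse = ", "))
  }
  do.call(run_config, kv)
}
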