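#' Repeated k-fold cross-validation of the network
#'
#' Replicates the study protocol: the dataset is split at random into `k`
#' near-equal folds; each fold in turn is held out for testing while the
#' network is trained on the rest; the whole resampling is repeated
#' `repetitions` times with fresh splits and fresh weight initializations.
#'
#' Two split modes exist. `"sample"` (default, the protocol as stated)
#' randomizes over samples, so one subject's 25 tasks may span folds —
#' this leaks subject identity between train and test and is kept because
#' it is the stated protocol. `"subject"` assigns whole subjects to folds,
#' which is the leakage-safe alternative.
#'
#' Standardization scope: `"global"` (default, the stated order) fits the
#' scaler on the whole table before splitting; `"per_fold"` fits it on each
#' training split only and applies it to the held-out fold.
#'
#' @param table a raw (unstandardized) `feature_table`.
#' @param k number of folds (default 10).
#' @param repetitions number of repeats (default 5).
#' @param n_hidden hidden-layer size (default 5).
#' @param cfg a [train_config()]; its seed is combined with fold/repetition
#'   indices via [derive_seed()].
#' @param split_mode `"sample"` or `"subject"`.
#' @param scope `"global"` or `"per_fold"` standardization.
#' @param seed master seed for fold assignment and weight initialization.
#' @return a `cv_result` list:
#'   `folds` — `data.table` with one row per fold-model (`repetition`,
#'   `fold`, `test_n`, `accuracy`, `sensitivity`, `specificity`, `auc`);
#'   `mean_accuracy`, `sd_accuracy` — over per-repetition average
#'   accuracies; `sd_accuracy_folds` — over all k x repetitions folds;
#'   `best` — the best fold-model (highest test accuracy, ties to the
#'   earlier fold): trained `mlp_model` plus its held-out table and metrics;
#'   `epoch_trace` — mean training accuracy per epoch across fold-models;
#'   `assignments` — fold id per sample per repetition.
#' @export
cross_validate <- function(table, k = 10L, repetitions = 5L, n_hidden = 5L,
                           cfg = train_config(), split_mode = c("sample", "subject"),
                           scope = c("global", "per_fold"), seed = 1L) {
  split_mode <- match.arg(split_mode)
  scope <- match.arg(scope)
  n <- nrow(table)
  if (k > n) tk_stop("touchkin_config_error", "k = %d exceeds n = %d", k, n)

  global <- if (scope == "global") standardize(table, "fit") else NULL

  fold_rows <- list()
  traces <- list()
  best <- NULL
  assignments <- matrix(NA_integer_, n, repetitions)
  rep_means <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    set.seed(derive_seed(seed, "folds", r))
    fold_id <- make_folds(table, k, split_mode)
    assignments[, r] <- fold_id
    accs <- numeric(k)
    for (f in seq_len(k)) {
      test_idx <- which(fold_id == f)
      train_tab <- table[-test_idx]
      test_tab <- table[test_idx]
      if (scope == "global") {
        sc <- global$params
        train_std <- standardize(train_tab, sc)$table
        test_std <- standardize(test_tab, sc)$table
      } else {
        fit <- standardize(train_tab, "fit")
        sc <- fit$params
        train_std <- fit$table
        test_std <- standardize(test_tab, sc)$table
      }
      model <- build_model(mlp_spec(n_hidden = n_hidden),
                           seed = derive_seed(cfg$seed, "init", r, f))
      model <- train(model, train_std, cfg)
      model$scaler <- sc
      met <- evaluate(model, test_std)
      accs[f] <- met$accuracy
      fold_rows[[length(fold_rows) + 1L]] <- data.table::data.table(
        repetition = r, fold = f, test_n = length(test_idx),
        accuracy = met$accuracy, sensitivity = met$sensitivity,
        specificity = met$specificity, auc = met$auc
      )
      traces[[length(traces) + 1L]] <- model$trace$accuracy
      if (is.null(best) || met$accuracy > best$metrics$accuracy) {
        best <- list(model = model, metrics = met, repetition = r, fold = f,
                     test_table = test_std, test_index = test_idx)
      }
    }
    rep_means[r] <- mean(accs)
  }
  folds <- data.table::rbindlist(fold_rows)
  structure(list(
    folds = folds,
    mean_accuracy = mean(rep_means),
    sd_accuracy = if (repetitions > 1) sample_sd(rep_means) else NA_real_,
    sd_accuracy_folds = sample_sd(folds$accuracy),
    repetition_means = rep_means,
    best = best,
    epoch_trace = data.table::data.table(
      epoch = seq_len(cfg$epochs),
      accuracy = Reduce(`+`, traces) / length(traces)
    ),
    assignments = assignments,
    k = k, repetitions = repetitions, split_mode = split_mode, scope = scope
  ), class = "cv_result")
}

# Fold assignment: near-equal sizes (differ by <= 1). In subject mode whole
# subjects are assigned to folds instead of individual samples.
make_folds <- function(table, k, split_mode) {
  n <- nrow(table)
  if (split_mode == "sample") {
    fold_id <- rep(seq_len(k), length.out = n)[sample.int(n)]
  } else {
    subj <- unique(table$subject_id)
    sf <- rep(seq_len(k), length.out = length(subj))[sample.int(length(subj))]
    fold_id <- sf[match(table$subject_id, subj)]
  }
  fold_id
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV x %d repetitions (%s split, %s standardization)\n",
              x$k, x$repetitions, x$split_mode, x$scope))
  cat(sprintf("mean accuracy %.3f +/- %.3f (SD over repetitions; %.3f over %d folds)\n",
              x$mean_accuracy, x$sd_accuracy, x$sd_accuracy_folds, nrow(x$folds)))
  cat(sprintf("best fold-model: repetition %d fold %d, accuracy %.3f\n",
              x$best$repetition, x$best$fold, x$best$metrics$accuracy))
  invisible(x)
}

#' Descending grid search over hidden-layer sizes
#'
#' Evaluates each candidate hidden-layer size by cross-validation and, to
#' keep the model as simple as possible, returns the smallest candidate
#' whose mean CV accuracy is within `tolerance` of the best candidate's.
#'
#' @param table raw `feature_table`.
#' @param candidates hidden-layer sizes, conventionally descending from 10.
#' @param tolerance accuracy slack counted as "comparable" (default 0.01,
#'   i.e. one percentage point).
#' @param ... passed to [cross_validate()] (`k`, `repetitions`, `cfg`,
#'   `seed`, ...).
#' @return list with `selected` (the chosen size), `accuracies`
#'   (`data.table` of `n_hidden`, `mean_accuracy`, `sd_accuracy`), and
#'   `results` (the full `cv_result` per candidate).
#' @export
grid_search_hidden <- function(table, candidates = 10:2, tolerance = 0.01, ...) {
  if (length(candidates) == 0) tk_stop("touchkin_config_error", "no candidate sizes")
  results <- lapply(candidates, function(h) cross_validate(table, n_hidden = h, ...))
  acc <- data.table::data.table(
    n_hidden = as.integer(candidates),
    mean_accuracy = vapply(results, `[[`, 0, "mean_accuracy"),
    sd_accuracy = vapply(results, `[[`, 0, "sd_accuracy")
  )
  list(selected = select_smallest_within(acc$n_hidden, acc$mean_accuracy, tolerance),
       accuracies = acc, results = setNames(results, paste0("H", candidates)))
}

# Parsimony rule shared with tests: smallest size within tolerance of the
# best mean accuracy.
select_smallest_within <- function(sizes, accuracies, tolerance) {
  ok <- accuracies >= max(accuracies) - tolerance
  min(sizes[ok])
}
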