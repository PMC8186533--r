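test_that("model construction follows the stated architecture", {
  m <- build_model(mlp_spec(17, 5, 2), seed = 1)
  expect_identical(n_parameters(m), 17L * 5L + 5L + 5L * 2L + 2L)
  # Xavier uniform limits
  l1 <- sqrt(6 / (17 + 5))
  expect_true(all(abs(m$W1) <= l1))
  expect_true(all(m$b1 == 0) && all(m$b2 == 0))
  expect_identical(build_model(mlp_spec(17, 5, 2), seed = 1)$W1, m$W1)
  expect_false(identical(build_model(mlp_spec(17, 5, 2), seed = 2)$W1, m$W1))

  X <- matrix(rnorm(17 * 8), 8, 17)
  fw <- mlp_forward(m, X)
  expect_equal(rowSums(fw$probs), rep(1, 8), tolerance = 1e-12)
  expect_true(all(fw$hidden >= -1 & fw$hidden <= 1))
  expect_error(mlp_spec(0, 5, 2), class = "touchkin_config_error")
})

test_that("training separates well-separated blobs and is deterministic", {
  tab <- toy_feature_table(n = 100, seed = 3)
  # push the labeled groups >= 6 SD apart on two columns
  tab$MeanSpeed <- tab$MeanSpeed + ifelse(tab$label == "ASD", 6, -6)
  tab$DC <- tab$DC + ifelse(tab$label == "ASD", 6, -6)
  std <- standardize(tab, "fit")$table
  cfg <- train_config(0.01, 500, seed = 1)
  m1 <- train(build_model(mlp_spec(), seed = 1), std, cfg)
  expect_equal(evaluate(m1, std)$accuracy, 1.0)
  expect_identical(nrow(m1$trace), 500L)
  expect_lt(m1$trace$loss[500], m1$trace$loss[1])

  m2 <- train(build_model(mlp_spec(), seed = 1), std, cfg)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
})

test_that("metrics, ROC and AUC behave as defined", {
  # perfect predictions
  truth <- rep(c("ASD", "TD"), each = 10)
  perfect <- compute_metrics(truth, ifelse(truth == "ASD", 0.9, 0.1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)

  # constant "ASD" predictor on a balanced set
  const <- compute_metrics(truth, rep(0.9, 20))
  expect_equal(const$accuracy, 0.5)
  expect_equal(const$sensitivity, 1)
  expect_equal(const$specificity, 0)

  # confusion arithmetic: [[13,2],[1,14]] -> acc 27/30
  truth2 <- c(rep("ASD", 15), rep("TD", 15))
  scores2 <- c(rep(0.9, 13), rep(0.1, 2), rep(0.9, 1), rep(0.1, 14))
  met <- compute_metrics(truth2, scores2)
  expect_identical(unname(met$confusion), matrix(c(13L, 1L, 2L, 14L), 2))
  expect_equal(met$accuracy, 27 / 30)
  expect_equal(met$sensitivity, 13 / 15)
  expect_equal(met$specificity, 14 / 15)
  expect_identical(sum(met$confusion), 30L)

  # ROC endpoints and monotonicity on arbitrary scores
  set.seed(11)
  r <- compute_metrics(sample(c("ASD", "TD"), 50, TRUE), runif(50))$roc
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[nrow(r)], r$tpr[nrow(r)]), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))

  expect_error(compute_metrics(c("ASD", "other"), c(0.1, 0.2)),
               class = "touchkin_label_error")
})

test_that("cross-validation bookkeeping is exact", {
  tab <- toy_feature_table(n = 60, seed = 8)
  tab$MeanSpeed <- tab$MeanSpeed + ifelse(tab$label == "ASD", 4, -4)
  cv <- cross_validate(tab, k = 5, repetitions = 2, n_hidden = 3,
                       cfg = train_config(0.01, 40, seed = 2), seed = 9)
  expect_identical(nrow(cv$folds), 10L)
  for (r in 1:2) {
    fid <- cv$assignments[, r]
    expect_identical(sort(unique(fid)), 1:5)
    expect_true(max(table(fid)) - min(table(fid)) <= 1)
    # each sample tested exactly once per repetition
    expect_identical(length(fid), 60L)
  }
  expect_identical(nrow(cv$epoch_trace), 40L)
  expect_equal(cv$mean_accuracy, mean(cv$repetition_means))
  best_acc <- max(cv$folds$accuracy)
  expect_equal(cv$best$metrics$accuracy, best_acc)
  # tie-break: first fold-model in scan order achieving the max
  first <- which(cv$folds$accuracy == best_acc)[1]
  expect_identical(cv$best$repetition, cv$folds$repetition[first])
  expect_identical(cv$best$fold, cv$folds$fold[first])
  expect_error(cross_validate(tab, k = 100), class = "touchkin_config_error")
})

test_that("subject-grouped splitting keeps subjects within one fold", {
  tab <- small_cohort_table(seed = 17, n_per_group = 5)
  cv <- cross_validate(tab, k = 5, repetitions = 1, n_hidden = 2,
                       cfg = train_config(0.01, 10, seed = 1),
                       split_mode = "subject", seed = 3)
  fid <- cv$assignments[, 1]
  per_subj <- tapply(fid, tab$subject_id, function(v) length(unique(v)))
  expect_true(all(per_subj == 1))
})

test_that("grid search applies the parsimony rule", {
  # exact ties -> smallest candidate
  expect_identical(touchkin:::select_smallest_within(c(10, 7, 4), c(0.9, 0.9, 0.9), 0.01), 4)
  # within-tolerance runner-up wins over a marginally better large model
  expect_identical(touchkin:::select_smallest_within(c(10, 5, 2), c(0.95, 0.945, 0.8), 0.01), 5)
  expect_identical(touchkin:::select_smallest_within(c(8), c(0.7), 0.01), 8)

  tab <- toy_feature_table(n = 60, seed = 12)
  tab$STH <- tab$STH + ifelse(tab$label == "ASD", 4, -4)
  gs <- grid_search_hidden(tab, candidates = c(4, 2), tolerance = 0.01,
                           k = 5, repetitions = 1,
                           cfg = train_config(0.01, 40, seed = 2), seed = 5)
  expect_identical(nrow(gs$accuracies), 2L)
  expect_gte(gs$accuracies[n_hidden == gs$selected, mean_accuracy],
             max(gs$accuracies$mean_accuracy) - 0.01)
  expect_error(grid_search_hidden(tab, candidates = integer(0)),
               class = "touchkin_config_error")
})

test_that("non-finite loss raises a named divergence error", {
  tab <- toy_feature_table(n = 30, seed = 2)
  std <- standardize(tab, "fit")$table
  m <- build_model(mlp_spec(), 1)
  m$W1[1, 1] <- NaN
  expect_error(train(m, std, train_config(epochs = 5, seed = 1)),
               class = "touchkin_divergence_error")
})
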