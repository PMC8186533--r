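#' Evaluate a trained model with some kinematic inputs masked
#'
#' "Removing an input neuron" without retraining is implemented by fixing
#' the masked standardized inputs to 0 — their expected value after
#' standardization — which is weight-equivalent to severing the neuron's
#' contribution at its mean. Subtest indicators may never be masked: the
#' task identity is always provided to the network.
#'
#' @param model trained `mlp_model`.
#' @param table `feature_table` standardized with the model's scaler.
#' @param masked character vector of kinematic feature names (possibly
#'   empty).
#' @return a `tk_metrics` object.
#' @export
masked_metrics <- function(model, table, masked = character(0)) {
  bad <- setdiff(masked, kinematic_feature_names())
  if (length(bad)) {
    tk_stop("touchkin_mask_error",
            "cannot mask non-kinematic input(s): %s", paste(bad, collapse = ", "))
  }
  tab <- data.table::copy(table)
  for (f in masked) data.table::set(tab, j = f, value = 0)
  evaluate(model, tab)
}

#' Greedy backward input ablation
#'
#' Starting from all 12 kinematic inputs, each round masks every remaining
#' feature in turn, identifies the one whose removal hurts accuracy least
#' (ties broken by higher resulting sensitivity, then by fixed column
#' order), removes it permanently, and records accuracy, sensitivity and
#' specificity. Twelve rounds exhaust the kinematic inputs; the subtest
#' indicators are always left in place. The model is never retrained.
#'
#' @param model trained `mlp_model`.
#' @param table standardized evaluation `feature_table` (by default the
#'   best CV model's held-out fold; a whole-dataset table is valid for
#'   diagnostics).
#' @return an `ablation_curve`: `data.table` with one row per retained
#'   count 12 down to 1 (`retained`, `removed_feature` — the feature whose
#'   removal produced that row, `NA` for the full model —, `accuracy`,
#'   `sensitivity`, `specificity`), with attributes `removal_order` (all 12
#'   features in removal order), `masks` (the mask used at each recorded
#'   row) and `all_masked` (metrics with every kinematic input masked).
#' @export
backward_elimination <- function(model, table) {
  feats <- kinematic_feature_names()
  full <- masked_metrics(model, table, character(0))
  rows <- list(data.table::data.table(
    retained = 12L, removed_feature = NA_character_,
    accuracy = full$accuracy, sensitivity = full$sensitivity,
    specificity = full$specificity
  ))
  masks <- list(character(0))
  removed <- character(0)
  remaining <- feats
  while (length(remaining) > 1) {
    cand_acc <- cand_sen <- numeric(length(remaining))
    for (i in seq_along(remaining)) {
      met <- masked_metrics(model, table, c(removed, remaining[i]))
      cand_acc[i] <- met$accuracy
      cand_sen[i] <- met$sensitivity
    }
    # least-impact feature: highest accuracy after removal, then highest
    # sensitivity, then first in fixed column order
    best <- order(-cand_acc, -cand_sen, seq_along(remaining))[1]
    pick <- remaining[best]
    removed <- c(removed, pick)
    remaining <- setdiff(remaining, pick)
    met <- masked_metrics(model, table, removed)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      retained = length(remaining), removed_feature = pick,
      accuracy = met$accuracy, sensitivity = met$sensitivity,
      specificity = met$specificity
    )
    masks[[length(masks) + 1L]] <- removed
  }
  removal_order <- c(removed, remaining) # the last feature standing is removed last
  curve <- data.table::rbindlist(rows)
  data.table::setattr(curve, "removal_order", removal_order)
  data.table::setattr(curve, "masks", masks)
  data.table::setattr(curve, "all_masked", masked_metrics(model, table, feats))
  data.table::setattr(curve, "class", c("ablation_curve", class(curve)))
  curve[]
}

#' Write an ablation curve as CSV
#'
#' Emits `retained, removed_feature, accuracy, sensitivity, specificity`,
#' one row per retained-feature count from 12 to 1.
#'
#' @param curve an `ablation_curve`.
#' @param path CSV path.
#' @export
write_ablation_curve <- function(curve, path) {
  data.table::fwrite(curve, path)
  invisible(path)
}
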