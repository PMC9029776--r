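# End-to-end benchmark runner: generate a synthetic split, select models
# under both scoring modes, and evaluate them in and out of distribution.

#' Re-select the winner of a finished grid search under another scoring mode
#'
#' Reuses the stored cross-validation results (the expensive part), so both
#' selection modes can be compared on identical folds and fits.
#'
#' @param outcome A [grid_search()] result.
#' @param scoring_mode `"validation"` or `"gap_penalized"`.
#' @param grid The configuration list used for the original search.
#' @param x,y The training data for refitting the new winner.
#' @return A `selection_outcome` for the requested mode.
#' @export
reselect <- function(outcome, scoring_mode = c("validation", "gap_penalized"),
                     grid, x, y) {
  scoring_mode <- match.arg(scoring_mode)
  scores <- if (scoring_mode == "validation") {
    outcome$table$score_validation
  } else {
    outcome$table$score_gap_penalized
  }
  best <- select_best(scores, grid)
  model <- if (best == outcome$best_index) outcome$model else
    fit_final(grid[[best]], x, y)
  structure(
    list(scoring_mode = scoring_mode, best_index = best,
         best_config = grid[[best]], best_score = scores[best],
         table = outcome$table, cv = outcome$cv, model = model),
    class = "selection_outcome"
  )
}

#' Run the full selection benchmark on one synthetic split
#'
#' Generates an analogue-series library, assigns noisy gated labels, builds
#' a scaffold-held-out split, grid-searches the requested algorithm under
#' 5-fold cross-validation, selects one model by validation MCC and one by
#' the gap-penalized score (identical folds and fits), and evaluates both on
#' the iid and the out-of-distribution test sets.
#'
#' @param seed Integer seed controlling every random draw.
#' @param spec A [library_spec()]; its `seed` is replaced by `seed`.
#' @param algorithm `"random_forest"` or `"svm"`.
#' @param feature_set,fp_bits Feature settings for the model matrix.
#' @param grid Optional configuration list; defaults to the reduced grid.
#' @param k Number of cross-validation folds.
#' @return A list: `split`, `outcomes` (per mode), and `metrics` — a
#'   data.frame with one row per scoring mode holding cross-validation,
#'   iid, and OOD MCCs plus the winning regularization hyperparameter
#'   (`min_samples_leaf` or `cost`).
#' @export
run_selection_benchmark <- function(seed,
                                    spec = library_spec(),
                                    algorithm = c("random_forest", "svm"),
                                    feature_set = "pc+fp", fp_bits = 512,
                                    grid = NULL, k = 5) {
  algorithm <- match.arg(algorithm)
  spec$seed <- as.integer(seed)
  lib <- assign_labels(generate_library(spec))
  split <- shift_split(lib)
  x_train <- build_feature_matrix(split$train, feature_set, fp_bits = fp_bits)
  x_iid <- build_feature_matrix(split$iid_test, feature_set, fp_bits = fp_bits)
  x_ood <- build_feature_matrix(split$ood_test, feature_set, fp_bits = fp_bits)
  y_train <- split$train$label
  folds <- stratified_folds(y_train, k = k, seed = derive_seed(seed, "folds"))
  if (is.null(grid)) {
    grid <- default_grid(algorithm, feature_set = feature_set,
                         seed = derive_seed(seed, "fit"), reduced = TRUE)
  }
  base <- grid_search(grid, x_train, y_train, folds,
                      scoring_mode = "validation")
  outcomes <- list(
    validation = base,
    gap_penalized = reselect(base, "gap_penalized", grid, x_train, y_train)
  )
  metrics <- do.call(rbind, lapply(names(outcomes), function(mode) {
    oc <- outcomes[[mode]]
    hp <- oc$best_config$hyperparameters
    data.frame(
      mode = mode,
      cv_score = oc$best_score,
      cv_val_mcc = oc$table$score_validation[oc$best_index],
      iid_mcc = mcc_labels(predict(oc$model, x_iid)$label,
                           split$iid_test$label),
      ood_mcc = mcc_labels(predict(oc$model, x_ood)$label,
                           split$ood_test$label),
      regularization = if (algorithm == "random_forest") {
        as.numeric(hp$min_samples_leaf)
      } else {
        as.numeric(hp$cost)
      },
      stringsAsFactors = FALSE
    )
  }))
  list(split = split, outcomes = outcomes, metrics = metrics,
       algorithm = algorithm)
}
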