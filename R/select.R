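# Hyperparameter selection: grid search under k-fold cross-validation, scored
# by mean validation MCC or by the gap-penalized score that subtracts the mean
# train-validation gap.

.label_levels <- c("non_activator", "activator")

#' Matthews correlation coefficient from confusion-matrix counts
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' conventional value 0 whenever a factor of the denominator is zero
#' (e.g. a constant classifier).
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return A value in `[-1, 1]`.
#' @export
mcc <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# MCC of predicted vs true labels with "activator" as the positive class.
mcc_labels <- function(pred, truth) {
  mcc(sum(pred == "activator" & truth == "activator"),
      sum(pred == "activator" & truth == "non_activator"),
      sum(pred == "non_activator" & truth == "activator"),
      sum(pred == "non_activator" & truth == "non_activator"))
}

#' Stratified fold assignment for cross-validation
#'
#' Partitions records into `k` folds, stratified by class so every fold's
#' class ratio is within one record of the global ratio. Reproducible for a
#' fixed seed; the caller's RNG state is untouched.
#'
#' @param labels Character vector of class labels.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return A `fold_assignment` list with elements `k`, `fold` (fold index per
#'   record), `seed`.
#' @export
stratified_folds <- function(labels, k = 5, seed = 1) {
  tab <- table(labels)
  if (any(tab < k)) {
    stopf("class '%s' has fewer than k = %d members",
          names(tab)[which.min(tab)], k)
  }
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  structure(list(k = as.integer(k), fold = fold, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Construct a model configuration
#'
#' @param algorithm `"random_forest"` or `"svm"`.
#' @param hyperparameters Named list. Random forest: `num_trees`,
#'   `max_features` (`"sqrt"` or a fraction), `min_samples_split`,
#'   `min_samples_leaf`, `max_depth` (0 = unlimited). SVM: `kernel`
#'   (`"radial"`), `cost`, `gamma` (`"scale"` or a positive number).
#' @param feature_set Feature set the configuration is meant for
#'   (`"pc"`, `"fp"`, `"pc+fp"`); informational.
#' @param seed Integer seed used when fitting.
#' @return A `model_config` object.
#' @export
model_config <- function(algorithm = c("random_forest", "svm"),
                         hyperparameters = list(), feature_set = "pc",
                         seed = 1) {
  algorithm <- match.arg(algorithm)
  hp <- hyperparameters
  if (algorithm == "random_forest") {
    hp$num_trees <- hp$num_trees %||% 500
    hp$max_features <- hp$max_features %||% "sqrt"
    hp$min_samples_split <- hp$min_samples_split %||% 2
    hp$min_samples_leaf <- hp$min_samples_leaf %||% 1
    hp$max_depth <- hp$max_depth %||% 0
    stopifnot(hp$num_trees >= 1, hp$min_samples_leaf >= 1,
              hp$min_samples_split >= 2, hp$max_depth >= 0)
  } else {
    hp$kernel <- hp$kernel %||% "radial"
    hp$cost <- hp$cost %||% 1
    hp$gamma <- hp$gamma %||% "scale"
    stopifnot(hp$cost > 0)
  }
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 feature_set = feature_set, seed = as.integer(seed)),
            class = "model_config")
}

#' Default hyperparameter grids
#'
#' The full grids bracket the contrasts this workflow is designed to expose:
#' shallow-to-deep random forests (leaf sizes 1 to 256, depths 4 to
#' unlimited) and soft-to-hard-margin SVMs (C over four orders of magnitude).
#' `reduced = TRUE` gives a small regularization-spanning grid suitable for
#' repeated benchmark runs.
#'
#' @param algorithm `"random_forest"` or `"svm"`.
#' @param feature_set Feature set recorded in each configuration.
#' @param seed Seed recorded in each configuration.
#' @param reduced Use the reduced grid.
#' @return List of [model_config()] objects.
#' @export
default_grid <- function(algorithm = c("random_forest", "svm"),
                         feature_set = "pc", seed = 1, reduced = FALSE) {
  algorithm <- match.arg(algorithm)
  if (algorithm == "random_forest") {
    g <- if (reduced) {
      # a regularization ladder from deep/noise-fitting to coarse/robust;
      # split and leaf sizes rise together so heavily regularized forests
      # still find admissible splits on imbalanced fingerprint bits
      data.frame(num_trees = 100, max_features = "0.3",
                 min_samples_split = c(2, 8, 32, 128),
                 min_samples_leaf = c(1, 4, 8, 16),
                 max_depth = 0, stringsAsFactors = FALSE)
    } else {
      expand.grid(num_trees = c(100, 500), max_features = c("sqrt", "0.3"),
                  min_samples_split = c(2, 8, 32, 128),
                  min_samples_leaf = c(1, 4, 16, 64, 256),
                  max_depth = c(0, 4, 8, 16), stringsAsFactors = FALSE)
    }
    lapply(seq_len(nrow(g)), function(i) {
      model_config("random_forest", as.list(g[i, ]), feature_set, seed)
    })
  } else {
    g <- if (reduced) {
      expand.grid(cost = c(0.1, 1, 10, 100), gamma = "scale",
                  stringsAsFactors = FALSE)
    } else {
      expand.grid(cost = c(0.01, 0.1, 1, 10, 100),
                  gamma = c("scale", "0.001", "0.01", "0.1"),
                  stringsAsFactors = FALSE)
    }
    lapply(seq_len(nrow(g)), function(i) {
      gm <- g$gamma[i]
      model_config("svm",
                   list(kernel = "radial", cost = g$cost[i],
                        gamma = if (gm == "scale") "scale" else as.numeric(gm)),
                   feature_set, seed)
    })
  }
}

# ---- model fitting ---------------------------------------------------------

fit_model <- function(config, x, y, seed = NULL) {
  stopifnot(inherits(config, "model_config"))
  y <- factor(as.character(y), levels = .label_levels)
  if (any(is.na(y))) stopf("labels outside {activator, non_activator}")
  if (length(unique(y)) < 2) stopf("training data contains a single class")
  x <- unclass(x)
  seed <- seed %||% config$seed
  hp <- config$hyperparameters
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%05d", seq_len(p))
  if (config$algorithm == "random_forest") {
    mtry <- if (identical(hp$max_features, "sqrt")) {
      max(1L, floor(sqrt(p)))
    } else {
      max(1L, floor(as.numeric(hp$max_features) * p))
    }
    fit <- ranger::ranger(
      x = x, y = y, num.trees = hp$num_trees, mtry = mtry,
      min.node.size = hp$min_samples_split, min.bucket = hp$min_samples_leaf,
      max.depth = hp$max_depth, probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1
    )
    scaling <- NULL
    # record per-leaf training occupancy for complexity diagnostics
    tn <- predict(fit, data = x, type = "terminalNodes",
                  num.threads = 1)$predictions
    leaf_counts <- lapply(seq_len(ncol(tn)), function(j) {
      tb <- table(tn[, j])
      stats::setNames(as.integer(tb), names(tb))
    })
  } else {
    center <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0 | is.na(scl)] <- 1
    xs <- scale(x, center = center, scale = scl)
    gamma <- if (identical(hp$gamma, "scale")) {
      v <- mean(apply(xs, 2, var))
      if (!is.finite(v) || v <= 0) v <- 1
      1 / (p * v)
    } else {
      as.numeric(hp$gamma)
    }
    fit <- with_seed(seed, e1071::svm(
      x = xs, y = y, kernel = "radial", cost = hp$cost, gamma = gamma,
      probability = TRUE, scale = FALSE
    ))
    scaling <- list(center = center, scale = scl)
    leaf_counts <- NULL
  }
  structure(list(algorithm = config$algorithm, config = config, fit = fit,
                 scaling = scaling, n_features = p,
                 feature_names = colnames(x), leaf_counts = leaf_counts),
            class = "pxr_model")
}

#' Predict activity labels and ranking scores
#'
#' @param object A fitted `pxr_model`.
#' @param newdata Feature matrix with the same columns the model was
#'   trained on; a mismatch in feature count is an error, never a silent
#'   truncation.
#' @param ... Unused.
#' @return Data.frame with `score` (probability of the activator class, in
#'   `[0, 1]`) and `label` (`"activator"` iff `score >= 0.5`).
#' @export
predict.pxr_model <- function(object, newdata, ...) {
  newdata <- unclass(newdata)
  if (ncol(newdata) != object$n_features) {
    stopf("feature count mismatch: model expects %d, got %d",
          object$n_features, ncol(newdata))
  }
  colnames(newdata) <- object$feature_names
  if (object$algorithm == "random_forest") {
    pr <- predict(object$fit, data = newdata, num.threads = 1)$predictions
    score <- pr[, "activator"]
  } else {
    xs <- scale(newdata, center = object$scaling$center,
                scale = object$scaling$scale)
    pv <- predict(object$fit, xs, probability = TRUE)
    score <- attr(pv, "probabilities")[, "activator"]
  }
  data.frame(
    score = unname(score),
    label = ifelse(score >= 0.5, "activator", "non_activator"),
    stringsAsFactors = FALSE
  )
}

#' Cross-validate one configuration
#'
#' For each fold, the model is fitted on the remaining k-1 folds and scored by
#' MCC both on those training folds and on the held-out fold. Any per-fold
#' preprocessing (feature standardization for the SVM) is learned on the
#' training folds only.
#'
#' @param config A [model_config()].
#' @param x Feature matrix.
#' @param y Label vector.
#' @param folds A [stratified_folds()] assignment.
#' @return A `cv_result` data.frame with columns `fold`, `mcc_train`,
#'   `mcc_val`.
#' @export
cross_validate <- function(config, x, y, folds) {
  stopifnot(inherits(folds, "fold_assignment"), nrow(x) == length(y),
            length(folds$fold) == length(y))
  res <- data.frame(fold = seq_len(folds$k), mcc_train = NA_real_,
                    mcc_val = NA_real_)
  for (i in seq_len(folds$k)) {
    tr <- folds$fold != i
    fit <- fit_model(config, x[tr, , drop = FALSE], y[tr],
                     seed = derive_seed(config$seed, paste0("fold", i)))
    pred_tr <- predict(fit, x[tr, , drop = FALSE])$label
    pred_va <- predict(fit, x[!tr, , drop = FALSE])$label
    res$mcc_train[i] <- mcc_labels(pred_tr, y[tr])
    res$mcc_val[i] <- mcc_labels(pred_va, y[!tr])
  }
  structure(res, class = c("cv_result", "data.frame"))
}

#' Mean validation MCC across folds
#' @param cv A `cv_result`.
#' @return Mean of the per-fold validation MCCs.
#' @export
score_validation <- function(cv) mean(cv$mcc_val)

#' Gap-penalized cross-validation score
#'
#' Mean validation MCC minus the mean (train - validation) MCC gap:
#' `(1/k) sum(mcc_val_i) - (1/k) sum(mcc_train_i - mcc_val_i)`. The gap term
#' is signed, so a model whose validation score exceeds its training score is
#' rewarded; algebraically the score equals `(1/k) sum(2*mcc_val_i -
#' mcc_train_i)`.
#'
#' @param cv A `cv_result`.
#' @return The gap-penalized score.
#' @export
score_gap_penalized <- function(cv) {
  mean(cv$mcc_val) - mean(cv$mcc_train - cv$mcc_val)
}

# Deterministic winner selection on a score table: highest score, then lowest
# model complexity (largest min_samples_leaf for forests, smallest C for
# SVMs), then grid order.
select_best <- function(scores, configs) {
  reg <- vapply(configs, function(cfg) {
    if (cfg$algorithm == "random_forest") {
      -as.numeric(cfg$hyperparameters$min_samples_leaf)
    } else {
      as.numeric(cfg$hyperparameters$cost)
    }
  }, numeric(1))
  order(-scores, reg, seq_along(configs))[1]
}

#' Grid search with shared cross-validation folds
#'
#' Evaluates every configuration once with the same fold assignment, stores
#' both the validation score and the gap-penalized score for each, selects
#' the winner for the requested scoring mode (ties broken toward the less
#' complex model, then grid order), and refits it on the full training data.
#'
#' @param grid List of [model_config()] objects (non-empty).
#' @param x Feature matrix for the training set.
#' @param y Labels.
#' @param folds A [stratified_folds()] assignment shared by all
#'   configurations.
#' @param scoring_mode `"validation"` (mean validation MCC) or
#'   `"gap_penalized"`.
#' @return A `selection_outcome` list: `scoring_mode`, `best_index`,
#'   `best_config`, `best_score`, `table` (per-config hyperparameters and both
#'   scores), `cv` (per-config `cv_result`s), and `model` (the refitted
#'   winner).
#' @export
grid_search <- function(grid, x, y, folds,
                        scoring_mode = c("validation", "gap_penalized")) {
  scoring_mode <- match.arg(scoring_mode)
  if (length(grid) == 0) stopf("empty hyperparameter grid")
  cvs <- lapply(grid, cross_validate, x = x, y = y, folds = folds)
  sv <- vapply(cvs, score_validation, numeric(1))
  sg <- vapply(cvs, score_gap_penalized, numeric(1))
  tab <- do.call(rbind, lapply(seq_along(grid), function(i) {
    cfg <- grid[[i]]
    hp <- cfg$hyperparameters
    data.frame(
      config = i, algorithm = cfg$algorithm,
      hyperparameters = paste(names(hp), unlist(lapply(hp, as.character)),
                              sep = "=", collapse = ","),
      mean_mcc_train = mean(cvs[[i]]$mcc_train),
      score_validation = sv[i], score_gap_penalized = sg[i],
      stringsAsFactors = FALSE
    )
  }))
  scores <- if (scoring_mode == "validation") sv else sg
  best <- select_best(scores, grid)
  model <- fit_final(grid[[best]], x, y)
  structure(
    list(scoring_mode = scoring_mode, best_index = best,
         best_config = grid[[best]], best_score = scores[best], table = tab,
         cv = cvs, model = model),
    class = "selection_outcome"
  )
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat(sprintf("<selection_outcome> mode=%s, %d configs, best #%d (score %.4f)\n",
              x$scoring_mode, nrow(x$table), x$best_index, x$best_score))
  cat("  best:", x$table$hyperparameters[x$best_index], "\n")
  invisible(x)
}

#' Fit the final model on the full training set
#'
#' @param config A [model_config()].
#' @param x Feature matrix (ideally a [build_feature_matrix()] result so the
#'   feature manifest travels with the model).
#' @param y Labels; both classes must be present.
#' @return A `pxr_model` with the feature manifest attached.
#' @export
fit_final <- function(config, x, y) {
  model <- fit_model(config, x, y)
  model$manifest <- if (inherits(x, "feature_matrix")) feature_manifest(x) else
    list(feature_set = config$feature_set, fp_radius = NA, fp_bits = NA,
         n_features = ncol(x))
  model
}
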