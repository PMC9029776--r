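test_that("mcc matches its closed form on worked confusion matrices", {
  expect_equal(mcc(5, 0, 0, 5), 1)
  expect_equal(mcc(0, 5, 5, 0), -1)
  expect_equal(mcc(3, 1, 2, 4), 10 / sqrt(600))
  expect_equal(mcc(0, 0, 0, 10), 0) # constant classifier convention
})

test_that("mcc agrees with a brute-force correlation oracle on all small tables", {
  for (tp in 0:5) for (fp in 0:5) for (fn in 0:5) for (tn in 0:5) {
    expect_equal(mcc(tp, fp, fn, tn), mcc_oracle(tp, fp, fn, tn),
                 tolerance = 1e-12)
  }
})

test_that("mcc is class-swap invariant and negates under label inversion", {
  withr::with_seed(3, {
    for (i in 1:50) {
      cm <- sample(0:20, 4, replace = TRUE)
      expect_equal(mcc(cm[1], cm[2], cm[3], cm[4]),
                   mcc(cm[4], cm[3], cm[2], cm[1]))
      expect_equal(mcc(cm[1], cm[2], cm[3], cm[4]),
                   -mcc(cm[3], cm[4], cm[1], cm[2]))
    }
  })
})

test_that("stratified folds partition records and balance classes", {
  labels <- c(rep("activator", 202), rep("non_activator", 739))
  f <- stratified_folds(labels, k = 5, seed = 42)
  expect_equal(sort(unique(f$fold)), 1:5)
  expect_length(f$fold, 941)
  per_fold_act <- tapply(labels == "activator", f$fold, sum)
  expect_true(all(per_fold_act %in% c(40, 41)))
  expect_equal(stratified_folds(labels, k = 5, seed = 42)$fold, f$fold)
  expect_false(identical(stratified_folds(labels, k = 5, seed = 43)$fold,
                         f$fold))
  expect_error(stratified_folds(c("activator", rep("non_activator", 10)),
                                k = 5), "fewer than")
})

test_that("the two scoring rules reproduce hand-computed examples", {
  cv <- structure(data.frame(fold = 1:2, mcc_train = c(0.9, 0.7),
                             mcc_val = c(0.5, 0.3)),
                  class = c("cv_result", "data.frame"))
  expect_equal(score_validation(cv), 0.4)
  expect_equal(score_gap_penalized(cv), 0.0)

  cv2 <- structure(data.frame(fold = 1:2, mcc_train = c(0.2, 0.6),
                              mcc_val = c(0.2, 0.6)),
                   class = c("cv_result", "data.frame"))
  expect_equal(score_validation(cv2), 0.4)
  expect_equal(score_gap_penalized(cv2), score_validation(cv2))

  # the gap term is signed: validation above training is rewarded
  cv3 <- structure(data.frame(fold = 1, mcc_train = 0.4, mcc_val = 0.5),
                   class = c("cv_result", "data.frame"))
  expect_equal(score_gap_penalized(cv3), 0.6)
})

test_that("the gap score satisfies its algebraic identity and ordering", {
  withr::with_seed(99, {
    for (i in 1:1000) {
      cv <- random_cv(sample(2:8, 1))
      expect_equal(score_gap_penalized(cv),
                   mean(2 * cv$mcc_val - cv$mcc_train), tolerance = 1e-12)
      if (mean(cv$mcc_train) >= mean(cv$mcc_val)) {
        expect_lte(score_gap_penalized(cv), score_validation(cv) + 1e-12)
      }
    }
  })
})

test_that("selection modes can disagree exactly as in the two-config example", {
  cfg_x <- model_config("random_forest", list(min_samples_leaf = 1))
  cfg_y <- model_config("random_forest", list(min_samples_leaf = 64))
  sv <- c(0.50, 0.45)          # validation scores of X and Y
  sg <- c(0.50 - 0.40, 0.45 - 0.05) # gap-penalized scores
  expect_equal(pxrgap:::select_best(sv, list(cfg_x, cfg_y)), 1)
  expect_equal(pxrgap:::select_best(sg, list(cfg_x, cfg_y)), 2)
  # ties break toward the less complex model
  expect_equal(pxrgap:::select_best(c(0.4, 0.4), list(cfg_x, cfg_y)), 2)
})

make_separable <- function(n = 60) {
  withr::with_seed(5, {
    y <- rep(c("activator", "non_activator"), each = n / 2)
    x <- cbind(sig = ifelse(y == "activator", 1, -1) * runif(n, 1, 2),
               noise = rnorm(n))
  })
  list(x = x, y = y)
}

test_that("cross-validation memorizes separable data and records both scores", {
  d <- make_separable()
  folds <- stratified_folds(d$y, k = 3, seed = 1)
  cfg <- model_config("random_forest",
                      list(num_trees = 50, min_samples_leaf = 1), seed = 2)
  cv <- cross_validate(cfg, d$x, d$y, folds)
  expect_equal(nrow(cv), 3)
  expect_true(all(cv$mcc_train == 1))
  expect_true(all(cv$mcc_val == 1))
  expect_true(all(cv$mcc_val >= -1 & cv$mcc_val <= 1))
})

test_that("fitted models return bounded scores and reject column mismatches", {
  d <- make_separable()
  for (alg in c("random_forest", "svm")) {
    cfg <- model_config(alg, seed = 3)
    m <- fit_final(cfg, d$x, d$y)
    pr <- predict(m, d$x)
    expect_true(all(pr$score >= 0 & pr$score <= 1))
    expect_equal(pr$label, ifelse(pr$score >= 0.5, "activator",
                                  "non_activator"))
    expect_error(predict(m, d$x[, 1, drop = FALSE]), "mismatch")
    # refit with the same seed is deterministic
    expect_equal(predict(fit_final(cfg, d$x, d$y), d$x), pr)
  }
  expect_error(fit_final(model_config("svm"), d$x,
                         rep("activator", nrow(d$x))), "single class")
})

test_that("an interpolating model reaches training MCC 1", {
  d <- make_separable()
  m <- fit_final(model_config("random_forest",
                              list(num_trees = 100, min_samples_leaf = 1),
                              seed = 4),
                 d$x, d$y)
  expect_equal(pxrgap:::mcc_labels(predict(m, d$x)$label, d$y), 1)
})

test_that("grid search is reproducible, exhaustive, and tracks both scores", {
  d <- make_separable()
  folds <- stratified_folds(d$y, k = 3, seed = 6)
  grid <- default_grid("svm", reduced = TRUE, seed = 7)
  out <- grid_search(grid, d$x, d$y, folds, "validation")
  expect_equal(nrow(out$table), length(grid))
  expect_true(all(c("score_validation", "score_gap_penalized") %in%
                    names(out$table)))
  expect_equal(out$best_score, max(out$table$score_validation))
  out2 <- grid_search(grid, d$x, d$y, folds, "validation")
  expect_equal(out$table, out2$table)
  expect_equal(out$best_index, out2$best_index)

  single <- grid_search(grid[2], d$x, d$y, folds)
  expect_equal(single$best_index, 1)
  expect_error(grid_search(list(), d$x, d$y, folds), "empty")

  resel <- reselect(out, "gap_penalized", grid, d$x, d$y)
  expect_equal(resel$best_score,
               max(out$table$score_gap_penalized))
})
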