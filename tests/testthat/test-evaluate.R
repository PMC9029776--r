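test_that("maximum-similarity profiles find exact and partial matches", {
  train <- fp_mat(list(c(1, 2, 3), c(7, 8)))
  test <- fp_mat(list(c(2, 3, 4), c(1, 2, 3)))
  prof <- max_similarity_profile(test, train)
  expect_equal(prof, c(0.5, 1.0))
  expect_equal(max_similarity_profile(test, train[2:1, , drop = FALSE]), prof)
  expect_error(max_similarity_profile(test, train[0, , drop = FALSE]),
               "empty")
})

test_that("stratified MCC has ten nested rows and matches the overall score at t=1", {
  withr::with_seed(21, {
    truth <- sample(c("activator", "non_activator"), 120, replace = TRUE)
    pred <- ifelse(runif(120) < 0.8, truth,
                   ifelse(truth == "activator", "non_activator", "activator"))
    prof <- runif(120)
  })
  sp <- stratified_mcc(pred, truth, prof)
  expect_equal(nrow(sp), 10)
  expect_equal(sp$threshold, seq(0.1, 1, 0.1))
  expect_true(all(diff(sp$n) >= 0))
  expect_equal(sp$n[10], 120)
  expect_equal(sp$mcc[10], pxrgap:::mcc_labels(pred, truth))
})

test_that("all-dissimilar profiles make every stratum identical, degenerate strata are NA", {
  truth <- rep(c("activator", "non_activator"), 10)
  pred <- truth
  sp <- stratified_mcc(pred, truth, rep(0.05, 20))
  expect_true(all(sp$n == 20))
  expect_true(all(sp$mcc == 1))

  sp2 <- stratified_mcc(pred, truth, c(rep(0.05, 2), rep(0.95, 18)))
  expect_true(all(sp2$n[1:8] == 2))
  # the low strata hold one record of each class here, so MCC is defined;
  # shift both low records to one class to force NA
  truth3 <- c("activator", "activator", truth[3:20])
  sp3 <- stratified_mcc(pred, truth3, c(rep(0.05, 2), rep(0.95, 18)))
  expect_true(all(is.na(sp3$mcc[1:8])))
  expect_false(is.na(sp3$mcc[10]))
})

test_that("coverage curves are exact on containment and disjointness", {
  ref <- fp_mat(list(c(1, 2), c(3, 4), c(5, 6)))
  cov <- coverage_fraction(ref, ref)
  expect_true(all(cov$fraction == 1))
  far <- fp_mat(list(c(9, 10), c(11, 12), c(13, 14)))
  cov2 <- coverage_fraction(ref, far, thresholds = c(0.5, 1.0))
  expect_equal(cov2$fraction[cov2$threshold == 1.0], 0)
})

test_that("coverage is non-increasing in threshold on random fingerprint sets", {
  withr::with_seed(77, {
    for (i in 1:100) {
      ref <- matrix(rbinom(6 * 32, 1, 0.25), nrow = 6)
      qry <- matrix(rbinom(5 * 32, 1, 0.25), nrow = 5)
      cov <- coverage_fraction(ref, qry)
      expect_true(all(diff(cov$fraction) <= 1e-12))
    }
  })
})

test_that("Murcko frameworks prune side chains and fix rings", {
  benzene <- murcko_scaffold("c1ccccc1")
  expect_equal(murcko_scaffold("Cc1ccccc1"), benzene)   # toluene
  expect_equal(murcko_scaffold(benzene), benzene)       # fixed point
  expect_equal(murcko_scaffold("CCCCCC"), "")           # acyclic
  # idempotence across varied ring systems
  smis <- c("O=C(Nc1ccccc1)c1ccc2ccccc2c1", "O=C1CCCCC1",
            "c1ccc(-c2ccccn2)cc1", "CC(=O)Oc1ccccc1C(=O)O")
  sc <- murcko_scaffold(smis)
  expect_equal(murcko_scaffold(sc[sc != ""]), sc[sc != ""])
})

test_that("carbonyls attached to a framework survive scaffold pruning", {
  ring_ketone <- murcko_scaffold("O=C1CCCCC1")
  expect_true(grepl("O", ring_ketone))
  # benzaldehyde's exocyclic CHO is a side chain and is removed
  expect_equal(murcko_scaffold("O=Cc1ccccc1"), murcko_scaffold("c1ccccc1"))
})

test_that("scaffold reports count overlap and molecules per scaffold", {
  # ten molecules spread over four ring systems (4 + 3 + 2 + 1)
  ds <- data.frame(
    id = 1:10,
    smiles_std = c("Cc1ccccc1", "CCc1ccccc1", "Cc1ccccc1C", "Oc1ccccc1",
                   "Cc1ccc2ccccc2c1", "CCc1ccc2ccccc2c1", "Oc1ccc2ccccc2c1",
                   "Cc1ccccn1", "CCc1ccccn1",
                   "Cc1ccc2ncccc2c1")
  )
  rep1 <- scaffold_report(ds)
  expect_equal(rep1$n_molecules, 10)
  expect_equal(rep1$n_scaffolds, 4)
  expect_equal(rep1$molecules_per_scaffold, 2.5)

  rep2 <- scaffold_report(ds, reference = ds)
  expect_equal(rep2$pct_overlap, 100)
})

test_that("acyclic molecules share one reserved empty-scaffold key", {
  ds <- data.frame(id = 1:3,
                   smiles_std = c("CCCCCCCCCCCC", "CCCCOCCCC", "c1ccccc1"))
  rep1 <- scaffold_report(ds)
  expect_equal(rep1$n_scaffolds, 2)
  expect_true("" %in% rep1$scaffolds)
})

test_that("forest complexity reports heights and occupancy-weighted leaves", {
  d <- withr::with_seed(9, {
    y <- rep(c("activator", "non_activator"), each = 40)
    x <- cbind(a = rnorm(80, ifelse(y == "activator", 1, -1)), b = rnorm(80))
    list(x = x, y = y)
  })
  deep <- fit_final(model_config("random_forest",
                                 list(num_trees = 20, min_samples_leaf = 1),
                                 seed = 1), d$x, d$y)
  cs <- rf_complexity(deep)
  expect_true(all(cs$heights >= 0))
  expect_equal(sum(cs$leaf_weights), 1, tolerance = 1e-9)
  # every tree routes all 80 training molecules to its leaves
  expect_true(all(cs$per_tree_totals == 80))

  # min.bucket = n forces single-leaf trees: height 0, selection probability 1
  stump <- fit_final(model_config("random_forest",
                                  list(num_trees = 10, min_samples_leaf = 80),
                                  seed = 1), d$x, d$y)
  cs2 <- rf_complexity(stump)
  expect_true(all(cs2$heights == 0))
  expect_equal(cs2$median_leaf_occupancy, 80)
  expect_true(cs$median_height > cs2$median_height)
})

test_that("importance audits count used features and rank planted signal first", {
  d <- withr::with_seed(13, {
    y <- rep(c("activator", "non_activator"), each = 50)
    sig <- ifelse(y == "activator", 1, -1)
    x <- cbind(matrix(rnorm(100 * 17), ncol = 17),
               s1 = sig + rnorm(100, sd = 0.1),
               s2 = -sig + rnorm(100, sd = 0.1),
               s3 = sig * 2 + rnorm(100, sd = 0.1))
    colnames(x)[1:17] <- paste0("n", 1:17)
    list(x = x, y = y)
  })
  m <- fit_final(model_config("random_forest",
                              list(num_trees = 100, min_samples_leaf = 2),
                              seed = 2), d$x, d$y)
  aud <- importance_audit(m)
  expect_lte(aud$n_positive, aud$total)
  expect_equal(sum(aud$table$importance), 1, tolerance = 1e-9)
  expect_setequal(aud$table$feature[1:3], c("s1", "s2", "s3"))

  sv <- fit_final(model_config("svm", seed = 2), d$x, d$y)
  expect_error(importance_audit(sv), "unsupported")
})
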