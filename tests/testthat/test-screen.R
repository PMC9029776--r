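# The screening tests share one small trained model and library.
screen_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      split <- bench_split()
      xt <- build_feature_matrix(split$train, "pc+fp", fp_bits = 256)
      m_rf <- fit_final(model_config("random_forest",
                                     list(num_trees = 50,
                                          min_samples_leaf = 4),
                                     feature_set = "pc+fp", seed = 1),
                        xt, split$train$label)
      m_svm <- fit_final(model_config("svm", feature_set = "pc+fp", seed = 1),
                         xt, split$train$label)
      lib <- as.data.frame(split$ood_test)
      cache <<- list(split = split, xt = xt, rf = m_rf, svm = m_svm,
                     lib = lib)
    }
    cache
  }
})

test_that("library ranking is a descending permutation with stable ties", {
  fx <- screen_fixture()
  feats <- build_feature_matrix(fx$lib, "pc+fp", fp_bits = 256)
  ranked <- rank_library(fx$rf, feats, fx$lib$id)
  expect_setequal(ranked$id, fx$lib$id)
  expect_equal(ranked$rank, seq_len(nrow(ranked)))
  expect_true(all(diff(ranked$score) <= 1e-12))
  ties <- ranked[duplicated(ranked$score) |
                   duplicated(ranked$score, fromLast = TRUE), ]
  if (nrow(ties) > 1) {
    for (s in unique(ties$score)) {
      ids <- ties$id[ties$score == s]
      expect_equal(ids, sort(ids))
    }
  }
})

test_that("chunked and single-pass ranking agree on a 1000-compound library", {
  spec <- library_spec(n_scaffolds = 20, analogues_per_scaffold = 50,
                       seed = 31)
  lib <- generate_library(spec)
  feats <- build_feature_matrix(
    data.frame(smiles_std = lib$smiles), "pc")
  fx <- screen_fixture()
  m <- fit_final(model_config("random_forest",
                              list(num_trees = 30, min_samples_leaf = 4),
                              feature_set = "pc", seed = 5),
                 build_feature_matrix(fx$split$train, "pc"),
                 fx$split$train$label)
  single <- rank_library(m, feats, lib$id, chunk_size = nrow(feats))
  chunked <- rank_library(m, feats, lib$id, chunk_size = 37)
  expect_equal(single, chunked)
})

test_that("consensus keeps only unanimous activator calls", {
  votes <- rbind(rep("activator", 6),
                 c(rep("activator", 5), "non_activator"),
                 rep("non_activator", 6))
  rownames(votes) <- c("a", "b", "c")
  expect_equal(consensus_filter(votes), "a")
  expect_equal(consensus_filter(votes[0, , drop = FALSE]), character(0))
  votes[2, 3] <- NA
  expect_error(consensus_filter(votes), "missing")
})

test_that("nearest neighbors are exact for shared structures and consistent with profiles", {
  fx <- screen_fixture()
  train <- fx$split$train
  cands <- rbind(
    data.frame(id = "known", smiles_std = train$smiles_std[5]),
    data.frame(id = "other", smiles_std = fx$lib$smiles_std[1])
  )
  nn <- nearest_neighbor_report(cands, train, n_bits = 512)
  expect_equal(nn$nn_similarity[1], 1)
  expect_equal(nn$nn_id[1], train$id[5])

  cfp <- fingerprint_matrix(cands$smiles_std, radius = 2, n_bits = 512)
  tfp <- fingerprint_matrix(train$smiles_std, radius = 2, n_bits = 512)
  expect_equal(nn$nn_similarity, max_similarity_profile(cfp, tfp))
})

test_that("end-to-end screening votes, flags consensus, and skips failures", {
  fx <- screen_fixture()
  lib <- rbind(fx$lib[1:30, c("id", "smiles_std")],
               data.frame(id = "broken", smiles_std = "qq$7"))
  lib <- data.frame(id = lib$id, smiles = lib$smiles_std)
  models <- list(rf1 = fx$rf, svm1 = fx$svm)
  res <- screen_library(lib, models, fx$split$train, guiding = "rf1",
                        sim_bits = 512)
  expect_equal(attr(res, "skipped")$id, "broken")
  expect_setequal(res$id, lib$id[lib$id != "broken"])
  # consensus implies every individual vote is active
  if (any(res$consensus)) {
    expect_true(all(res$vote_rf1[res$consensus] == "activator"))
    expect_true(all(res$vote_svm1[res$consensus] == "activator"))
  }
  expect_equal(res$consensus,
               res$vote_rf1 == "activator" & res$vote_svm1 == "activator")
  expect_equal(res$novel, res$nn_similarity < 0.7)
  expect_true(all(res$nn_similarity >= 0 & res$nn_similarity <= 1))
})
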