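test_that("standardization strips salts and keeps single parents unchanged", {
  std <- standardize_smiles(c("CCO.Cl", "CCO"))
  expect_true(all(std$ok))
  expect_equal(std$smiles_std[1], std$smiles_std[2])
  expect_equal(std$inchi[1], "InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3")
})

test_that("tautomer pairs collapse to one canonical parent", {
  std <- standardize_smiles(c("Oc1ccccn1", "O=c1cccc[nH]1"))
  expect_true(all(std$ok))
  expect_equal(std$smiles_std[1], std$smiles_std[2])
  expect_equal(std$inchi[1], std$inchi[2])
})

test_that("standardization is deterministic and order-independent", {
  smis <- c(clean_smiles, "CCO.Cl", "Oc1ccccn1")
  a <- standardize_smiles(smis)
  b <- standardize_smiles(rev(smis))
  expect_equal(a$inchi, rev(b$inchi))
  expect_equal(a$smiles_std, rev(b$smiles_std))
  expect_equal(standardize_smiles(smis), a)
})

test_that("unparseable SMILES are rejected with a diagnostic, not a crash", {
  std <- standardize_smiles(c("CCO", "qq$7", "C1CC"))
  expect_equal(std$ok, c(TRUE, FALSE, FALSE))
  expect_true(all(!is.na(std$diagnostic[!std$ok])))
})

test_that("ToxCast hit-call merging follows the two-assay rule", {
  expect_equal(toxcast_label(1, 1), "activator")
  expect_equal(toxcast_label(0, 0), "non_activator")
  expect_equal(toxcast_label(1, 0), "inconclusive")
  expect_equal(toxcast_label(0, 1), "inconclusive")
  expect_true(is.na(toxcast_label(NA, 1)))
})

test_that("weight and element filters fire in order on standardized records", {
  std <- standardize_smiles(
    c("CCO",                              # 46 Da
      "CCCC[Sn](CCCC)CCCC",               # tin, 291 Da
      "CCCCCCCCCCCCCCCCCC(=O)NCCO")      # ~327 Da, C/H/N/O
  )
  expect_lt(std$mw[1], 200)
  flt <- apply_filters(std)
  expect_equal(flt$steps$n_removed, c(1, 1))
  expect_equal(nrow(flt$kept), 1)
  expect_equal(flt$kept$id, "3")
})

test_that("duplicate groups keep one concordant instance and drop discordant ones", {
  recs <- data.frame(
    id = c("a", "b", "c", "d", "e"),
    inchi = c("X", "X", "Y", "Y", "Z"),
    label = c("activator", "activator", "activator", "non_activator",
              "non_activator"),
    stringsAsFactors = FALSE
  )
  out <- resolve_duplicates(recs)
  expect_equal(out$n_duplicates, 1)
  expect_equal(out$n_contradicting, 2)
  expect_equal(out$kept$id, c("a", "e"))
  expect_false(anyDuplicated(out$kept$inchi) > 0)

  uniq <- recs[c(1, 3, 5), ]
  out2 <- resolve_duplicates(uniq)
  expect_equal(out2$kept, uniq)
  expect_equal(out2$n_duplicates + out2$n_contradicting, 0)
})

test_that("train overlap removal drops shared InChIs and preserves order", {
  ds <- small_dataset()
  train <- labeled_dataset(as.data.frame(ds)[1:2, ], "train")
  test <- labeled_dataset(as.data.frame(ds)[c(3, 2, 4), ], "test")
  out <- remove_train_overlap(test, train)
  expect_equal(out$id, as.data.frame(ds)$id[c(3, 4)])
  disjoint <- labeled_dataset(as.data.frame(ds)[3:5, ], "test2")
  expect_equal(as.data.frame(remove_train_overlap(disjoint, train)),
               as.data.frame(disjoint))
})

test_that("the engineered 10-record table yields removal rows (1,1,1,2) and 5 survivors", {
  res <- run_preprocessing(fixture10(), dialect = "user")
  steps <- res$report$steps
  got <- setNames(steps$n_removed, steps$step)
  expect_equal(unname(got[c("missing_identifier_or_smiles", "below_weight",
                            "disallowed_elements", "contradicting_labels")]),
               c(1, 1, 1, 2))
  expect_equal(unname(got[c("inconclusive_activity", "unparseable_smiles",
                            "duplicates")]), c(0, 0, 0))
  expect_equal(res$report$n_final, 5)
  expect_equal(res$report$n_initial - sum(steps$n_removed),
               res$report$n_final)
  expect_equal(res$report$n_activators + res$report$n_non_activators,
               res$report$n_final)
})

test_that("an all-clean table passes with zero removals and reruns idempotently", {
  raw <- data.frame(id = paste0("c", seq_along(clean_smiles)),
                    smiles = clean_smiles,
                    label = rep("activator", length(clean_smiles)))
  res <- run_preprocessing(raw, dialect = "user")
  expect_equal(sum(res$report$steps$n_removed), 0)

  again <- run_preprocessing(
    data.frame(id = res$dataset$id, smiles = res$dataset$smiles_std,
               label = res$dataset$label),
    dialect = "user"
  )
  expect_equal(sum(again$report$steps$n_removed), 0)
  expect_equal(sort(again$dataset$inchi), sort(res$dataset$inchi))
})

test_that("toxcast dialect derives labels and counts missing assay values upfront", {
  raw <- data.frame(
    id = paste0("t", 1:6),
    smiles = c(clean_smiles[1:5], clean_smiles[1]),
    hitc_cis_up = c(1, 0, 1, NA, 1, 1),
    hitc_trans_up = c(1, 0, 0, 1, 1, 1)
  )
  res <- run_preprocessing(raw, dialect = "toxcast")
  steps <- setNames(res$report$steps$n_removed, res$report$steps$step)
  expect_equal(unname(steps["missing_identifier_or_smiles"]), 1)
  expect_equal(unname(steps["inconclusive_activity"]), 1)
  expect_equal(unname(steps["duplicates"]), 1) # t1 and t6 share a structure
  expect_equal(res$report$n_final, 3)
  expect_equal(res$report$n_activators, 2)
})

test_that("reference dialect skips weight and element filters", {
  raw <- data.frame(id = c("r1", "r2"), smiles = c("CCO", "CCCC[Sn](CCCC)CCCC"))
  res <- run_preprocessing(raw, dialect = "reference")
  expect_equal(sum(res$report$steps$n_removed), 0)
  expect_equal(res$report$n_final, 2)
})

test_that("SDF input is accepted record-wise", {
  ds <- small_dataset()
  graphs <- pxrgap:::mol_graphs(ds$smiles_std[1:2])
  blocks <- vapply(seq_along(graphs), function(i) {
    pxrgap:::write_molblock(graphs[[i]], title = paste0("mol", i))
  }, character(1))
  path <- withr::local_tempfile(fileext = ".sdf")
  writeLines(paste(blocks, collapse = "\n"), path)
  tab <- read_compound_table(path)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$id, c("mol1", "mol2"))
  re <- standardize_smiles(tab$smiles)
  expect_equal(re$inchi, ds$inchi[1:2])
})
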