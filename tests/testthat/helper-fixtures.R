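# Shared fixtures, built in code at test time.

# binary fingerprint row from 1-based bit indices
fp_row <- function(bits, n_bits = 16) {
  v <- integer(n_bits)
  v[bits] <- 1L
  v
}

fp_mat <- function(bit_list, n_bits = 16) {
  do.call(rbind, lapply(bit_list, fp_row, n_bits = n_bits))
}

# five clean, distinct, >200 Da C/H/N/O/S molecules
clean_smiles <- c(
  "CC(=O)Oc1ccc(cc1)C(=O)NCCc1ccccc1",
  "O=S(=O)(c1ccccc1)Nc1ccc(OCC)cc1",
  "O=C(Nc1ccc(Cl)cc1)c1ccc2ccccc2c1",
  "CCN(CC)C(=O)c1ccc(N(C)C)c(OC)c1",
  "O=C(OCCN1CCCCC1)c1ccccc1OC"
)

# the engineered 10-record table: 1 missing SMILES, 1 light molecule,
# 1 disallowed element (tin, above the weight cutoff), 1 contradicting pair
fixture10 <- function() {
  data.frame(
    id = paste0("r", 1:10),
    smiles = c(clean_smiles,
               NA,                          # missing SMILES
               "CCO",                       # 46 Da, weight filter
               "CCCC[Sn](CCCC)CCCC",            # tin, element filter
               "O=C(Nc1ccccc1)Nc1ccc(Cl)cc1",   # contradicting pair ...
               "O=C(Nc1ccccc1)Nc1ccc(Cl)cc1"),
    label = c(rep(c("activator", "non_activator"), length.out = 5),
              "activator", "activator", "activator",
              "activator", "non_activator"),
    stringsAsFactors = FALSE
  )
}

# a small labeled dataset built from the clean molecules
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      res <- run_preprocessing(
        data.frame(id = paste0("c", seq_along(clean_smiles)),
                   smiles = clean_smiles,
                   label = rep(c("activator", "non_activator"),
                               length.out = length(clean_smiles))),
        dialect = "user", name = "clean"
      )
      cache <<- res$dataset
    }
    cache
  }
})

# one shared synthetic benchmark split (200 molecules), reused across files
bench_split <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- library_spec(n_scaffolds = 20, analogues_per_scaffold = 10,
                           seed = 7)
      cache <<- shift_split(assign_labels(generate_library(spec)))
    }
    cache
  }
})

# independent MCC oracle: Pearson correlation of expanded 0/1 vectors
mcc_oracle <- function(tp, fp, fn, tn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  if (length(pred) == 0) return(0)
  r <- suppressWarnings(cor(pred, truth))
  if (is.na(r)) 0 else r
}

random_cv <- function(k) {
  structure(data.frame(fold = seq_len(k),
                       mcc_train = runif(k, -1, 1),
                       mcc_val = runif(k, -1, 1)),
            class = c("cv_result", "data.frame"))
}
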