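# Virtual screening: ranking by a guiding model, unanimity consensus over a
# model consortium, and nearest-training-neighbor novelty triage.

#' Rank a screening library with a guiding model
#'
#' Scores every library compound with the guiding model (probability of the
#' activator class) and returns the library in descending score order, ties
#' broken lexicographically by identifier. The library is processed in
#' chunks, so arbitrarily large feature matrices can be streamed through
#' without changing the result.
#'
#' @param model A fitted `pxr_model`.
#' @param features Feature matrix of the library, built with the model's
#'   manifest settings.
#' @param ids Compound identifiers aligned with `features`.
#' @param chunk_size Number of rows scored per chunk.
#' @return Data.frame `id`, `score`, `label`, `rank` — a permutation of the
#'   input library.
#' @export
rank_library <- function(model, features, ids, chunk_size = 10000) {
  stopifnot(nrow(features) == length(ids), chunk_size >= 1)
  n <- nrow(features)
  score <- numeric(n)
  label <- character(n)
  start <- 1
  while (start <= n) {
    end <- min(start + chunk_size - 1, n)
    pr <- predict(model, features[start:end, , drop = FALSE])
    score[start:end] <- pr$score
    label[start:end] <- pr$label
    start <- end + 1
  }
  o <- order(-score, as.character(ids))
  data.frame(id = as.character(ids)[o], score = score[o], label = label[o],
             rank = seq_len(n), stringsAsFactors = FALSE)
}

#' Unanimity consensus filter
#'
#' Keeps the compounds predicted active by every model of the consortium
#' (by convention three random forests and three SVMs).
#'
#' @param votes A data.frame or matrix of per-model predicted labels
#'   (`"activator"`/`"non_activator"`, or logical), rows = compounds,
#'   with row names or an `id` column identifying compounds.
#' @param ids Optional compound identifiers (overrides row names).
#' @return Character vector of identifiers passing the consensus.
#' @export
consensus_filter <- function(votes, ids = NULL) {
  if (is.data.frame(votes)) {
    if (is.null(ids) && "id" %in% names(votes)) {
      ids <- votes$id
      votes <- votes[, setdiff(names(votes), "id"), drop = FALSE]
    }
    votes <- as.matrix(votes)
  }
  if (nrow(votes) == 0) return(character(0))
  if (is.null(ids)) ids <- rownames(votes)
  if (is.null(ids)) stopf("compound identifiers missing")
  if (any(is.na(votes))) stopf("missing votes")
  active <- if (is.logical(votes)) votes else votes == "activator"
  as.character(ids)[rowSums(active) == ncol(votes)]
}

#' Nearest training neighbor of candidate compounds
#'
#' For every candidate, the training molecule with the highest Tanimoto
#' similarity (similarity fingerprints: radius 2, 2048 bits by default), with
#' deterministic tie-breaking by training identifier. Low nearest-neighbor
#' similarity flags structurally novel candidates.
#'
#' @param candidates Data.frame with `id` and `smiles_std` (or `smiles`)
#'   columns.
#' @param train A [labeled_dataset()].
#' @param radius,n_bits Similarity fingerprint settings.
#' @return Data.frame `id`, `nn_id`, `nn_similarity`.
#' @export
nearest_neighbor_report <- function(candidates, train, radius = 2,
                                    n_bits = 2048) {
  tr <- dataset_records(train)
  if (nrow(tr) == 0) stopf("empty training set")
  cs <- if ("smiles_std" %in% names(candidates)) candidates$smiles_std else
    candidates$smiles
  cfp <- fingerprint_matrix(cs, radius = radius, n_bits = n_bits)
  tfp <- fingerprint_matrix(tr$smiles_std, radius = radius, n_bits = n_bits)
  sim <- tanimoto_matrix(cfp, tfp)
  ord_ids <- order(as.character(tr$id))
  out <- lapply(seq_len(nrow(sim)), function(i) {
    s <- sim[i, ]
    best <- max(s)
    cand <- ord_ids[s[ord_ids] == best][1]
    data.frame(id = as.character(candidates$id[i]),
               nn_id = as.character(tr$id[cand]), nn_similarity = best,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Consensus virtual screening of a compound library
#'
#' The full screening protocol: library compounds are standardized (failures
#' are logged and skipped, never silently scored), featurized per model
#' manifest, ranked by the guiding model, voted on by the whole consortium,
#' flagged by the unanimity consensus rule, and annotated with their nearest
#' training neighbor and a novelty flag (nearest-neighbor similarity below
#' `novelty_cutoff`, default 0.7 — the conventional close-structural-
#' relationship threshold).
#'
#' @param library Data.frame with `id` and `smiles` columns.
#' @param models Named list of fitted `pxr_model`s (by convention six: three
#'   random forests and three SVMs over the three feature sets).
#' @param train The training [labeled_dataset()] for the nearest-neighbor
#'   report.
#' @param guiding Name or index of the guiding model within `models`.
#' @param chunk_size Chunk size for ranking.
#' @param novelty_cutoff Nearest-neighbor similarity below which a candidate
#'   counts as novel.
#' @param sim_radius,sim_bits Similarity fingerprint settings.
#' @param standardize Standardize library SMILES first (disable only for
#'   pre-standardized input).
#' @return A `screening_result` data.frame: `id`, `score`, `rank`, one
#'   `vote_*` column per model, `consensus`, `nn_id`, `nn_similarity`,
#'   `novel`. Skipped compounds are reported in attribute `"skipped"`.
#' @export
screen_library <- function(library, models, train, guiding = 1,
                           chunk_size = 10000, novelty_cutoff = 0.7,
                           sim_radius = 2, sim_bits = 2048,
                           standardize = TRUE) {
  stopifnot(all(c("id", "smiles") %in% names(library)), length(models) >= 1)
  if (is.null(names(models))) names(models) <- paste0("m", seq_along(models))
  gname <- if (is.character(guiding)) guiding else names(models)[guiding]

  if (standardize) {
    std <- standardize_smiles(library$smiles, ids = library$id)
    skipped <- std[!std$ok, c("id", "diagnostic"), drop = FALSE]
    recs <- std[std$ok, c("id", "smiles_std"), drop = FALSE]
  } else {
    skipped <- data.frame(id = character(0), diagnostic = character(0))
    recs <- data.frame(id = as.character(library$id),
                       smiles_std = library$smiles, stringsAsFactors = FALSE)
  }
  if (nrow(recs) == 0) stopf("no library compound survived standardization")

  # one feature matrix per distinct manifest
  manifests <- lapply(models, function(m) m$manifest)
  keys <- vapply(manifests, function(mf) {
    paste(mf$feature_set, mf$fp_radius, mf$fp_bits, sep = "|")
  }, character(1))
  feats <- list()
  for (k in unique(keys)) {
    mf <- manifests[[match(k, keys)]]
    feats[[k]] <- build_feature_matrix(
      recs, feature_set = mf$feature_set,
      fp_radius = if (is.na(mf$fp_radius)) 2 else mf$fp_radius,
      fp_bits = if (is.na(mf$fp_bits)) 8192 else mf$fp_bits
    )
  }

  ranked <- rank_library(models[[gname]], feats[[keys[gname]]], recs$id,
                         chunk_size = chunk_size)
  votes <- do.call(cbind, lapply(names(models), function(nm) {
    predict(models[[nm]], feats[[keys[nm]]])$label
  }))
  colnames(votes) <- paste0("vote_", names(models))
  rownames(votes) <- recs$id
  consensus_ids <- consensus_filter(votes == "activator", ids = recs$id)

  nn <- nearest_neighbor_report(recs, train, radius = sim_radius,
                                n_bits = sim_bits)
  res <- ranked
  res <- cbind(res, votes[res$id, , drop = FALSE])
  res$consensus <- res$id %in% consensus_ids
  res$nn_id <- nn$nn_id[match(res$id, nn$id)]
  res$nn_similarity <- nn$nn_similarity[match(res$id, nn$id)]
  res$novel <- res$nn_similarity < novelty_cutoff
  rownames(res) <- NULL
  structure(res, class = c("screening_result", "data.frame"),
            skipped = skipped, guiding = gname)
}
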