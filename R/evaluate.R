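# Out-of-distribution diagnostics: similarity-stratified performance,
# chemical-space coverage, Murcko scaffolds, forest complexity, feature
# importance.

#' Maximum Tanimoto similarity of each test molecule to a training set
#'
#' The applicability-domain coordinate used throughout the evaluation:
#' for every test molecule, the maximum Tanimoto similarity over all
#' training molecules, computed on the similarity fingerprints (by
#' convention radius 2, 2048 bits).
#'
#' @param test_fps,train_fps Binary fingerprint matrices with matching
#'   column counts; the training set must be non-empty.
#' @return Numeric vector in `[0, 1]`, one value per test molecule.
#' @export
max_similarity_profile <- function(test_fps, train_fps) {
  if (nrow(train_fps) == 0) stopf("empty training fingerprint set")
  sim <- tanimoto_matrix(test_fps, train_fps)
  apply(sim, 1, max)
}

#' Similarity-stratified test performance
#'
#' For each threshold t in 0.1, 0.2, ..., 1.0 the subset S_t collects the
#' test molecules whose maximum similarity to the training set is at most t
#' (inclusive). The MCC on each nested subset shows where in the
#' applicability domain a model earns its performance; subsets that are empty
#' or single-class in the true labels report `NA` rather than a fabricated 0.
#'
#' @param predictions,truth Predicted and true label vectors.
#' @param profile Output of [max_similarity_profile()] aligned with the test
#'   set.
#' @return A `stratified_performance` data.frame with 10 rows: `threshold`,
#'   `n` (subset size), `fraction` (of the test set), `mcc`.
#' @export
stratified_mcc <- function(predictions, truth, profile) {
  stopifnot(length(predictions) == length(truth),
            length(truth) == length(profile))
  thresholds <- seq(0.1, 1.0, by = 0.1)
  rows <- lapply(thresholds, function(t) {
    sel <- profile <= t + 1e-12
    m <- if (sum(sel) == 0 || length(unique(truth[sel])) < 2) {
      NA_real_
    } else {
      mcc_labels(predictions[sel], truth[sel])
    }
    data.frame(threshold = t, n = sum(sel),
               fraction = sum(sel) / length(truth), mcc = m)
  })
  structure(do.call(rbind, rows),
            class = c("stratified_performance", "data.frame"))
}

#' Chemical-space coverage curve
#'
#' Fraction of reference molecules that have at least one query molecule at
#' Tanimoto similarity greater than or equal to each threshold. At the
#' conventional threshold 0.7 two molecules are considered to be in a close
#' structural relationship.
#'
#' @param reference_fps,query_fps Binary fingerprint matrices (both
#'   non-empty).
#' @param thresholds Similarity thresholds to evaluate.
#' @return A `coverage_curve` data.frame (`threshold`, `fraction`),
#'   non-increasing in threshold.
#' @export
coverage_fraction <- function(reference_fps, query_fps,
                              thresholds = seq(0.1, 1.0, by = 0.1)) {
  if (nrow(reference_fps) == 0 || nrow(query_fps) == 0) {
    stopf("both fingerprint sets must be non-empty")
  }
  best <- max_similarity_profile(reference_fps, query_fps)
  rows <- data.frame(
    threshold = thresholds,
    fraction = vapply(thresholds, function(t) mean(best >= t - 1e-12),
                      numeric(1))
  )
  structure(rows, class = c("coverage_curve", "data.frame"))
}

#' Murcko framework of a molecule
#'
#' The ring systems plus the linkers connecting them, with side chains
#' removed; substituents attached to the framework through a double bond
#' (e.g. carbonyl oxygens on rings) are retained. Acyclic molecules map to
#' the empty scaffold `""`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules, `NA` for unparseable input).
#' @export
murcko_scaffold <- function(smiles) {
  graphs <- mol_graphs(smiles)
  out <- rep(NA_character_, length(smiles))
  blocks <- character(0)
  block_idx <- integer(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (is.null(g)) next
    n <- length(g$symbols)
    if (nrow(g$bonds) == 0) {
      out[i] <- ""
      next
    }
    keep <- rep(TRUE, n)
    repeat {
      bsel <- keep[g$bonds[, "from"]] & keep[g$bonds[, "to"]]
      deg <- rep(0L, n)
      tb <- tabulate(c(g$bonds[bsel, "from"], g$bonds[bsel, "to"]), nbins = n)
      deg <- as.integer(tb)
      term <- keep & deg <= 1
      if (!any(term)) break
      keep[term] <- FALSE
      if (!any(keep)) break
    }
    if (!any(keep)) {
      out[i] <- ""
      next
    }
    # retain substituents double-bonded to the framework
    dbl <- g$bonds[g$bonds[, "order"] >= 2, , drop = FALSE]
    for (k in seq_len(nrow(dbl))) {
      f <- dbl[k, "from"]; t2 <- dbl[k, "to"]
      if (keep[f] && !keep[t2]) keep[t2] <- TRUE
      if (keep[t2] && !keep[f]) keep[f] <- TRUE
    }
    blocks <- c(blocks, write_molblock(g, keep, title = paste0("m", i)))
    block_idx <- c(block_idx, i)
  }
  if (length(blocks) > 0) {
    txt <- tryCatch(
      ChemmineOB::convertFormat("SDF", "CAN",
                                paste0(paste(blocks, collapse = "\n"), "\n")),
      error = function(e) NULL
    )
    got <- if (is.null(txt)) character(0) else
      strsplit(txt, "\n", fixed = TRUE)[[1]]
    for (line in got) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(parts) < 2) next
      i <- suppressWarnings(as.integer(sub("^m", "", trimws(parts[2]))))
      if (!is.na(i)) out[i] <- parts[1]
    }
    miss <- setdiff(block_idx, which(!is.na(out) & nzchar(out)))
    for (i in miss) {
      b <- blocks[match(i, block_idx)]
      t1 <- tryCatch(ChemmineOB::convertFormat("SDF", "CAN", paste0(b, "\n")),
                     error = function(e) NA_character_)
      if (!is.na(t1)) out[i] <- sub("[ \t\n].*$", "", t1)
    }
  }
  out
}

#' Scaffold composition and overlap report
#'
#' Unique Murcko frameworks of a dataset, their overlap with the frameworks
#' of a reference collection, and the average number of molecules per
#' scaffold (a diversity measure; analogue-series-heavy sets have high
#' ratios). Acyclic molecules are grouped under one reserved empty-scaffold
#' key.
#'
#' @param dataset A [labeled_dataset()] or data.frame with `smiles_std`.
#' @param reference Optional second dataset to compute overlap against.
#' @return A `scaffold_report` list: `n_molecules`, `n_scaffolds`,
#'   `scaffolds`, `molecules_per_scaffold`, and (when `reference` is given)
#'   `n_reference_scaffolds`, `n_overlap`, `pct_overlap` (overlap as a
#'   percentage of the reference scaffold count).
#' @export
scaffold_report <- function(dataset, reference = NULL) {
  recs <- dataset_records(dataset)
  sc <- murcko_scaffold(recs$smiles_std)
  sc <- sc[!is.na(sc)]
  uniq <- unique(sc)
  rep_out <- list(
    n_molecules = length(sc),
    n_scaffolds = length(uniq),
    scaffolds = uniq,
    molecules_per_scaffold = length(sc) / max(1, length(uniq))
  )
  if (!is.null(reference)) {
    rsc <- murcko_scaffold(dataset_records(reference)$smiles_std)
    runiq <- unique(rsc[!is.na(rsc)])
    rep_out$n_reference_scaffolds <- length(runiq)
    rep_out$n_overlap <- length(intersect(uniq, runiq))
    rep_out$pct_overlap <- 100 * rep_out$n_overlap / max(1, length(runiq))
  }
  structure(rep_out, class = "scaffold_report")
}

#' @export
print.scaffold_report <- function(x, ...) {
  cat(sprintf("<scaffold_report> %d molecules on %d scaffolds (%.2f per scaffold)\n",
              x$n_molecules, x$n_scaffolds, x$molecules_per_scaffold))
  if (!is.null(x$n_overlap)) {
    cat(sprintf("  overlap with reference: %d of %d (%.1f%%)\n",
                x$n_overlap, x$n_reference_scaffolds, x$pct_overlap))
  }
  invisible(x)
}

# Depth of every node of one ranger tree; height = max terminal depth.
tree_heights <- function(fit) {
  vapply(seq_len(fit$num.trees), function(tr) {
    ti <- ranger::treeInfo(fit, tr)
    depth <- rep(NA_real_, nrow(ti))
    depth[ti$nodeID == 0] <- 0
    # children appear after parents in treeInfo's node ordering
    for (r in seq_len(nrow(ti))) {
      if (!is.na(ti$leftChild[r])) {
        depth[ti$nodeID == ti$leftChild[r]] <- depth[r] + 1
        depth[ti$nodeID == ti$rightChild[r]] <- depth[r] + 1
      }
    }
    max(depth[ti$terminal], na.rm = TRUE)
  }, numeric(1))
}

weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  x[which(cw >= 0.5)[1]]
}

#' Structural complexity of a fitted random forest
#'
#' Summarizes how complex the trees of a forest are: the height of every
#' tree, the training-sample count of every leaf, and the occupancy-weighted
#' leaf distribution, in which each leaf is weighted by the probability that
#' a training molecule is routed to it (its sample count over the per-tree
#' total). Regularized forests have shallower trees and larger, more
#' populated leaves.
#'
#' @param model A random-forest `pxr_model` (fitted by this package, which
#'   records per-leaf training occupancy).
#' @return A `complexity_stats` list: `heights`, `median_height`,
#'   `leaf_samples`, `leaf_weights` (occupancy weights, summing to 1 per
#'   tree and normalized over trees), `median_leaf_samples` (plain median),
#'   `median_leaf_occupancy` (occupancy-weighted median samples per leaf).
#' @export
rf_complexity <- function(model) {
  if (!inherits(model, "pxr_model") || model$algorithm != "random_forest") {
    stopf("rf_complexity requires a random-forest model")
  }
  heights <- tree_heights(model$fit)
  leaf_samples <- unlist(lapply(model$leaf_counts, as.numeric))
  per_tree_tot <- vapply(model$leaf_counts, sum, numeric(1))
  leaf_weights <- unlist(lapply(model$leaf_counts, function(lc) lc / sum(lc)))
  leaf_weights <- leaf_weights / length(model$leaf_counts)
  structure(
    list(heights = heights, median_height = median(heights),
         leaf_samples = leaf_samples, leaf_weights = unname(leaf_weights),
         per_tree_totals = per_tree_tot,
         median_leaf_samples = median(leaf_samples),
         median_leaf_occupancy = weighted_median(leaf_samples,
                                                 unname(leaf_weights))),
    class = "complexity_stats"
  )
}

#' @export
print.complexity_stats <- function(x, ...) {
  cat(sprintf("<complexity_stats> %d trees; median height %g; median samples/leaf %g (occupancy-weighted %g)\n",
              length(x$heights), x$median_height, x$median_leaf_samples,
              x$median_leaf_occupancy))
  invisible(x)
}

#' Feature-importance audit
#'
#' Counts the features a random-forest model actually uses (strictly
#' positive impurity importance, normalized to sum to 1) and ranks them,
#' split into the physicochemical and fingerprint blocks.
#'
#' @param model A random-forest `pxr_model`.
#' @return An `importance_audit` list: `n_positive`, `total`, and `table`
#'   (feature, block `pc`/`fp`, importance, sorted descending).
#' @export
importance_audit <- function(model) {
  if (!inherits(model, "pxr_model")) stopf("not a pxr_model")
  if (model$algorithm != "random_forest") {
    stopf("feature importances are unsupported for algorithm '%s'",
          model$algorithm)
  }
  imp <- model$fit$variable.importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  tab <- data.frame(
    feature = names(imp),
    block = ifelse(names(imp) %in% physchem_names, "pc", "fp"),
    importance = unname(imp),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$importance), ]
  rownames(tab) <- NULL
  structure(list(n_positive = sum(imp > 0), total = length(imp), table = tab),
            class = "importance_audit")
}

#' @export
print.importance_audit <- function(x, ...) {
  cat(sprintf("<importance_audit> %d of %d features with positive importance\n",
              x$n_positive, x$total))
  print(head(x$table, 10))
  invisible(x)
}
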