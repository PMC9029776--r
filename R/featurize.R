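# Featurization: physicochemical descriptor block, hashed circular
# fingerprints, and Tanimoto similarity.

#' Names of the 17 physicochemical descriptors, in canonical order
#' @export
physchem_names <- c(
  "heavy_atoms", "o_count", "n_count", "s_count", "hba", "hbd", "rings",
  "rot_bonds", "halogens", "sp3_carbons", "aromatic_atoms", "tpsa", "mw",
  "mr", "logp", "esol", "frac_rot_bonds"
)

# rotatable bonds: acyclic single bonds between two heavy atoms that are both
# non-terminal (heavy degree >= 2)
count_rotatable <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  deg <- atom_degrees(g)
  rb <- ring_bonds(g)
  sum(g$bonds[, "order"] == 1 & !rb &
        deg[g$bonds[, "from"]] >= 2 & deg[g$bonds[, "to"]] >= 2)
}

count_sp3_carbons <- function(g) {
  is_c <- g$symbols == "C"
  if (!any(is_c)) return(0L)
  has_multi <- rep(FALSE, length(g$symbols))
  if (nrow(g$bonds) > 0) {
    multi <- g$bonds[g$bonds[, "order"] > 1, , drop = FALSE]
    has_multi[c(multi[, "from"], multi[, "to"])] <- TRUE
  }
  sum(is_c & !has_multi)
}

#' Compute the physicochemical descriptor block
#'
#' Computes, for each molecule, the 17 descriptors used by this workflow, in
#' fixed order: number of heavy atoms, oxygen atoms, nitrogen atoms, sulfur
#' atoms, H-bond acceptors, H-bond donors, rings, rotatable bonds, halogens,
#' sp3 carbons, and aromatic atoms; TPSA (A^2); molecular weight (Da); molar
#' refractivity; logP; estimated log solubility (log mol/L, the ESOL linear
#' model); and the fraction of rotatable bonds among heavy-atom bonds.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @return Numeric matrix with one row per molecule and the 17 columns of
#'   [physchem_names]. Rows for molecules that fail descriptor calculation are
#'   `NA` and their indices are reported in the `"failed"` attribute.
#' @export
physchem_matrix <- function(smiles) {
  n <- length(smiles)
  out <- matrix(NA_real_, nrow = n, ncol = length(physchem_names),
                dimnames = list(NULL, physchem_names))
  props <- ob_properties(smiles)
  graphs <- mol_graphs(ifelse(props$ok, props$cansmi, NA_character_))
  failed <- integer(0)
  for (i in seq_len(n)) {
    g <- graphs[[i]]
    if (!props$ok[i] || is.null(g)) {
      failed <- c(failed, i)
      next
    }
    counts <- parse_formula(props$formula[i])
    cnt <- function(e) sum(counts[names(counts) %in% e])
    tok <- smiles_atom_counts(props$cansmi[i])
    heavy <- length(g$symbols)
    rb <- count_rotatable(g)
    nb <- nrow(g$bonds)
    ap <- if (heavy > 0) tok$aromatic / heavy else 0
    logp <- props$logp[i]
    mw <- props$mw[i]
    esol <- 0.16 - 0.63 * logp - 0.0062 * mw + 0.066 * rb - 0.74 * ap
    out[i, ] <- c(
      heavy, cnt("O"), cnt("N"), cnt("S"), props$hba[i], props$hbd[i],
      ring_count(g), rb, cnt(c("F", "Cl", "Br", "I")), count_sp3_carbons(g),
      tok$aromatic, props$tpsa[i], mw, props$mr[i], logp, esol,
      if (nb > 0) rb / nb else 0
    )
  }
  attr(out, "failed") <- failed
  out
}

#' Single-molecule physicochemical descriptor vector
#'
#' @param smiles One SMILES string.
#' @return Named numeric vector of length 17 (see [physchem_names]).
#' @export
physchem_vector <- function(smiles) {
  stopifnot(length(smiles) == 1)
  m <- physchem_matrix(smiles)
  if (length(attr(m, "failed")) > 0) stopf("descriptor calculation failed for '%s'", smiles)
  m[1, ]
}

# ---- hashed circular (Morgan-type) fingerprints ----------------------------

.hash_prime <- 16777213 # largest prime below 2^24; keeps products exact in doubles

hmix <- function(h, v) (h * 31 + v) %% .hash_prime

hash_vec <- function(values) {
  h <- 7
  for (v in values) h <- hmix(h, v)
  h
}

# Circular substructure identifiers for one molecular graph. Atom environments
# of radius 0..radius are hashed iteratively from (element, heavy degree,
# implicit H count, formal charge, ring membership) seed invariants; an atom
# stops emitting once its environment has stopped growing (its graph
# eccentricity is reached), so e.g. methane yields exactly one identifier.
morgan_ids <- function(g, radius = 2) {
  n <- length(g$symbols)
  elem <- .atomic_numbers[g$symbols]
  elem[is.na(elem)] <- 99
  deg <- atom_degrees(g)
  hs <- implicit_h(g)
  inring <- rep(0L, n)
  if (nrow(g$bonds) > 0) {
    rb <- ring_bonds(g)
    inring[c(g$bonds[rb, "from"], g$bonds[rb, "to"])] <- 1L
  }
  ids <- vapply(seq_len(n), function(a) {
    hash_vec(c(elem[a], deg[a], hs[a], g$charges[a] + 4, inring[a]))
  }, numeric(1))
  emitted <- ids

  if (radius > 0 && n > 1 && nrow(g$bonds) > 0) {
    ig <- igraph::make_empty_graph(n, directed = FALSE)
    ig <- igraph::add_edges(ig, t(g$bonds[, c("from", "to"), drop = FALSE]))
    dmat <- igraph::distances(ig)
    ecc <- apply(dmat, 1, function(d) max(d[is.finite(d)]))
    adj <- vector("list", n)
    for (k in seq_len(nrow(g$bonds))) {
      f <- g$bonds[k, "from"]; t2 <- g$bonds[k, "to"]; o <- g$bonds[k, "order"]
      adj[[f]] <- rbind(adj[[f]], c(t2, o))
      adj[[t2]] <- rbind(adj[[t2]], c(f, o))
    }
    for (r in seq_len(radius)) {
      grow <- which(ecc >= r)
      if (length(grow) == 0) break
      new_ids <- ids
      for (a in grow) {
        nb <- adj[[a]]
        ord <- order(nb[, 2], ids[nb[, 1]])
        vals <- c(r, ids[a])
        for (j in ord) vals <- c(vals, nb[j, 2], ids[nb[j, 1]])
        new_ids[a] <- hash_vec(vals)
      }
      emitted <- c(emitted, new_ids[grow])
      ids <- new_ids
    }
  }
  unique(emitted)
}

#' Hashed circular fingerprints
#'
#' Binary Morgan-type fingerprints: atom-centered circular substructure
#' environments up to `radius` bonds are hashed into a fixed-length bit
#' vector. Model fingerprints default to 8192 bits; similarity calculations
#' elsewhere in the package use radius 2 with 2048 bits.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Maximum environment radius in bonds.
#' @param n_bits Fingerprint length (a power of two).
#' @return Integer 0/1 matrix, one row per molecule, `n_bits` columns. Rows
#'   for unparseable molecules are `NA`; indices in attribute `"failed"`.
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 8192) {
  if (n_bits <= 0) stopf("n_bits must be positive")
  if (bitwAnd(n_bits, n_bits - 1L) != 0) stopf("n_bits must be a power of two")
  graphs <- mol_graphs(smiles)
  out <- matrix(0L, nrow = length(smiles), ncol = n_bits,
                dimnames = list(NULL, sprintf("fp%04d", seq_len(n_bits))))
  failed <- integer(0)
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (is.null(g)) {
      out[i, ] <- NA_integer_
      failed <- c(failed, i)
      next
    }
    bits <- unique(morgan_ids(g, radius = radius) %% n_bits) + 1
    out[i, bits] <- 1L
  }
  attr(out, "failed") <- failed
  attr(out, "radius") <- radius
  out
}

#' Tanimoto similarity of two fingerprint vectors
#'
#' @param a,b Binary 0/1 vectors of equal length.
#' @return `|a AND b| / |a OR b|`; 0 when both vectors are empty.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stopf("fingerprint lengths differ")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) 0 else inter / uni
}

#' All-pairs Tanimoto similarity between two fingerprint sets
#'
#' @param A,B Binary fingerprint matrices with equal column counts.
#' @return Numeric matrix of dimension `nrow(A)` x `nrow(B)`; pairs of empty
#'   fingerprints score 0.
#' @export
tanimoto_matrix <- function(A, B) {
  if (ncol(A) != ncol(B)) stopf("fingerprint lengths differ")
  A <- matrix(as.numeric(A), nrow = nrow(A))
  B <- matrix(as.numeric(B), nrow = nrow(B))
  inter <- A %*% t(B)
  ra <- rowSums(A)
  rb <- rowSums(B)
  uni <- outer(ra, rb, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / uni)
  sim
}

#' Build a model feature matrix for a dataset
#'
#' Assembles the per-molecule representation used for model training: the 17
#' physicochemical descriptors (`"pc"`), the hashed circular fingerprint block
#' (`"fp"`), or their column-concatenation (`"pc+fp"`, descriptor block
#' first). With default fingerprint settings the column counts are 17, 8192,
#' and 8209.
#'
#' @param dataset A [labeled_dataset()] (or data.frame with `smiles_std`).
#' @param feature_set One of `"pc"`, `"fp"`, `"pc+fp"`.
#' @param fp_radius,fp_bits Fingerprint settings for the `fp` block.
#' @return A numeric matrix with class `feature_matrix`; attributes
#'   `feature_set`, `fp_radius`, `fp_bits` form the feature manifest that
#'   models carry along for compatibility checks.
#' @export
build_feature_matrix <- function(dataset, feature_set = c("pc", "fp", "pc+fp"),
                                 fp_radius = 2, fp_bits = 8192) {
  feature_set <- match.arg(feature_set)
  recs <- dataset_records(dataset)
  if (nrow(recs) == 0) stopf("empty dataset")
  smiles <- recs$smiles_std
  blocks <- list()
  failed <- integer(0)
  if (feature_set %in% c("pc", "pc+fp")) {
    pc <- physchem_matrix(smiles)
    failed <- union(failed, attr(pc, "failed"))
    blocks$pc <- pc
  }
  if (feature_set %in% c("fp", "pc+fp")) {
    fp <- fingerprint_matrix(smiles, radius = fp_radius, n_bits = fp_bits)
    failed <- union(failed, attr(fp, "failed"))
    blocks$fp <- fp
  }
  if (length(failed) > 0) {
    stopf("featurization failed for %d record(s): %s", length(failed),
          paste(head(recs$id[sort(failed)], 5), collapse = ", "))
  }
  m <- do.call(cbind, unname(blocks))
  structure(m, class = c("feature_matrix", class(m)),
            feature_set = feature_set,
            fp_radius = if (!is.null(blocks$fp)) fp_radius else NA_integer_,
            fp_bits = if (!is.null(blocks$fp)) fp_bits else NA_integer_)
}

feature_manifest <- function(fm) {
  list(feature_set = attr(fm, "feature_set"),
       fp_radius = attr(fm, "fp_radius"),
       fp_bits = attr(fm, "fp_bits"),
       n_features = ncol(fm))
}
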