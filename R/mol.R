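# Molecule layer: OpenBabel-backed parsing, properties, and molecular graphs.
#
# OpenBabel (via ChemmineOB) provides format conversion, canonical SMILES,
# standard InChI and the scalar properties (MW, logP, TPSA, MR, H-bond
# donor/acceptor counts). Molecular graphs are read from the V2000 mol blocks
# OpenBabel emits, because graph-level quantities (ring perception, rotatable
# bonds, sp3 carbons, circular fingerprints, Murcko frameworks) are not
# available from any installed R package at the settings this workflow needs.

.prop_cache <- new.env(parent = emptyenv())

#' Clear the internal molecular property cache
#'
#' Properties computed by OpenBabel are memoised per SMILES string. The cache
#' is purely an optimisation; clearing it never changes results.
#' @return Invisibly, the number of entries removed.
#' @export
clear_mol_cache <- function() {
  n <- length(ls(.prop_cache))
  rm(list = ls(.prop_cache), envir = .prop_cache)
  invisible(n)
}

# Per-molecule OpenBabel property computation. Batch conversion is not used
# here because OpenBabel aborts a whole batch on the first hard parse failure;
# a per-record tryCatch keeps record alignment and gives per-record
# diagnostics. Returns a data.frame aligned with `smiles`, with ok = FALSE for
# records OpenBabel cannot parse.
ob_properties <- function(smiles, use_cache = TRUE) {
  n <- length(smiles)
  out <- data.frame(
    ok = logical(n), cansmi = NA_character_, inchi = NA_character_,
    formula = NA_character_, mw = NA_real_, logp = NA_real_, tpsa = NA_real_,
    mr = NA_real_, hba = NA_real_, hbd = NA_real_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    smi <- smiles[i]
    if (is.na(smi) || !nzchar(trimws(smi))) next
    key <- smi
    if (use_cache && !is.null(row <- .prop_cache[[key]])) {
      out[i, ] <- row
      next
    }
    p <- tryCatch(
      ChemmineOB::forEachMol("SMILES", paste0(smi, "\tx\n"),
                             function(m) ChemmineOB::prop_OB(m))[[1]],
      error = function(e) NULL
    )
    if (is.null(p) || !nzchar(p$cansmi)) next
    out$ok[i] <- TRUE
    out$cansmi[i] <- sub("[ \t].*$", "", sub("\n$", "", p$cansmi))
    out$inchi[i] <- sub("[ \t\n].*$", "", p$InChI)
    out$formula[i] <- p$formula
    out$mw[i] <- p$MW
    out$logp[i] <- p$logP
    out$tpsa[i] <- p$TPSA
    out$mr[i] <- p$MR
    out$hba[i] <- p$HBA1
    out$hbd[i] <- p$HBD
    if (use_cache) .prop_cache[[key]] <- out[i, ]
  }
  out
}

# Convert a batch of InChI strings back to canonical SMILES. Standard InChI
# merges mobile-H tautomers into one representation, so the round trip
# SMILES -> InChI -> SMILES yields a deterministic canonical tautomer.
inchi_to_smiles <- function(inchi) {
  if (length(inchi) == 0) return(character(0))
  out <- rep(NA_character_, length(inchi))
  okin <- !is.na(inchi) & nzchar(inchi)
  if (!any(okin)) return(out)
  txt <- tryCatch(
    ChemmineOB::convertFormat("INCHI", "CAN",
                              paste0(inchi[okin], "\n", collapse = "")),
    error = function(e) NULL
  )
  smi <- if (is.null(txt)) character(0) else
    sub("\t.*$", "", strsplit(txt, "\n", fixed = TRUE)[[1]])
  if (length(smi) == sum(okin)) {
    out[okin] <- smi
  } else {
    # batch failed or dropped records; fall back to per-record conversion
    idx <- which(okin)
    for (i in idx) {
      t1 <- tryCatch(
        ChemmineOB::convertFormat("INCHI", "CAN", paste0(inchi[i], "\n")),
        error = function(e) NA_character_
      )
      out[i] <- sub("\t.*$", "", strsplit(t1, "\n", fixed = TRUE)[[1]][1])
    }
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

# ---- V2000 mol-block graph parsing -----------------------------------------

.charge_codes <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                   `6` = -2, `7` = -3)

parse_molblock <- function(lines) {
  if (length(lines) < 4) return(NULL)
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || natoms < 1) return(NULL)
  atom_lines <- lines[5:(4 + natoms)]
  symbols <- trimws(substr(atom_lines, 32, 34))
  codes <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  codes[is.na(codes) | codes < 0 | codes > 7] <- 0L
  charges <- unname(.charge_codes[as.character(codes)])
  bonds <- if (!is.na(nbonds) && nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    cbind(
      from = as.integer(substr(bl, 1, 3)),
      to = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    matrix(integer(0), ncol = 3, dimnames = list(NULL, c("from", "to", "order")))
  }
  # M  CHG lines supersede atom-block charge codes when present
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines) > 0) {
    charges <- rep(0, natoms)
    for (cl in chg_lines) {
      tok <- as.integer(strsplit(trimws(substr(cl, 7, nchar(cl))), "[ ]+")[[1]])
      nch <- tok[1]
      for (j in seq_len(nch)) {
        charges[tok[2 * j]] <- tok[2 * j + 1]
      }
    }
  }
  list(symbols = symbols, charges = charges, bonds = bonds)
}

# Parse a batch of (already validated) SMILES into molecular graphs.
# Returns a list aligned with `smiles`; NULL elements mark parse failures.
mol_graphs <- function(smiles) {
  n <- length(smiles)
  graphs <- vector("list", n)
  okin <- !is.na(smiles) & nzchar(smiles)
  if (!any(okin)) return(graphs)
  txt <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "SDF",
      paste0(smiles[okin], "\tm", which(okin), "\n", collapse = "")
    ),
    error = function(e) NULL
  )
  blocks <- if (is.null(txt)) character(0) else
    strsplit(txt, "$$$$\n", fixed = TRUE)[[1]]
  parsed_idx <- integer(0)
  for (b in blocks) {
    lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
    if (length(lines) < 4) next
    title <- trimws(lines[1])
    i <- suppressWarnings(as.integer(sub("^m", "", title)))
    if (is.na(i) || i < 1 || i > n) next
    graphs[[i]] <- parse_molblock(lines)
    parsed_idx <- c(parsed_idx, i)
  }
  missing <- setdiff(which(okin), parsed_idx)
  for (i in missing) {
    t1 <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles[i], "\tx\n")),
      error = function(e) NULL
    )
    if (!is.null(t1)) {
      graphs[[i]] <- parse_molblock(strsplit(t1, "\n", fixed = TRUE)[[1]])
    }
  }
  graphs
}

# ---- graph utilities --------------------------------------------------------

.atomic_numbers <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15, S = 16,
  Cl = 17, Se = 34, Br = 35, I = 53
)

.default_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, Se = 2
)

atom_degrees <- function(g) {
  deg <- rep(0L, length(g$symbols))
  if (nrow(g$bonds) > 0) {
    tb <- tabulate(c(g$bonds[, "from"], g$bonds[, "to"]),
                   nbins = length(g$symbols))
    deg <- as.integer(tb)
  }
  deg
}

# Implicit hydrogen count per atom from default valences adjusted by formal
# charge (N+ binds 4, O- binds 1, ...); bond orders are kekulized in the
# OpenBabel mol blocks this package parses.
implicit_h <- function(g) {
  n <- length(g$symbols)
  bsum <- rep(0, n)
  if (nrow(g$bonds) > 0) {
    ord <- g$bonds[, "order"]
    ord[ord == 4] <- 1.5 # defensive: aromatic bond code
    for (k in seq_len(nrow(g$bonds))) {
      bsum[g$bonds[k, "from"]] <- bsum[g$bonds[k, "from"]] + ord[k]
      bsum[g$bonds[k, "to"]] <- bsum[g$bonds[k, "to"]] + ord[k]
    }
  }
  val <- .default_valence[g$symbols]
  val[is.na(val)] <- 0
  eff <- val + ifelse(g$symbols %in% c("N", "P", "O", "S", "Se"), g$charges, 0)
  pmax(0, round(eff - bsum))
}

# Logical vector marking bonds that are part of a ring (non-bridge edges).
ring_bonds <- function(g) {
  nb <- nrow(g$bonds)
  if (nb == 0) return(logical(0))
  ig <- igraph::graph_from_edgelist(g$bonds[, c("from", "to"), drop = FALSE],
                                    directed = FALSE)
  if (igraph::vcount(ig) < length(g$symbols)) {
    ig <- igraph::add_vertices(ig, length(g$symbols) - igraph::vcount(ig))
  }
  br <- igraph::bridges(ig)
  res <- rep(TRUE, nb)
  res[as.integer(br)] <- FALSE
  res
}

# Smallest-set-of-smallest-rings count: E - V + number of components.
ring_count <- function(g) {
  n <- length(g$symbols)
  if (n == 0) return(0L)
  ig <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(g$bonds) > 0) {
    ig <- igraph::add_edges(ig, t(g$bonds[, c("from", "to"), drop = FALSE]))
  }
  as.integer(nrow(g$bonds) - n + igraph::components(ig)$no)
}

# Serialize an induced subgraph back to a V2000 mol block (zero coordinates),
# so OpenBabel can canonicalize it. `keep` is a logical or integer atom index.
write_molblock <- function(g, keep = seq_along(g$symbols), title = "s") {
  keep <- seq_along(g$symbols)[keep]
  if (length(keep) == 0) return(NULL)
  remap <- integer(length(g$symbols))
  remap[keep] <- seq_along(keep)
  bsel <- nrow(g$bonds) > 0 &
    g$bonds[, "from"] %in% keep & g$bonds[, "to"] %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  na <- length(keep)
  nb <- nrow(bonds)
  hdr <- c(title, " pxrgap", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$symbols[keep])
  blines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0",
            remap[bonds[, "from"]], remap[bonds[, "to"]], bonds[, "order"])
  } else {
    character(0)
  }
  chg <- which(g$charges[keep] != 0)
  chg_lines <- if (length(chg) > 0) {
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, g$charges[keep][chg]), collapse = ""))
  } else {
    character(0)
  }
  paste(c(hdr, atoms, blines, chg_lines, "M  END", "$$$$"), collapse = "\n")
}

# ---- SMILES token counting --------------------------------------------------

# Count heavy atoms and aromatic atoms in a SMILES string, and report whether
# it contains carbon. Used for fragment ranking and the aromatic-atom
# descriptor; only token-level lexing is needed, not full SMILES semantics.
smiles_atom_counts <- function(smiles) {
  heavy <- 0L
  aromatic <- 0L
  carbon <- FALSE
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  i <- 1L
  nc <- length(chars)
  while (i <= nc) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= nc && chars[j] != "]") j <- j + 1L
      tok <- paste0(chars[(i + 1):(j - 1)], collapse = "")
      sym <- regmatches(tok, regexpr("[A-Za-z][a-z]?", tok))
      if (length(sym) == 1) {
        base <- toupper(substr(sym, 1, 1))
        # two-letter symbols keep their second letter only if it forms a
        # known element (se, si, as, cl, br, ...)
        two <- paste0(base, substr(sym, 2, 2))
        elem <- if (nchar(sym) == 2 && two %in% c(names(.atomic_numbers),
                                                  "As", "Sn", "Fe", "Zn",
                                                  "Hg", "Pb", "Cu", "Mn",
                                                  "Mg", "Na", "Ca", "Al",
                                                  "Ni", "Co", "Pt", "Pd",
                                                  "Ag", "Au", "Cd", "Ba",
                                                  "Ti", "Cr", "Li", "Sb",
                                                  "Bi", "Te", "Ge", "Sr")) {
          two
        } else {
          base
        }
        if (elem != "H") {
          heavy <- heavy + 1L
          if (substr(sym, 1, 1) %in% letters) aromatic <- aromatic + 1L
          if (elem == "C") carbon <- TRUE
        }
      }
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "S", "P", "B", "F", "I")) {
      nxt <- if (i < nc) chars[i + 1L] else ""
      two <- paste0(ch, nxt)
      if (two %in% c("Cl", "Br")) {
        heavy <- heavy + 1L
        i <- i + 2L
      } else {
        heavy <- heavy + 1L
        if (ch == "C") carbon <- TRUE
        i <- i + 1L
      }
    } else if (ch %in% c("c", "n", "o", "s", "p", "b")) {
      heavy <- heavy + 1L
      aromatic <- aromatic + 1L
      if (ch == "c") carbon <- TRUE
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(heavy = heavy, aromatic = aromatic, carbon = carbon)
}

# Parse a molecular formula string ("C9H8O4", "C5H5N+") into named counts.
parse_formula <- function(formula) {
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(toks) == 0) return(integer(0))
  elems <- sub("[0-9]+$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  tapply(counts, elems, sum)
}
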