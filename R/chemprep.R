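# Standardization and filter cascade for raw compound tables.

.allowed_elements <- c("H", "B", "C", "N", "O", "Si", "P", "S", "Se",
                       "F", "Cl", "Br", "I")

#' Standardize SMILES to parent structures
#'
#' Applies the two-step standardization used throughout this workflow:
#' the largest organic fragment is kept (salts and solvents stripped), and the
#' parent is tautomer-canonicalized by a standard-InChI round trip (standard
#' InChI merges mobile-hydrogen tautomers, and converting the InChI back to
#' SMILES picks one deterministic representative). The charge state of the
#' parent fragment is left untouched.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Optional identifiers, recycled into the result.
#' @return A data.frame with one row per input: `id`, `ok` (logical),
#'   `smiles_std` (canonical SMILES of the standardized parent), `inchi`
#'   (standard InChI of the parent, the identity key), `mw` (molecular weight
#'   of the parent, Da), `formula`, `parent_tie` (TRUE when two equally large
#'   organic fragments were tie-broken by canonical SMILES order), and
#'   `diagnostic` (reason for rejection when `ok` is FALSE).
#' @examples
#' \dontrun{
#' standardize_smiles(c("CCO.Cl", "Oc1ccccn1", "O=c1cccc[nH]1"))
#' }
#' @export
standardize_smiles <- function(smiles, ids = NULL) {
  n <- length(smiles)
  ids <- if (is.null(ids)) as.character(seq_len(n)) else as.character(ids)
  out <- data.frame(
    id = ids, ok = FALSE, smiles_std = NA_character_, inchi = NA_character_,
    mw = NA_real_, formula = NA_character_, parent_tie = FALSE,
    diagnostic = NA_character_, stringsAsFactors = FALSE
  )
  props <- ob_properties(smiles)
  out$diagnostic[!props$ok] <- "unparseable SMILES"

  # largest-organic-fragment selection on the canonical SMILES
  parent <- rep(NA_character_, n)
  for (i in which(props$ok)) {
    frags <- strsplit(props$cansmi[i], ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    if (length(frags) == 0) {
      out$diagnostic[i] <- "empty structure"
      next
    }
    info <- lapply(frags, smiles_atom_counts)
    heavy <- vapply(info, `[[`, integer(1), "heavy")
    organic <- vapply(info, `[[`, logical(1), "carbon")
    cand <- if (any(organic)) which(organic) else seq_along(frags)
    best <- cand[heavy[cand] == max(heavy[cand])]
    if (length(best) > 1) {
      out$parent_tie[i] <- TRUE
      best <- best[order(frags[best])][1]
    }
    parent[i] <- frags[best]
  }

  pidx <- which(!is.na(parent))
  if (length(pidx) > 0) {
    pprops <- ob_properties(parent[pidx])
    std <- inchi_to_smiles(pprops$inchi)
    for (k in seq_along(pidx)) {
      i <- pidx[k]
      if (!pprops$ok[k] || is.na(pprops$inchi[k]) || is.na(std[k])) {
        out$diagnostic[i] <- "standardization failed"
        next
      }
      out$ok[i] <- TRUE
      out$smiles_std[i] <- std[k]
      out$inchi[i] <- pprops$inchi[k]
      out$mw[i] <- pprops$mw[k]
      out$formula[i] <- pprops$formula[k]
    }
  }
  out
}

#' Derive binary PXR activity labels from paired ToxCast hit calls
#'
#' Merges the hit calls (`hitc`) of the two "up" PXR reporter assays into one
#' label: a compound is an activator when both assays score 1, a non-activator
#' when both score 0, and inconclusive when the assays disagree. Missing
#' values yield `NA`.
#'
#' @param hitc_cis_up,hitc_trans_up Numeric/integer vectors of 0/1 hit calls.
#' @return Character vector with values `"activator"`, `"non_activator"`,
#'   `"inconclusive"`, or `NA` for missing input.
#' @export
toxcast_label <- function(hitc_cis_up, hitc_trans_up) {
  stopifnot(length(hitc_cis_up) == length(hitc_trans_up))
  out <- rep(NA_character_, length(hitc_cis_up))
  both <- !is.na(hitc_cis_up) & !is.na(hitc_trans_up)
  out[both & hitc_cis_up == 1 & hitc_trans_up == 1] <- "activator"
  out[both & hitc_cis_up == 0 & hitc_trans_up == 0] <- "non_activator"
  out[both & hitc_cis_up != hitc_trans_up] <- "inconclusive"
  out
}

#' Weight and element filters for standardized records
#'
#' Removes records with molecular weight below `min_mw` and records whose
#' standardized parent contains an element outside the allowed set. Counts are
#' attributed to the first filter that fires, in that order.
#'
#' @param records Data.frame of standardized records (needs `mw`, `formula`).
#' @param min_mw Minimum molecular weight in Da (default 200).
#' @param allowed_elements Character vector of allowed element symbols.
#' @return List with `kept` (filtered data.frame) and `steps`
#'   (data.frame of step/n_removed rows).
#' @export
apply_filters <- function(records, min_mw = 200,
                          allowed_elements = .allowed_elements) {
  light <- !is.na(records$mw) & records$mw < min_mw
  rest <- records[!light, , drop = FALSE]
  bad_elem <- vapply(rest$formula, function(f) {
    if (is.na(f)) return(TRUE)
    elems <- names(parse_formula(f))
    length(setdiff(elems, allowed_elements)) > 0
  }, logical(1), USE.NAMES = FALSE)
  list(
    kept = rest[!bad_elem, , drop = FALSE],
    steps = data.frame(
      step = c("below_weight", "disallowed_elements"),
      n_removed = c(sum(light), sum(bad_elem)),
      stringsAsFactors = FALSE
    )
  )
}

#' Resolve duplicate structures by InChI
#'
#' Groups records with identical InChI. A group whose activity labels all
#' agree keeps one representative (the first in input order); a group with
#' conflicting labels is removed entirely.
#'
#' @param records Data.frame with `inchi` and `label` columns.
#' @return List with `kept`, `n_contradicting` (records removed from
#'   label-discordant groups), and `n_duplicates` (surplus records removed
#'   from concordant groups).
#' @export
resolve_duplicates <- function(records) {
  if (nrow(records) == 0) {
    return(list(kept = records, n_contradicting = 0L, n_duplicates = 0L))
  }
  keep <- rep(TRUE, nrow(records))
  n_contra <- 0L
  n_dup <- 0L
  groups <- split(seq_len(nrow(records)), records$inchi)
  for (idx in groups) {
    if (length(idx) == 1) next
    labs <- unique(records$label[idx])
    if (length(labs) > 1) {
      keep[idx] <- FALSE
      n_contra <- n_contra + length(idx)
    } else {
      keep[idx[-1]] <- FALSE
      n_dup <- n_dup + length(idx) - 1L
    }
  }
  list(kept = records[keep, , drop = FALSE],
       n_contradicting = n_contra, n_duplicates = n_dup)
}

#' Remove test compounds already present in a training set
#'
#' Drops test records whose InChI occurs in the training set, preserving
#' order. This enforces a honest train/test separation before any external
#' evaluation.
#'
#' @param test,train `labeled_dataset` objects (or data.frames with `inchi`).
#' @return The filtered test set, same class as the input.
#' @export
remove_train_overlap <- function(test, train) {
  recs <- dataset_records(test)
  kept <- recs[!(recs$inchi %in% dataset_records(train)$inchi), , drop = FALSE]
  if (inherits(test, "labeled_dataset")) {
    labeled_dataset(kept, name = attr(test, "name"))
  } else {
    kept
  }
}

# ---- dataset / report containers -------------------------------------------

#' Construct a labeled dataset
#'
#' A `labeled_dataset` is a data.frame of standardized molecule records
#' (`id`, `smiles_std`, `inchi`, `label`, `mw`, and optional extras) whose
#' InChIs are unique. It is the common currency between preprocessing,
#' featurization, and evaluation.
#'
#' @param records Data.frame of molecule records.
#' @param name Dataset name used in reports.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(records, name = "dataset") {
  req <- c("id", "smiles_std", "inchi", "label")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0) stopf("records lack columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records$inchi)) stopf("duplicate InChIs in dataset '%s'", name)
  rownames(records) <- NULL
  structure(records, class = c("labeled_dataset", "data.frame"), name = name %||% "dataset")
}

dataset_records <- function(x) {
  if (inherits(x, "labeled_dataset")) as.data.frame(x) else x
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("<labeled_dataset '%s'> %d molecules (%d activators, %d non-activators)\n",
              attr(x, "name"), nrow(x),
              sum(x$label == "activator", na.rm = TRUE),
              sum(x$label == "non_activator", na.rm = TRUE)))
  invisible(x)
}

new_filter_report <- function(steps, n_initial, n_final, n_act, n_non) {
  structure(
    list(steps = steps, n_initial = n_initial, n_final = n_final,
         n_activators = n_act, n_non_activators = n_non),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("Filter report: %d -> %d compounds\n", x$n_initial, x$n_final))
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %-28s %6d removed\n", x$steps$step[i], x$steps$n_removed[i]))
  }
  cat(sprintf("  final: %d activators / %d non-activators\n",
              x$n_activators, x$n_non_activators))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) x$steps

# Normalize heterogeneous activity annotations to the internal label set.
normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("inconclusive", length(x))
  out[x %in% c("activator", "active", "a", "1", "true")] <- "activator"
  out[x %in% c("non_activator", "nonactivator", "non-activator",
               "inactive", "n", "0", "false")] <- "non_activator"
  out[is.na(x) | !nzchar(x)] <- NA_character_
  out
}

#' Run the full preprocessing cascade on a raw compound table
#'
#' Executes, in order: removal of rows with missing identifier or SMILES
#' (including missing assay values for the ToxCast dialect), removal of
#' inconclusive activity labels, standardization (largest organic fragment,
#' canonical tautomer; unparseable SMILES are counted in their own step),
#' the molecular weight filter, the element filter, removal of
#' label-contradicting InChI groups, and deduplication. The weight and
#' element filters are skipped for the `"reference"` dialect (unlabeled
#' reference collections used only for coverage and scaffold analyses).
#'
#' @param raw Data.frame. Columns by dialect: `pubchem`/`literature`/`user`
#'   need `id`, `smiles`, `label`; `toxcast` needs `id`, `smiles`,
#'   `hitc_cis_up`, `hitc_trans_up`; `reference` needs `id`, `smiles`.
#' @param dialect Source dialect, one of `"pubchem"`, `"toxcast"`,
#'   `"literature"`, `"user"`, `"reference"`.
#' @param min_mw Weight-filter threshold in Da.
#' @param allowed_elements Element whitelist for the element filter.
#' @param name Dataset name.
#' @return List with `dataset` (a [labeled_dataset()]) and `report`
#'   (a `filter_report` whose removal counts sum to
#'   `n_initial - n_final`).
#' @export
run_preprocessing <- function(raw,
                              dialect = c("user", "pubchem", "toxcast",
                                          "literature", "reference"),
                              min_mw = 200,
                              allowed_elements = .allowed_elements,
                              name = NULL) {
  dialect <- match.arg(dialect)
  name <- name %||% dialect
  if (!all(c("id", "smiles") %in% names(raw))) {
    stopf("raw table must have 'id' and 'smiles' columns")
  }
  n_initial <- nrow(raw)
  steps <- data.frame(step = character(0), n_removed = integer(0))
  add_step <- function(step, n) {
    steps <<- rbind(steps, data.frame(step = step, n_removed = as.integer(n)))
  }

  # 1. missing identifier / SMILES (and missing assay values for toxcast)
  miss <- is.na(raw$id) | !nzchar(trimws(as.character(raw$id))) |
    is.na(raw$smiles) | !nzchar(trimws(as.character(raw$smiles)))
  if (dialect == "toxcast") {
    if (!all(c("hitc_cis_up", "hitc_trans_up") %in% names(raw))) {
      stopf("toxcast dialect needs 'hitc_cis_up' and 'hitc_trans_up' columns")
    }
    miss <- miss | is.na(raw$hitc_cis_up) | is.na(raw$hitc_trans_up)
  }
  add_step("missing_identifier_or_smiles", sum(miss))
  cur <- raw[!miss, , drop = FALSE]

  # 2. inconclusive activity
  label <- switch(dialect,
    toxcast = toxcast_label(cur$hitc_cis_up, cur$hitc_trans_up),
    reference = rep(NA_character_, nrow(cur)), # unlabeled collection
    {
      if (!"label" %in% names(raw)) stopf("dialect '%s' needs a 'label' column", dialect)
      normalize_label(cur$label)
    }
  )
  inconc <- is.na(label) | label == "inconclusive"
  if (dialect == "reference") inconc <- rep(FALSE, nrow(cur))
  add_step("inconclusive_activity", sum(inconc))
  cur <- cur[!inconc, , drop = FALSE]
  label <- label[!inconc]

  # 3. standardization
  std <- standardize_smiles(cur$smiles, ids = cur$id)
  add_step("unparseable_smiles", sum(!std$ok))
  recs <- std[std$ok, c("id", "smiles_std", "inchi", "mw", "formula",
                        "parent_tie"), drop = FALSE]
  recs$label <- label[std$ok]

  # 4./5. weight and element filters (not applied to reference collections)
  if (dialect == "reference") {
    add_step("below_weight", 0L)
    add_step("disallowed_elements", 0L)
  } else {
    flt <- apply_filters(recs, min_mw = min_mw,
                         allowed_elements = allowed_elements)
    steps <- rbind(steps, flt$steps)
    recs <- flt$kept
  }

  # 6./7. contradicting labels, duplicates
  dup <- resolve_duplicates(recs)
  add_step("contradicting_labels", dup$n_contradicting)
  add_step("duplicates", dup$n_duplicates)
  recs <- dup$kept

  recs <- recs[, c("id", "smiles_std", "inchi", "label", "mw", "formula",
                   "parent_tie"), drop = FALSE]
  ds <- labeled_dataset(recs, name = name)
  report <- new_filter_report(
    steps, n_initial = n_initial, n_final = nrow(recs),
    n_act = sum(recs$label == "activator", na.rm = TRUE),
    n_non = sum(recs$label == "non_activator", na.rm = TRUE)
  )
  stopifnot(report$n_initial - sum(report$steps$n_removed) == report$n_final)
  list(dataset = ds, report = report)
}

#' Read a compound table from CSV or SDF
#'
#' CSV files are read as-is (columns `id`, `smiles`, plus dialect-specific
#' label columns). For SDF files the first molecule block of each record is
#' converted to SMILES; identifiers come from `id_field` (an SDF data field)
#' or the record title, and labels from `label_field` when given.
#'
#' @param path File path (`.csv` or `.sdf`).
#' @param id_field,label_field Optional SDF data-field names.
#' @return Data.frame with `id`, `smiles`, and (if available) `label`.
#' @export
read_compound_table <- function(path, id_field = NULL, label_field = NULL) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    blocks <- strsplit(txt, "$$$$", fixed = TRUE)[[1]]
    blocks <- blocks[vapply(blocks, function(b) nzchar(trimws(b)), logical(1))]
    out <- lapply(seq_along(blocks), function(k) {
      b <- sub("^\n+", "", blocks[[k]])
      lines <- strsplit(b, "\n", fixed = TRUE)[[1]]
      get_field <- function(f) {
        hit <- grep(sprintf("^> *<%s>", f), lines)
        if (length(hit) == 1 && hit < length(lines)) trimws(lines[hit + 1]) else NA_character_
      }
      smi <- tryCatch({
        s <- ChemmineOB::convertFormat("SDF", "CAN", paste0(b, "\n$$$$\n"))
        sub("[ \t\n].*$", "", s)
      }, error = function(e) NA_character_)
      id <- if (!is.null(id_field)) get_field(id_field) else trimws(lines[1])
      if (is.na(id) || !nzchar(id)) id <- as.character(k)
      data.frame(id = id, smiles = smi,
                 label = if (!is.null(label_field)) get_field(label_field) else NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Write a cleaned dataset and its filter report
#'
#' @param result The list returned by [run_preprocessing()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_preprocessing <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds_path <- file.path(dir, "dataset.csv")
  rep_path <- file.path(dir, "filter_report.json")
  write.csv(as.data.frame(result$dataset)[, c("id", "smiles_std", "inchi", "label")],
            ds_path, row.names = FALSE)
  rep <- result$report
  jsonlite::write_json(
    list(n_initial = rep$n_initial, n_final = rep$n_final,
         n_activators = rep$n_activators, n_non_activators = rep$n_non_activators,
         steps = rep$steps),
    rep_path, auto_unbox = TRUE, digits = NA
  )
  invisible(c(ds_path, rep_path))
}
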