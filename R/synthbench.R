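# Synthetic analogue-series benchmark: clustered SAR libraries with label
# noise, class imbalance, and a scaffold-held-out out-of-distribution split.
# The generator exists so the selection and evaluation machinery can be
# exercised end-to-end without any external compound data.

# Hard-coded drug-like ring-system templates. Each template carries three
# substitution points written as ({1}), ({2}), ({3}); replacing a marker with
# "" yields the unsubstituted parent, replacing it with "(<fragment>)"
# attaches a substituent by a single bond. All parents are heavier than
# 200 Da, use only whitelisted elements, and have pairwise distinct Murcko
# frameworks; substituents are acyclic, so every analogue of a template keeps
# its framework.
.scaffold_templates <- c(
  "O=S(=O)(c1ccc({1})cc1)Nc1ccc({2})c({3})c1",
  "O=C(Nc1ccc({1})cc1)c1ccc2cc({2})c({3})cc2c1",
  "O=C(Oc1ccc({1})cc1)c1ccc2cc({2})c({3})cc2c1",
  "O=S(=O)(c1ccc({1})cc1C)c1ccc({2})c({3})c1",
  "O=C(c1ccc({1})cc1)c1ccc2cc({2})c({3})cc2c1",
  "O=C(Nc1ccc({1})cc1C)Nc1ccc({2})c({3})c1",
  "O=C(Nc1ccc({1})cc1C)Oc1ccc({2})c({3})c1",
  "c1ccc(-c2nc3cc({1})c({2})cc3s2)c({3})c1",
  "Clc1ccc(-c2nc3cc({1})c({2})cc3o2)c({3})c1",
  "n1cc({3})ccc1-n1c2ccccc2c2cc({1})c({2})cc21",
  "O=C(c1ccc({1})cc1Cl)N1CCN(c2ccc({2})c({3})c2Cl)CC1",
  "c1cc({1})ccc1Nc1ccnc2cc({2})c({3})cc12",
  "O=S(=O)(N1CCOCC1)c1ccc(-c2ccc({1})c({2})c2)c({3})c1",
  "O=C(N1CCCC1)c1ccc(Oc2ccc({1})c({2})c2)c({3})c1",
  "O=S(=O)(N)c1ccc(Oc2ccc({1})c({2})c2)c({3})c1",
  "O=C(Nc1ccc2cc({3})ccc2c1)c1ccc({1})c({2})c1",
  "C(c1ccc({1})cc1)(c1ccc({2})cn1)c1ccc({3})nc1",
  "O=C(CSc1nnc(-c2ccc({1})cc2)o1)Nc1ccc({2})c({3})c1",
  "c1cc({1})ccc1OCc1ccc(C(=O)Nc2ccc({2})c({3})c2)nc1",
  "O=C1c2cc({1})c({2})cc2Sc2c(C)c({3})ccc21"
)

# Acyclic substituent pool; "" is hydrogen. Spans roughly four logP units so
# the physicochemical activity gate splits every analogue series.
.substituents <- c("", "C", "CC", "CCC", "C(C)C", "OC", "O", "N", "N(C)C",
                   "F", "Cl", "Br", "C(F)(F)F", "C#N")

#' Specification of a synthetic analogue-series library
#'
#' Defaults describe the benchmark's study conditions: 20 analogue series of
#' 25 compounds (500 molecules), 75% of scaffolds in the active-scaffold
#' set (so the activity posterior of the transferable lipophilicity gate is
#' bounded away from 1/2), a 10% symmetric label-flip rate, and a target
#' activator prevalence of 25% — the class imbalance regime of typical
#' public PXR screening data.
#'
#' @param n_scaffolds Number of analogue series (max 20 built-in templates).
#' @param analogues_per_scaffold Compounds per series (max 14^3 substituent
#'   combinations).
#' @param fraction_active_scaffolds Fraction of scaffolds whose series can
#'   contain activators.
#' @param label_noise_rate Probability that a label is flipped, in `[0, 1)`.
#' @param prevalence Target activator prevalence in `(0, 1)`; must not
#'   exceed `fraction_active_scaffolds`.
#' @param seed Integer seed; every downstream draw derives from it.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_scaffolds = 20, analogues_per_scaffold = 25,
                         fraction_active_scaffolds = 0.75,
                         label_noise_rate = 0.1, prevalence = 0.25,
                         seed = 1) {
  stopifnot(n_scaffolds >= 1, analogues_per_scaffold >= 1,
            label_noise_rate >= 0, label_noise_rate < 1,
            prevalence > 0, prevalence < 1,
            fraction_active_scaffolds > 0, fraction_active_scaffolds <= 1)
  if (n_scaffolds > length(.scaffold_templates)) {
    stopf("at most %d scaffold templates available",
          length(.scaffold_templates))
  }
  if (analogues_per_scaffold > length(.substituents)^3) {
    stopf("at most %d analogues per scaffold available",
          length(.substituents)^3)
  }
  if (prevalence > fraction_active_scaffolds) {
    stopf("prevalence cannot exceed fraction_active_scaffolds")
  }
  structure(list(n_scaffolds = n_scaffolds,
                 analogues_per_scaffold = analogues_per_scaffold,
                 fraction_active_scaffolds = fraction_active_scaffolds,
                 label_noise_rate = label_noise_rate,
                 prevalence = prevalence, seed = as.integer(seed)),
            class = "library_spec")
}

substitute_markers <- function(template, subs) {
  for (k in 1:3) {
    marker <- sprintf("({%d})", k)
    repl <- if (nzchar(subs[k])) paste0("(", subs[k], ")") else ""
    template <- sub(marker, repl, template, fixed = TRUE)
  }
  template
}

#' Generate a synthetic analogue-series library
#'
#' Enumerates valid molecules by decorating built-in ring-system templates
#' with acyclic substituents at three attachment points. Every generated
#' molecule parses, survives the preprocessing cascade without removals
#' (MW over 200 Da, whitelisted elements, unique structures), and carries its
#' series (scaffold) assignment and logP.
#'
#' @param spec A [library_spec()].
#' @return A `synth_library` data.frame: `id`, `smiles`, `scaffold`, `logp`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  ns <- length(.substituents)
  rows <- with_seed(derive_seed(spec$seed, "library"), {
    lapply(seq_len(spec$n_scaffolds), function(s) {
      combos <- sample.int(ns^3, spec$analogues_per_scaffold) - 1L
      smi <- vapply(combos, function(cd) {
        subs <- .substituents[c(cd %% ns, (cd %/% ns) %% ns,
                                cd %/% (ns^2)) + 1L]
        substitute_markers(.scaffold_templates[s], subs)
      }, character(1))
      data.frame(
        id = sprintf("S%02d_A%03d", s, seq_along(smi)),
        smiles = smi, scaffold = sprintf("scaffold%02d", s),
        stringsAsFactors = FALSE
      )
    })
  })
  lib <- do.call(rbind, rows)
  props <- ob_properties(lib$smiles)
  if (any(!props$ok)) {
    stopf("internal template error: %d generated molecules failed to parse",
          sum(!props$ok))
  }
  if (anyDuplicated(props$inchi)) {
    stopf("internal template error: %d duplicate structures generated",
          sum(duplicated(props$inchi)))
  }
  lib$logp <- props$logp
  structure(lib, class = c("synth_library", "data.frame"), spec = spec)
}

#' Assign binary activity labels to a synthetic library
#'
#' A molecule is active precisely when its scaffold belongs to the
#' active-scaffold set AND its logP exceeds a gate cutoff derived from the
#' spec: the library logP quantile chosen so that, after accounting for the
#' label-flip rate, the expected labeled prevalence matches the target.
#' Each label is then flipped independently with the spec's noise rate. The signal is therefore carried jointly by fingerprint
#' (scaffold identity) and physicochemical (lipophilicity gate) features,
#' but only the gate transfers to unseen scaffolds.
#'
#' @param library A [generate_library()] result.
#' @param spec The [library_spec()] (defaults to the one stored in
#'   `library`).
#' @return The library with added columns `rule_label` (noise-free label of
#'   the generating rule) and `label`; attributes `gate_cutoff` and
#'   `active_scaffolds`.
#' @export
assign_labels <- function(library, spec = attr(library, "spec")) {
  stopifnot(!is.null(spec))
  scaffolds <- unique(library$scaffold)
  n_active <- max(1L, round(spec$fraction_active_scaffolds * length(scaffolds)))
  active <- with_seed(derive_seed(spec$seed, "scaffolds"),
                      sample(scaffolds, n_active))
  # Noise-corrected rule prevalence: if the generating rule marks a fraction
  # p of molecules active and labels flip with probability nu, the observed
  # prevalence is p(1-nu) + (1-p)nu; invert so the labeled prevalence matches
  # the spec's target. At nu = 1/2 prevalence is 1/2 regardless; fall back to
  # the target and clamp into the attainable range.
  nu <- spec$label_noise_rate
  rule_prev <- if (abs(1 - 2 * nu) < 1e-9) {
    spec$prevalence
  } else {
    (spec$prevalence - nu) / (1 - 2 * nu)
  }
  rule_prev <- min(max(rule_prev, 0.02), spec$fraction_active_scaffolds)
  gate_q <- 1 - rule_prev / spec$fraction_active_scaffolds
  cutoff <- unname(quantile(library$logp, probs = gate_q))
  rule <- library$scaffold %in% active & library$logp > cutoff
  flip <- with_seed(derive_seed(spec$seed, "noise"),
                    stats::runif(nrow(library)) < spec$label_noise_rate)
  lab <- xor(rule, flip)
  library$rule_label <- ifelse(rule, "activator", "non_activator")
  library$label <- ifelse(lab, "activator", "non_activator")
  attr(library, "gate_cutoff") <- cutoff
  attr(library, "active_scaffolds") <- active
  attr(library, "spec") <- spec
  library
}

#' Scaffold-held-out benchmark split
#'
#' Emulates the relationship between a training screen, an in-distribution
#' test set, and a structurally shifted external test set: whole analogue
#' series are held out to form the out-of-distribution (OOD) test set (its
#' scaffolds never occur in training), and the remaining records are split
#' record-wise into training and an iid test set that shares the training
#' scaffolds. All records are standardized; the three sets are disjoint by
#' InChI.
#'
#' @param library A labeled library from [assign_labels()].
#' @param fractions Length-3 numeric (train, iid, ood), summing to 1.
#' @param seed Split seed (defaults to the spec seed).
#' @return A `benchmark_split` list: `train`, `iid_test`, `ood_test`
#'   ([labeled_dataset()]s carrying `scaffold` columns), `ood_scaffolds`,
#'   `fractions`, `seed`.
#' @export
shift_split <- function(library, fractions = c(0.6, 0.2, 0.2), seed = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, length(fractions) == 3)
  spec <- attr(library, "spec")
  seed <- seed %||% (if (!is.null(spec)) spec$seed else 1)
  scaffolds <- unique(library$scaffold)
  if (length(scaffolds) < 4) stopf("need at least 4 scaffolds to hold out")
  n <- nrow(library)
  sizes <- table(library$scaffold)

  split_ids <- with_seed(derive_seed(seed, "split"), {
    target_ood <- fractions[3] * n
    shuffled <- sample(scaffolds)
    ood_sc <- character(0)
    count <- 0
    for (sc in shuffled) {
      if (length(ood_sc) >= length(scaffolds) - 1) break
      new_count <- count + sizes[[sc]]
      if (abs(new_count - target_ood) <= abs(count - target_ood)) {
        ood_sc <- c(ood_sc, sc)
        count <- new_count
      } else {
        break
      }
    }
    if (length(ood_sc) == 0) ood_sc <- shuffled[1]
    rest <- which(!(library$scaffold %in% ood_sc))
    n_iid <- round(n * fractions[2])
    iid_idx <- sample(rest, min(n_iid, length(rest) - 1))
    list(ood_sc = ood_sc, iid_idx = iid_idx)
  })
  ood_sc <- split_ids$ood_sc

  std <- standardize_smiles(library$smiles, ids = library$id)
  if (any(!std$ok)) stopf("standardization failed for generated library")
  recs <- data.frame(
    id = library$id, smiles_std = std$smiles_std, inchi = std$inchi,
    label = library$label, mw = std$mw, scaffold = library$scaffold,
    logp = library$logp, stringsAsFactors = FALSE
  )
  if (anyDuplicated(recs$inchi)) {
    dup <- duplicated(recs$inchi) | duplicated(recs$inchi, fromLast = TRUE)
    stopf("generated library contains %d duplicate structures", sum(dup))
  }
  is_ood <- recs$scaffold %in% ood_sc
  is_iid <- seq_len(n) %in% split_ids$iid_idx & !is_ood
  structure(
    list(
      train = labeled_dataset(recs[!is_ood & !is_iid, , drop = FALSE], "train"),
      iid_test = labeled_dataset(recs[is_iid, , drop = FALSE], "iid_test"),
      ood_test = labeled_dataset(recs[is_ood, , drop = FALSE], "ood_test"),
      ood_scaffolds = ood_sc, fractions = fractions, seed = seed
    ),
    class = "benchmark_split"
  )
}

#' @export
print.benchmark_split <- function(x, ...) {
  cat(sprintf("<benchmark_split> train %d / iid %d / ood %d (%d held-out scaffolds)\n",
              nrow(x$train), nrow(x$iid_test), nrow(x$ood_test),
              length(x$ood_scaffolds)))
  invisible(x)
}

#' Write a benchmark split to CSV files with provenance
#'
#' @param split A [shift_split()] result.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_benchmark <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("train", "iid_test", "ood_test")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write.csv(as.data.frame(split[[nm]]), p, row.names = FALSE)
    paths <- c(paths, p)
  }
  prov <- file.path(dir, "provenance.json")
  jsonlite::write_json(
    list(ood_scaffolds = split$ood_scaffolds, fractions = split$fractions,
         seed = split$seed),
    prov, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, prov))
}
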