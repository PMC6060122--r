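# The medicine composition model: formulas (layer 1) are sets of crude
# drugs (layer 2), crude drugs are sets of constituent compounds (layer 3),
# and compounds interact with target proteins (layer 4).  Identifiers are
# opaque strings; all orderings are lexicographic so outputs are
# byte-stable.

#' Build a medicine registry
#'
#' @param compounds data frame with columns `compound_id`, `name`, and
#'   optionally `smiles`.
#' @param crude_drugs data frame of composition edges with columns
#'   `crude_drug_id`, `crude_drug_name`, `compound_id` (one row per
#'   crude-drug/compound edge).
#' @param formulas data frame of composition edges with columns
#'   `formula_id`, `formula_name`, `crude_drug_id`.
#' @return an object of class `medicine_registry`.  Construction validates
#'   referential integrity: every `compound_id` in `crude_drugs` must be in
#'   `compounds`, and every `crude_drug_id` in `formulas` must appear in
#'   `crude_drugs`.
#' @export
medicine_registry <- function(compounds, crude_drugs, formulas) {
  stopifnot(is.data.frame(compounds), is.data.frame(crude_drugs),
            is.data.frame(formulas))
  compounds <- as_chr_df(compounds, c("compound_id", "name"),
                         optional = "smiles")
  crude_drugs <- as_chr_df(crude_drugs,
                           c("crude_drug_id", "crude_drug_name", "compound_id"))
  formulas <- as_chr_df(formulas,
                        c("formula_id", "formula_name", "crude_drug_id"))
  if (anyDuplicated(compounds$compound_id)) {
    ht_abort("duplicate compound_id in compound registry",
             "ht_integrity_error")
  }
  dangling <- setdiff(crude_drugs$compound_id, compounds$compound_id)
  if (length(dangling)) {
    ht_abort(sprintf("crude-drug composition references unknown compound(s): %s",
                     paste(sort(dangling), collapse = ", ")),
             "ht_integrity_error", ids = dangling)
  }
  dangling <- setdiff(formulas$crude_drug_id, crude_drugs$crude_drug_id)
  if (length(dangling)) {
    ht_abort(sprintf("formula composition references unknown crude drug(s): %s",
                     paste(sort(dangling), collapse = ", ")),
             "ht_integrity_error", ids = dangling)
  }
  crude_drugs <- unique(crude_drugs[order(crude_drugs$crude_drug_id,
                                          crude_drugs$compound_id), ])
  formulas <- unique(formulas[order(formulas$formula_id,
                                    formulas$crude_drug_id), ])
  rownames(crude_drugs) <- rownames(formulas) <- NULL
  structure(list(compounds = compounds, crude_drugs = crude_drugs,
                 formulas = formulas),
            class = "medicine_registry")
}

as_chr_df <- function(df, cols, optional = character(0)) {
  if (!all(cols %in% names(df))) {
    ht_abort(sprintf("missing column(s): %s",
                     paste(setdiff(cols, names(df)), collapse = ", ")),
             "ht_integrity_error")
  }
  keep <- c(cols, intersect(optional, names(df)))
  df <- df[, keep, drop = FALSE]
  df[] <- lapply(df, as.character)
  df
}

#' @export
print.medicine_registry <- function(x, ...) {
  cat(sprintf("<medicine_registry: %d formulas, %d crude drugs, %d compounds>\n",
              length(unique(x$formulas$formula_id)),
              length(unique(x$crude_drugs$crude_drug_id)),
              nrow(x$compounds)))
  invisible(x)
}

#' Constituent compounds of a formula or crude drug
#'
#' @param registry a [medicine_registry()].
#' @param id a formula id or crude-drug id.
#' @return sorted character vector of compound ids.
#' @export
constituent_compounds <- function(registry, id) {
  stopifnot(inherits(registry, "medicine_registry"))
  assert_string(id, "id")
  if (id %in% registry$formulas$formula_id) {
    cds <- registry$formulas$crude_drug_id[registry$formulas$formula_id == id]
    sort(unique(
      registry$crude_drugs$compound_id[
        registry$crude_drugs$crude_drug_id %in% cds]))
  } else if (id %in% registry$crude_drugs$crude_drug_id) {
    sort(unique(
      registry$crude_drugs$compound_id[
        registry$crude_drugs$crude_drug_id == id]))
  } else if (id %in% registry$compounds$compound_id) {
    id
  } else {
    ht_abort(sprintf("unknown formula/crude-drug/compound id: '%s'", id),
             "ht_not_found_error", id = id)
  }
}

#' Union of known target proteins over a set of compounds
#'
#' @param compound_ids character vector of compound ids (may be empty).
#' @param interactome an [interactome()].
#' @return sorted character vector of protein ids: the exact union of the
#'   compounds' known targets.
#' @export
compound_target_union <- function(compound_ids, interactome) {
  stopifnot(inherits(interactome, "interactome"))
  if (length(compound_ids) == 0L) return(character(0))
  rec <- interactome$records
  sort(unique(rec$protein_id[rec$compound_id %in% compound_ids]))
}

#' Resolve the full four-layer tree for a formula
#'
#' Expands a formula into its crude drugs (layer 2), their constituent
#' compounds (layer 3), and each compound's target proteins (layer 4).
#' Layer 4 defaults to the known targets from the interactome; a table of
#' predicted targets can be supplied to include similarity-search
#' predictions.  Each node carries its provenance path from the root.
#'
#' @param registry a [medicine_registry()].
#' @param formula_id the formula to expand.
#' @param interactome an [interactome()] providing known targets.
#' @param predictions optional named list (compound id ->
#'   `target_predictions`) whose proteins are added to layer 4 with their
#'   scores.
#' @return a nested list of class `medicine_hierarchy`:
#'   `formula_id`, `name`, `crude_drugs` (each with `compounds`, each with
#'   `targets`), and `layer4`, the deduplicated union of all target
#'   proteins.
#' @export
resolve_hierarchy <- function(registry, formula_id, interactome,
                              predictions = NULL) {
  stopifnot(inherits(registry, "medicine_registry"),
            inherits(interactome, "interactome"))
  assert_string(formula_id, "formula_id")
  fed <- registry$formulas[registry$formulas$formula_id == formula_id, ,
                           drop = FALSE]
  if (nrow(fed) == 0L) {
    ht_abort(sprintf("unknown formula id: '%s'", formula_id),
             "ht_not_found_error", id = formula_id)
  }
  cname <- function(cid) {
    registry$compounds$name[match(cid, registry$compounds$compound_id)]
  }
  compound_targets <- function(cid) {
    known <- compound_target_union(cid, interactome)
    rows <- data.frame(protein_id = known,
                       score = rep(1, length(known)),
                       is_known = rep(TRUE, length(known)),
                       stringsAsFactors = FALSE)
    pred <- predictions[[cid]]
    if (!is.null(pred) && nrow(pred)) {
      extra <- pred[!pred$protein_id %in% known, , drop = FALSE]
      rows <- rbind(rows, data.frame(protein_id = extra$protein_id,
                                     score = extra$score,
                                     is_known = rep(FALSE, nrow(extra)),
                                     stringsAsFactors = FALSE))
    }
    rows[order(rows$protein_id), , drop = FALSE]
  }
  crude_nodes <- lapply(sort(unique(fed$crude_drug_id)), function(cdid) {
    ced <- registry$crude_drugs[registry$crude_drugs$crude_drug_id == cdid, ,
                                drop = FALSE]
    comp_nodes <- lapply(sort(unique(ced$compound_id)), function(cid) {
      tg <- compound_targets(cid)
      list(compound_id = cid, name = cname(cid),
           path = c(formula_id, cdid, cid),
           targets = tg)
    })
    list(crude_drug_id = cdid,
         name = ced$crude_drug_name[1L],
         path = c(formula_id, cdid),
         compounds = comp_nodes)
  })
  layer4 <- sort(unique(unlist(lapply(crude_nodes, function(cd) {
    unlist(lapply(cd$compounds, function(cp) cp$targets$protein_id))
  })) %||% character(0)))
  structure(list(formula_id = formula_id,
                 name = fed$formula_name[1L],
                 crude_drugs = crude_nodes,
                 layer4 = layer4),
            class = "medicine_hierarchy")
}

#' @export
print.medicine_hierarchy <- function(x, ...) {
  cat(sprintf("%s (%s)\n", x$formula_id, x$name))
  for (cd in x$crude_drugs) {
    cat(sprintf("  %s (%s)\n", cd$crude_drug_id, cd$name))
    for (cp in cd$compounds) {
      cat(sprintf("    %s (%s): %d target(s)\n", cp$compound_id, cp$name,
                  nrow(cp$targets)))
    }
  }
  cat(sprintf("  layer 4: %d protein(s)\n", length(x$layer4)))
  invisible(x)
}
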