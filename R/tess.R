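# TESS: target estimation based on similarity search.  Each interactome
# protein is scored for a query compound by the maximum fingerprint
# similarity between the query and the protein's known ligands; the best
# reference ligand is reported alongside the score.

#' Predict target proteins for a query compound by similarity search
#'
#' For every protein \eqn{k} in the interactome with known ligand set
#' \eqn{L_k}, the prediction score is
#' \eqn{\max_{c \in L_k} \mathrm{sim}(q, c)} where `sim` is the
#' generalized Jaccard similarity over substructure-count fingerprints.
#' When the query is itself a known ligand of the protein the score is 1
#' and the prediction is marked `is_known`.
#'
#' @param query either a compound id present in `fingerprints`, or a
#'   feature vector (optionally accompanied by `query_id` so known-ligand
#'   status can be flagged).
#' @param interactome an [interactome()].
#' @param fingerprints named list of feature vectors covering every
#'   interactome compound (missing fingerprints are a configuration error).
#' @param min_score minimum score to report (default 0: all interactome
#'   proteins are returned, ranked).
#' @param top_n optional truncation of the ranked list.
#' @param query_id optional compound id of the query, used to set
#'   `is_known`; inferred automatically when `query` is an id.
#' @return data frame of class `target_predictions` with columns
#'   `compound_id`, `protein_id`, `score`, `is_known`,
#'   `best_reference_compound_id`, sorted by (`score` desc, `protein_id`
#'   asc).
#' @export
tess_predict <- function(query, interactome, fingerprints,
                         min_score = 0, top_n = NULL, query_id = NULL) {
  stopifnot(inherits(interactome, "interactome"))
  if (length(interactome$index) == 0L) {
    ht_abort("interactome has no proteins", "ht_domain_error")
  }
  assert_fraction(min_score, "min_score")
  if (!is.null(top_n)) top_n <- assert_count(top_n, "top_n", min = 0L)
  if (is.character(query) && length(query) == 1L) {
    query_id <- query
    if (is.null(fingerprints[[query]])) {
      ht_abort(sprintf("no fingerprint for query compound '%s'", query),
               "ht_not_found_error")
    }
    query <- fingerprints[[query]]
  }
  query <- as_feature_vector(query)

  needed <- sort(unique(interactome$records$compound_id))
  missing <- setdiff(needed, names(fingerprints))
  if (length(missing)) {
    ht_abort(sprintf("missing fingerprints for interactome compound(s): %s",
                     paste(missing, collapse = ", ")),
             "ht_config_error", missing = missing)
  }

  # one similarity per interactome compound, then a per-protein max
  sims <- drop(similarity_matrix(list(q = query), fingerprints[needed]))
  names(sims) <- needed
  proteins <- names(interactome$index)
  score <- numeric(length(proteins))
  best <- character(length(proteins))
  known <- logical(length(proteins))
  for (i in seq_along(proteins)) {
    lig <- interactome$index[[i]]
    s <- sims[lig]
    j <- which.max(s)  # ties: first ligand in sorted id order
    score[i] <- s[[j]]
    best[i] <- lig[[j]]
    known[i] <- !is.null(query_id) && query_id %in% lig
  }
  out <- data.frame(
    compound_id = if (is.null(query_id)) NA_character_ else query_id,
    protein_id = proteins,
    score = score,
    is_known = known,
    best_reference_compound_id = best,
    stringsAsFactors = FALSE
  )
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(-out$score, out$protein_id), , drop = FALSE]
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("target_predictions", "data.frame")
  out
}

#' Predict targets for several compounds
#'
#' @param compound_ids character vector of query compound ids (all must
#'   have fingerprints).
#' @inheritParams tess_predict
#' @return named list of `target_predictions`, one per compound.
#' @export
tess_predict_many <- function(compound_ids, interactome, fingerprints,
                              min_score = 0, top_n = NULL) {
  out <- lapply(compound_ids, function(cid) {
    tess_predict(cid, interactome, fingerprints,
                 min_score = min_score, top_n = top_n)
  })
  names(out) <- compound_ids
  out
}

#' Aggregate per-compound predictions to a crude drug or formula
#'
#' The entity-level target set is the union over constituent compounds of
#' their predicted proteins.  Per protein the retained score is, by
#' default, the maximum across contributing compounds (preserving the best
#' single-compound evidence, consistent with the max-similarity scoring);
#' `mean` and `count` aggregations are available as alternatives.  Full
#' provenance -- every contributing (compound, score) pair -- is attached
#' as the `"contributions"` attribute.
#'
#' @param predictions named list of `target_predictions`
#'   (compound id -> prediction table), one entry per constituent compound;
#'   empty tables are allowed.
#' @param method aggregation of per-compound scores per protein:
#'   `"max"` (default), `"mean"`, or `"count"` (number of contributing
#'   compounds; not bounded by 1).
#' @return data frame with columns `protein_id`, `score`, `is_known`
#'   (any contributing compound a known ligand), `best_compound_id` and
#'   `best_reference_compound_id` (from the top-scoring contribution),
#'   `n_compounds`; sorted by (`score` desc, `protein_id` asc).
#' @export
aggregate_predictions <- function(predictions,
                                  method = c("max", "mean", "count")) {
  method <- match.arg(method)
  stopifnot(is.list(predictions))
  if (is.null(names(predictions)) && length(predictions)) {
    ht_abort("`predictions` must be named by compound id",
             "ht_integrity_error")
  }
  contrib <- do.call(rbind, c(lapply(names(predictions), function(cid) {
    p <- predictions[[cid]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    data.frame(protein_id = p$protein_id, compound_id = cid,
               score = p$score, is_known = p$is_known,
               best_reference_compound_id = p$best_reference_compound_id,
               stringsAsFactors = FALSE)
  }), list(make.row.names = FALSE)))
  if (!is.data.frame(contrib) || nrow(contrib) == 0L) {
    out <- data.frame(protein_id = character(0), score = numeric(0),
                      is_known = logical(0), best_compound_id = character(0),
                      best_reference_compound_id = character(0),
                      n_compounds = integer(0), stringsAsFactors = FALSE)
    attr(out, "contributions") <- data.frame(
      protein_id = character(0), compound_id = character(0),
      score = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  contrib <- contrib[order(contrib$protein_id, -contrib$score,
                           contrib$compound_id), , drop = FALSE]
  sp <- split(seq_len(nrow(contrib)), contrib$protein_id)
  rows <- lapply(sp, function(idx) {
    sub <- contrib[idx, , drop = FALSE]
    score <- switch(method,
      max = max(sub$score),
      mean = mean(sub$score),
      count = as.numeric(nrow(sub)))
    data.frame(protein_id = sub$protein_id[1L], score = score,
               is_known = any(sub$is_known),
               best_compound_id = sub$compound_id[1L],
               best_reference_compound_id = sub$best_reference_compound_id[1L],
               n_compounds = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$score, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "contributions") <- contrib[, c("protein_id", "compound_id",
                                            "score")]
  out
}
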