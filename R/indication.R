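# Indication prediction by target matching: a compound is linked to a
# disease through every protein shared between the compound's target list
# (known + predicted) and the disease's therapeutic-target set.  A link
# through a known target scores 1; a link through a predicted target
# carries its similarity-search score.

#' Construct a disease-target association map
#'
#' @param associations data frame with columns `disease_id`,
#'   `disease_name`, `protein_id`; duplicate (disease, protein) pairs are
#'   collapsed.
#' @return object of class `disease_target_map`.
#' @export
disease_target_map <- function(associations) {
  associations <- as_chr_df(associations,
                            c("disease_id", "disease_name", "protein_id"))
  key <- paste(associations$disease_id, associations$protein_id, sep = "\r")
  associations <- associations[!duplicated(key), , drop = FALSE]
  associations <- associations[order(associations$disease_id,
                                     associations$protein_id), , drop = FALSE]
  rownames(associations) <- NULL
  structure(list(associations = associations), class = "disease_target_map")
}

#' @export
print.disease_target_map <- function(x, ...) {
  cat(sprintf("<disease_target_map: %d associations, %d diseases, %d proteins>\n",
              nrow(x$associations),
              length(unique(x$associations$disease_id)),
              length(unique(x$associations$protein_id))))
  invisible(x)
}

#' Predict applicable diseases for a compound from its target list
#'
#' Every target protein of the query that appears in the disease-target
#' map produces one link per associated disease.  The link score is 1 when
#' the protein is a known target of the query and the prediction score
#' otherwise.  Diseases are ranked by their maximum link score (ties
#' broken by disease id); the full link table is returned so alternative
#' aggregations remain recomputable.
#'
#' @param targets a `target_predictions` data frame (columns `protein_id`,
#'   `score`, `is_known`; typically from [tess_predict()] or
#'   [aggregate_predictions()]).
#' @param disease_map a [disease_target_map()].
#' @return list of class `indication_result` with elements
#'   `diseases` (data frame `disease_id`, `disease_name`, `best_score`,
#'   `n_links`, ranked by score desc then id) and `links` (data frame
#'   `disease_id`, `protein_id`, `score`, `via_known`, plus `compound_id`
#'   when present in `targets`).
#' @export
predict_indications <- function(targets, disease_map) {
  stopifnot(is.data.frame(targets), inherits(disease_map, "disease_target_map"))
  needed <- c("protein_id", "score", "is_known")
  if (!all(needed %in% names(targets))) {
    ht_abort("`targets` needs columns protein_id, score, is_known",
             "ht_integrity_error")
  }
  assoc <- disease_map$associations
  hit <- assoc[assoc$protein_id %in% targets$protein_id, , drop = FALSE]
  if (nrow(targets) == 0L || nrow(hit) == 0L) {
    out <- list(
      diseases = data.frame(disease_id = character(0),
                            disease_name = character(0),
                            best_score = numeric(0), n_links = integer(0),
                            stringsAsFactors = FALSE),
      links = data.frame(disease_id = character(0), protein_id = character(0),
                         score = numeric(0), via_known = logical(0),
                         stringsAsFactors = FALSE))
    class(out) <- "indication_result"
    return(out)
  }
  ti <- match(hit$protein_id, targets$protein_id)
  links <- data.frame(
    disease_id = hit$disease_id,
    disease_name = hit$disease_name,
    protein_id = hit$protein_id,
    score = ifelse(targets$is_known[ti], 1, targets$score[ti]),
    via_known = targets$is_known[ti],
    stringsAsFactors = FALSE
  )
  if ("compound_id" %in% names(targets)) {
    links$compound_id <- targets$compound_id[ti]
  }
  links <- links[order(links$disease_id, -links$score, links$protein_id), ,
                 drop = FALSE]
  rownames(links) <- NULL
  best <- tapply(links$score, links$disease_id, max)
  nlinks <- tapply(links$score, links$disease_id, length)
  diseases <- data.frame(
    disease_id = names(best),
    disease_name = links$disease_name[match(names(best), links$disease_id)],
    best_score = as.numeric(best),
    n_links = as.integer(nlinks),
    stringsAsFactors = FALSE
  )
  diseases <- diseases[order(-diseases$best_score, diseases$disease_id), ,
                       drop = FALSE]
  rownames(diseases) <- NULL
  out <- list(diseases = diseases, links = links)
  class(out) <- "indication_result"
  out
}

#' @export
print.indication_result <- function(x, ...) {
  cat(sprintf("<indication_result: %d diseases, %d links>\n",
              nrow(x$diseases), nrow(x$links)))
  if (nrow(x$diseases)) print(utils::head(x$diseases, 5L))
  invisible(x)
}
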