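# The compound-protein interactome: known interaction records with activity
# evidence, filtered to confident pairs and indexed protein -> known ligands.

#' Build an interactome from interaction records
#'
#' Records are deduplicated on `(compound_id, protein_id)`; when duplicates
#' disagree, the record with the lowest affinity (strongest evidence) is
#' kept, and a flagged-active duplicate keeps the active flag.  The derived
#' index maps each protein to the sorted set of its known ligand compounds.
#'
#' @param records data frame with columns `compound_id`, `protein_id`,
#'   `affinity_nM` (numeric, `NA` allowed, `> 0` when present),
#'   `active_flag` (logical or 0/1), and optionally `source`.
#' @return an object of class `interactome`: a list with elements
#'   `records` (the deduplicated table) and `index` (named list
#'   `protein_id -> character vector of ligand compound ids`).
#' @seealso [filter_interactome()] for the activity-evidence filter that is
#'   normally applied first.
#' @export
interactome <- function(records) {
  records <- normalize_interaction_records(records)
  if (any(!is.na(records$affinity_nM) & records$affinity_nM <= 0)) {
    ht_abort("`affinity_nM` must be > 0 when present", "ht_domain_error")
  }
  if (nrow(records)) {
    # dedup keeping strongest evidence: lowest affinity first (NA last),
    # active flag preserved if any duplicate carried it
    key <- paste(records$compound_id, records$protein_id, sep = "\r")
    any_active <- tapply(records$active_flag, key, any)
    o <- order(key, is.na(records$affinity_nM), records$affinity_nM)
    records <- records[o, , drop = FALSE]
    keep <- !duplicated(key[o])
    records <- records[keep, , drop = FALSE]
    records$active_flag <- as.logical(
      any_active[paste(records$compound_id, records$protein_id, sep = "\r")])
    records <- records[order(records$protein_id, records$compound_id), ,
                       drop = FALSE]
    rownames(records) <- NULL
  }
  index <- lapply(
    split(records$compound_id, records$protein_id),
    function(x) sort(unique(x)))
  structure(list(records = records, index = index), class = "interactome")
}

normalize_interaction_records <- function(records) {
  stopifnot(is.data.frame(records))
  required <- c("compound_id", "protein_id")
  if (!all(required %in% names(records))) {
    ht_abort("interaction records need columns compound_id, protein_id",
             "ht_integrity_error")
  }
  n <- nrow(records)
  if (is.null(records$affinity_nM)) records$affinity_nM <- rep(NA_real_, n)
  if (is.null(records$active_flag)) records$active_flag <- rep(FALSE, n)
  if (is.null(records$source)) records$source <- rep("", n)
  records$compound_id <- as.character(records$compound_id)
  records$protein_id <- as.character(records$protein_id)
  records$affinity_nM <- as.numeric(records$affinity_nM)
  records$active_flag <- !is.na(records$active_flag) &
    (as.numeric(records$active_flag) != 0)
  records$source <- as.character(records$source)
  records[, c("compound_id", "protein_id", "affinity_nM", "active_flag",
              "source")]
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("<interactome: %d interactions, %d compounds, %d proteins>\n",
              nrow(x$records), length(unique(x$records$compound_id)),
              length(x$index)))
  invisible(x)
}

#' Filter raw interaction records to confident active interactions
#'
#' A record is kept iff it is flagged active or its measured affinity is
#' strictly below the threshold (default 30 uM = 30000 nM).  Records with
#' neither an affinity nor an active flag carry no usable evidence and are
#' dropped (their count is reported in a message, not an error).
#'
#' @param records data frame of raw interaction records (see
#'   [interactome()]).
#' @param threshold_nM strict upper bound on affinity, in nM; the default
#'   30000 nM corresponds to the conventional 30 uM activity cutoff.
#' @return an `interactome` built from the retained records.
#' @export
filter_interactome <- function(records, threshold_nM = 30000) {
  records <- normalize_interaction_records(records)
  if (!is.numeric(threshold_nM) || length(threshold_nM) != 1L ||
      is.na(threshold_nM) || threshold_nM <= 0) {
    ht_abort("`threshold_nM` must be a single positive number",
             "ht_domain_error")
  }
  no_evidence <- is.na(records$affinity_nM) & !records$active_flag
  if (any(no_evidence)) {
    message(sprintf("dropping %d record(s) with neither affinity nor active flag",
                    sum(no_evidence)))
  }
  keep <- records$active_flag |
    (!is.na(records$affinity_nM) & records$affinity_nM < threshold_nM)
  interactome(records[keep, , drop = FALSE])
}

#' Known ligand set of a protein
#' @param x an `interactome`.
#' @param protein_id protein identifier.
#' @return sorted character vector of compound ids (empty if none).
#' @export
ligands_of <- function(x, protein_id) {
  stopifnot(inherits(x, "interactome"))
  x$index[[protein_id]] %||% character(0)
}
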