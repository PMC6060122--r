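# Readers and writers for the interchange formats.  All tables are UTF-8
# TSV with a header row; missing values are empty fields.  Every writer's
# output is accepted by its paired reader (round-trip identity).

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    ht_abort(sprintf("file not found: '%s'", path), "ht_not_found_error")
  }
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          check.names = FALSE, na.strings = NULL,
                          fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    ht_abort(sprintf("'%s' is missing column(s): %s", path,
                     paste(missing, collapse = ", ")),
             "ht_parse_error")
  }
  df
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer,
                                                      logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.10g", x))
  })
  lg <- vapply(df, is.logical, logical(1))
  df[lg] <- lapply(df[lg], function(x) as.integer(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a compound registry table
#'
#' Columns: `compound_id`, `name`, optional `smiles`.
#' @param path file path.
#' @return data frame of compounds.
#' @export
read_compounds <- function(path) {
  df <- read_tsv_checked(path, c("compound_id", "name"))
  if (is.null(df$smiles)) df$smiles <- ""
  df[, c("compound_id", "name", "smiles")]
}

#' @rdname read_compounds
#' @param compounds compound table to write.
#' @export
write_compounds <- function(compounds, path) write_tsv(compounds, path)

#' Read / write sparse fingerprints
#'
#' Long-format TSV with columns `compound_id`, `feature_id`, `count`; one
#' row per nonzero feature.
#' @param path file path.
#' @return named list of feature vectors.
#' @export
read_fingerprints <- function(path) {
  df <- read_tsv_checked(path, c("compound_id", "feature_id", "count"))
  cnt <- suppressWarnings(as.numeric(df$count))
  if (anyNA(cnt)) {
    bad <- which(is.na(cnt))[1L]
    ht_abort(sprintf("'%s': non-numeric count at data line %d", path, bad),
             "ht_parse_error")
  }
  sp <- split(seq_len(nrow(df)), df$compound_id)
  out <- lapply(sp, function(idx) {
    feature_vector(stats::setNames(cnt[idx], df$feature_id[idx]))
  })
  out[order(names(out))]
}

#' @rdname read_fingerprints
#' @param fingerprints named list of feature vectors to write.
#' @export
write_fingerprints <- function(fingerprints, path) {
  rows <- lapply(sort(names(fingerprints)), function(cid) {
    fv <- fingerprints[[cid]]
    if (length(fv) == 0L) return(NULL)
    data.frame(compound_id = cid, feature_id = names(fv),
               count = as.numeric(fv), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows) %||%
    data.frame(compound_id = character(0), feature_id = character(0),
               count = numeric(0))
  write_tsv(df, path)
}

#' Read / write an interaction record table
#'
#' Columns: `compound_id`, `protein_id`, `affinity_nM` (empty allowed),
#' `active_flag` (0/1), `source`.
#' @param path file path.
#' @return data frame of raw interaction records (pass to
#'   [filter_interactome()] or [interactome()]).
#' @export
read_interactions <- function(path) {
  df <- read_tsv_checked(path, c("compound_id", "protein_id"))
  if (is.null(df$affinity_nM)) df$affinity_nM <- ""
  if (is.null(df$active_flag)) df$active_flag <- "0"
  if (is.null(df$source)) df$source <- ""
  df$affinity_nM <- suppressWarnings(
    as.numeric(ifelse(df$affinity_nM == "", NA, df$affinity_nM)))
  df$active_flag <- suppressWarnings(as.integer(df$active_flag)) != 0L
  normalize_interaction_records(df)
}

#' @rdname read_interactions
#' @param records record table to write.
#' @export
write_interactions <- function(records, path) {
  write_tsv(normalize_interaction_records(records), path)
}

#' Read composition tables
#'
#' `formulas.tsv` has columns `formula_id`, `formula_name`,
#' `crude_drug_id`; `crude_drugs.tsv` has `crude_drug_id`,
#' `crude_drug_name`, `compound_id`; one row per composition edge.
#' @param formulas_path,crude_drugs_path,compounds_path file paths.
#' @return a [medicine_registry()].
#' @export
read_registry <- function(compounds_path, crude_drugs_path, formulas_path) {
  medicine_registry(
    read_compounds(compounds_path),
    read_tsv_checked(crude_drugs_path,
                     c("crude_drug_id", "crude_drug_name", "compound_id")),
    read_tsv_checked(formulas_path,
                     c("formula_id", "formula_name", "crude_drug_id")))
}

#' @rdname read_registry
#' @param registry registry to write (three files).
#' @export
write_registry <- function(registry, compounds_path, crude_drugs_path,
                           formulas_path) {
  stopifnot(inherits(registry, "medicine_registry"))
  write_compounds(registry$compounds, compounds_path)
  write_tsv(registry$crude_drugs, crude_drugs_path)
  write_tsv(registry$formulas, formulas_path)
  invisible(NULL)
}

#' Read / write an annotation namespace in GMT format
#'
#' GMT: one term per line, tab-separated
#' `term_id<TAB>term_name<TAB>protein_id...` with at least one protein.
#' Duplicate proteins within a term are deduplicated with a warning;
#' a line with fewer than three fields is a parse error naming the line.
#'
#' @param path file path.
#' @param namespace namespace tag (`"pathway"`, `"brite"`, `"process"`,
#'   `"function"`).
#' @return an [annotation_namespace()].
#' @export
read_gmt <- function(path, namespace = "pathway") {
  if (!file.exists(path)) {
    ht_abort(sprintf("file not found: '%s'", path), "ht_not_found_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list(); term_names <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L || any(!nzchar(f[1:3]))) {
      ht_abort(sprintf("'%s': malformed GMT line %d (need id, name, >=1 protein)",
                       path, i), "ht_parse_error", line = i)
    }
    prot <- f[-(1:2)]
    prot <- prot[nzchar(prot)]
    if (anyDuplicated(prot)) {
      ht_warn(sprintf("'%s' line %d: duplicate protein id(s) in term '%s'",
                      path, i, f[1]), "ht_duplicate_warning")
      prot <- unique(prot)
    }
    terms[[f[1]]] <- prot
    term_names[f[1]] <- f[2]
  }
  annotation_namespace(terms, term_names, namespace)
}

#' @rdname read_gmt
#' @param ns annotation namespace to write.
#' @export
write_gmt <- function(ns, path) {
  stopifnot(inherits(ns, "annotation_namespace"))
  lines <- vapply(names(ns$terms), function(tid) {
    paste(c(tid, ns$term_names[[tid]], ns$terms[[tid]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a disease-target association table
#'
#' Columns: `disease_id`, `disease_name`, `protein_id`.
#' @param path file path.
#' @return a [disease_target_map()].
#' @export
read_disease_map <- function(path) {
  disease_target_map(read_tsv_checked(
    path, c("disease_id", "disease_name", "protein_id")))
}

#' @rdname read_disease_map
#' @param disease_map map to write.
#' @export
write_disease_map <- function(disease_map, path) {
  stopifnot(inherits(disease_map, "disease_target_map"))
  write_tsv(disease_map$associations, path)
}

#' Read / write a target-prediction table
#'
#' Columns: `compound_id`, `protein_id`, `score`, `is_known` (0/1),
#' `best_reference_compound_id`.
#' @param path file path.
#' @return `target_predictions` data frame.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_checked(path, c("protein_id", "score", "is_known"))
  if (is.null(df$compound_id)) df$compound_id <- NA_character_
  if (is.null(df$best_reference_compound_id)) {
    df$best_reference_compound_id <- NA_character_
  }
  df$score <- as.numeric(df$score)
  df$is_known <- as.integer(df$is_known) != 0L
  df <- df[, c("compound_id", "protein_id", "score", "is_known",
               "best_reference_compound_id")]
  class(df) <- c("target_predictions", "data.frame")
  df
}

#' @rdname read_predictions
#' @param predictions prediction table to write.
#' @export
write_predictions <- function(predictions, path) {
  write_tsv(as.data.frame(predictions), path)
}

#' Export a resolved hierarchy as JSON
#'
#' @param hierarchy a `medicine_hierarchy` from [resolve_hierarchy()].
#' @param path output path; when `NULL` the JSON string is returned.
#' @return the path (invisibly) or the JSON string.
#' @export
hierarchy_to_json <- function(hierarchy, path = NULL) {
  stopifnot(inherits(hierarchy, "medicine_hierarchy"))
  x <- unclass(hierarchy)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Write a simulated bundle to a directory
#'
#' Emits `compounds.tsv`, `fingerprints.tsv`, `interactions.tsv` (raw,
#' pre-filter), `crude_drugs.tsv`, `formulas.tsv`, one GMT per namespace
#' (`pathway.gmt`, ...), `disease_targets.tsv`, and `ground_truth.json`.
#'
#' @param bundle a `synth_bundle` from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synth_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_registry(bundle$registry, p("compounds.tsv"), p("crude_drugs.tsv"),
                 p("formulas.tsv"))
  write_fingerprints(bundle$fingerprints, p("fingerprints.tsv"))
  write_interactions(bundle$records, p("interactions.tsv"))
  for (tag in names(bundle$namespaces)) {
    write_gmt(bundle$namespaces[[tag]], p(paste0(tag, ".gmt")))
  }
  write_disease_map(bundle$diseases, p("disease_targets.tsv"))
  truth <- bundle$truth
  truth$compound_family <- as.list(truth$compound_family)
  truth$protein_family <- as.list(truth$protein_family)
  truth$planted_term <- as.list(truth$planted_term)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             p("ground_truth.json"), useBytes = TRUE)
  invisible(dir)
}

#' Read a bundle directory back into memory
#'
#' @param dir a directory written by [write_bundle()].
#' @return list with `fingerprints`, `records`, `interactome` (filtered at
#'   the default 30 uM cutoff), `registry`, `namespaces`, `diseases`.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  records <- read_interactions(p("interactions.tsv"))
  ns_tags <- c("pathway", "brite", "process", "function")
  namespaces <- lapply(ns_tags, function(tag) {
    read_gmt(p(paste0(tag, ".gmt")), namespace = tag)
  })
  names(namespaces) <- ns_tags
  list(
    fingerprints = read_fingerprints(p("fingerprints.tsv")),
    records = records,
    interactome = suppressMessages(filter_interactome(records)),
    registry = read_registry(p("compounds.tsv"), p("crude_drugs.tsv"),
                             p("formulas.tsv")),
    namespaces = namespaces,
    diseases = read_disease_map(p("disease_targets.tsv"))
  )
}

#' Run a functional-enrichment analysis for a query entity
#'
#' Resolves the query (formula, crude drug, or compound) to its
#' constituent compounds, builds the target set `G_comp` as the union of
#' their known targets (optionally extended by similarity-search
#' predictions above a score cutoff), and runs the hypergeometric
#' enrichment against the selected namespace.  The background universe
#' defaults to the interactome's known-target universe.
#'
#' @param query a formula, crude-drug, or compound id.
#' @param registry a [medicine_registry()].
#' @param interactome an [interactome()].
#' @param namespace an [annotation_namespace()].
#' @param fingerprints optional fingerprints; when supplied together with
#'   `min_score < 1`, predicted targets with score `>= min_score` are
#'   added to `G_comp`.
#' @param min_score score cutoff for including predicted targets
#'   (default 1: known targets only).
#' @param background optional background universe override.
#' @return an `enrichment_result` (see [enrich()]); empty (with a
#'   warning) when the query has no targets.
#' @export
run_functional_analysis <- function(query, registry, interactome, namespace,
                                    fingerprints = NULL, min_score = 1,
                                    background = NULL) {
  compounds <- constituent_compounds(registry, query)
  g_comp <- compound_target_union(compounds, interactome)
  if (is.null(background)) background <- sort(names(interactome$index))
  if (!is.null(fingerprints) && min_score < 1) {
    preds <- tess_predict_many(compounds, interactome, fingerprints,
                               min_score = min_score)
    agg <- aggregate_predictions(preds)
    g_comp <- sort(unique(c(g_comp, agg$protein_id)))
  }
  g_comp <- intersect(g_comp, background)
  enrich(g_comp, namespace, background = background)
}
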