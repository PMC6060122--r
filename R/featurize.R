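# Pluggable structure featurizer: counted linear-path substructures.
#
# The canonical descriptor space for this kind of similarity search is a
# counted chemical-substructure scheme of very high dimension, generated
# from a curated chemical ontology that cannot be recomputed offline.  The
# pipeline, however, only requires *some* deterministic sparse
# substructure-count vector, and precomputed fingerprint files are
# first-class input (see [read_fingerprints()]).  This featurizer is the
# built-in stand-in: it enumerates all simple linear paths of the heavy-atom
# graph up to a maximum bond length and counts each canonical path label.

#' Featurize a structure string into a counted-substructure vector
#'
#' Parses a SMILES string (via \pkg{ChemmineR}/Open Babel) and counts all
#' simple linear paths of the heavy-atom graph up to `max_path` bonds.
#' Each path is labelled by its element symbols and bond orders, reading
#' direction canonicalized lexicographically, so the same structure always
#' yields the same vector.
#'
#' @param structure a single SMILES string.
#' @param max_path maximum number of bonds in a counted path (default 3).
#' @return a [feature_vector()] of path counts.  A structure with a single
#'   heavy atom yields the single length-0 path feature for that atom.
#' @examples
#' \donttest{
#' fp <- featurize("CCO")
#' generalized_jaccard(featurize("CCO"), featurize("CCO"))  # 1
#' }
#' @export
featurize <- function(structure, max_path = 3L) {
  assert_string(structure, "structure")
  max_path <- assert_count(max_path, "max_path", min = 1L)
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    ht_abort("package 'ChemmineR' is required for SMILES featurization",
             "ht_config_error")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(structure)),
    error = function(e) NULL
  )
  atoms <- if (is.null(sdf)) NULL else tryCatch(
    ChemmineR::atomblock(sdf[[1]]), error = function(e) NULL)
  if (is.null(atoms) || nrow(atoms) == 0L) {
    ht_abort(sprintf("could not parse structure string: '%s'", structure),
             "ht_parse_error", structure = structure)
  }
  if (!any(grepl("_", rownames(atoms), fixed = TRUE))) {
    # bond-less molecule: ChemmineR returns a placeholder block, so read
    # the element symbols straight from the Open Babel molblock
    elements <- molblock_elements(structure)
    if (length(elements) == 0L) {
      ht_abort(sprintf("could not parse structure string: '%s'", structure),
               "ht_parse_error", structure = structure)
    }
    bonds <- NULL
  } else {
    elements <- sub("_[0-9]+$", "", rownames(atoms))
    bonds <- tryCatch(ChemmineR::bondblock(sdf[[1]]), error = function(e) NULL)
  }
  # adjacency with bond orders
  n <- length(elements)
  adj <- vector("list", n)
  ord <- vector("list", n)
  # a bond-less molecule yields a placeholder block with < 3 columns
  if (!is.null(bonds) && is.matrix(bonds) && nrow(bonds) > 0L &&
      ncol(bonds) >= 3L) {
    for (b in seq_len(nrow(bonds))) {
      a1 <- as.integer(bonds[b, 1]); a2 <- as.integer(bonds[b, 2])
      o <- as.integer(bonds[b, 3])
      if (a1 < 1L || a2 < 1L || a1 > n || a2 > n) next
      adj[[a1]] <- c(adj[[a1]], a2); ord[[a1]] <- c(ord[[a1]], o)
      adj[[a2]] <- c(adj[[a2]], a1); ord[[a2]] <- c(ord[[a2]], o)
    }
  }
  labels <- character(0)
  # depth-first enumeration of simple paths starting at every atom; each
  # path of >= 1 bond is seen twice (once per direction) so counts are
  # halved for those, while single-atom paths are counted once.
  walk <- function(path, bond_orders) {
    last <- path[length(path)]
    lab <- path_label(elements, path, bond_orders)
    labels[[length(labels) + 1L]] <<- lab
    if (length(path) > max_path) return(invisible())
    nb <- adj[[last]]; no <- ord[[last]]
    for (j in seq_along(nb)) {
      if (nb[j] %in% path) next
      walk(c(path, nb[j]), c(bond_orders, no[j]))
    }
  }
  for (a in seq_len(n)) walk(a, integer(0))
  counts <- table(labels)
  nb_bonds <- lengths(regmatches(names(counts), gregexpr(":", names(counts))))
  vals <- as.numeric(counts)
  vals[nb_bonds > 0L] <- vals[nb_bonds > 0L] / 2
  feature_vector(stats::setNames(vals, names(counts)))
}

# Element symbols of a V2000 molblock's atom lines (used only for
# bond-less molecules, which ChemmineR's SDF container rejects).
molblock_elements <- function(smiles) {
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", smiles),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(character(0))
  n_atoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  if (is.na(n_atoms) || n_atoms < 1L || length(lines) < 4L + n_atoms) {
    return(character(0))
  }
  vapply(lines[5:(4L + n_atoms)], function(ln) {
    strsplit(trimws(ln), "[[:space:]]+")[[1]][4]
  }, character(1), USE.NAMES = FALSE)
}

# Canonical label of a linear path: element/bond sequence, read in the
# lexicographically smaller of the two directions.
path_label <- function(elements, path, bond_orders) {
  seps <- if (length(bond_orders)) paste0(":", bond_orders) else character(0)
  fwd <- paste(elements[path], c(seps, "")[seq_along(path)],
               sep = "", collapse = "")
  bwd <- paste(elements[rev(path)], c(rev(seps), "")[seq_along(path)],
               sep = "", collapse = "")
  min(fwd, bwd)
}

#' Featurize a compound registry table
#'
#' @param compounds data frame with columns `compound_id` and `smiles`.
#' @param max_path passed to [featurize()].
#' @return named list of feature vectors keyed by `compound_id`; compounds
#'   with an empty `smiles` field are skipped.
#' @export
featurize_compounds <- function(compounds, max_path = 3L) {
  stopifnot(is.data.frame(compounds),
            all(c("compound_id", "smiles") %in% names(compounds)))
  keep <- !is.na(compounds$smiles) & nzchar(compounds$smiles)
  out <- lapply(compounds$smiles[keep], featurize, max_path = max_path)
  names(out) <- compounds$compound_id[keep]
  out
}
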