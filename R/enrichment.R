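# Functional enrichment of a target-protein set against annotation term
# sets (pathways, protein classifications, GO process/function), using the
# upper-tail hypergeometric test with Benjamini-Hochberg FDR control.

#' Upper-tail hypergeometric probability
#'
#' Probability of observing an intersection of size at least `z` between a
#' term set of size `k` and a query set of size `r` drawn from a universe
#' of `l` proteins:
#' \deqn{p = \sum_{i=z}^{\min(k,r)} \binom{k}{i}\binom{l-k}{r-i} / \binom{l}{r}.}
#'
#' @param l universe (background) size.
#' @param k term-set size, `0 <= k <= l`.
#' @param r query-set size, `0 <= r <= l`.
#' @param z observed intersection size, `0 <= z <= min(k, r)`.
#' @return the tail probability \eqn{P(X \ge z)}; exactly 1 when `z = 0`.
#' @examples
#' hypergeom_tail(10, 4, 5, 3)  # 66/252
#' @export
hypergeom_tail <- function(l, k, r, z) {
  l <- assert_count(l, "l"); k <- assert_count(k, "k")
  r <- assert_count(r, "r"); z <- assert_count(z, "z")
  if (k > l) ht_abort("`k` must satisfy 0 <= k <= l", "ht_domain_error")
  if (r > l) ht_abort("`r` must satisfy 0 <= r <= l", "ht_domain_error")
  if (z > min(k, r)) {
    ht_abort("`z` must satisfy 0 <= z <= min(k, r)", "ht_domain_error")
  }
  if (z == 0L) return(1)
  # P(X >= z) with X ~ Hypergeometric(l, k, r)
  stats::phyper(z - 1L, m = k, n = l - k, k = r, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; the returned vector is aligned
#' with the input positions, satisfies `q >= p` and `q <= 1`, and is
#' invariant (up to position mapping) under permutation of the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) {
    ht_abort("p-values must lie in [0, 1]", "ht_domain_error")
  }
  stats::p.adjust(p, method = "BH")
}

#' Annotation namespace (term -> protein sets)
#'
#' @param terms named list of character vectors: `term_id -> protein ids`;
#'   every set must be non-empty.
#' @param term_names named character vector `term_id -> display name`
#'   (defaults to the ids).
#' @param namespace one of `"pathway"`, `"brite"`, `"process"`,
#'   `"function"`.
#' @return object of class `annotation_namespace`.
#' @export
annotation_namespace <- function(terms, term_names = NULL,
                                 namespace = c("pathway", "brite",
                                               "process", "function")) {
  namespace <- match.arg(namespace)
  stopifnot(is.list(terms))
  if (length(terms) && (is.null(names(terms)) || any(!nzchar(names(terms))))) {
    ht_abort("terms must be named by term id", "ht_integrity_error")
  }
  if (any(lengths(terms) == 0L)) {
    ht_abort("every term set must be non-empty", "ht_integrity_error")
  }
  terms <- lapply(terms, function(x) sort(unique(as.character(x))))
  terms <- terms[order(names(terms))]
  if (is.null(term_names)) {
    term_names <- stats::setNames(names(terms), names(terms))
  }
  term_names <- term_names[names(terms)]
  structure(list(namespace = namespace, terms = terms,
                 term_names = term_names),
            class = "annotation_namespace")
}

#' @export
print.annotation_namespace <- function(x, ...) {
  cat(sprintf("<annotation_namespace '%s': %d terms, %d proteins>\n",
              x$namespace, length(x$terms),
              length(unique(unlist(x$terms)))))
  invisible(x)
}

#' Hypergeometric enrichment of a target set against a namespace
#'
#' For each term, computes the intersection size `z` between the query
#' target set `g_comp` and the term's protein set, the enrichment ratio
#' `z / k` (the fraction of the term's proteins hit by the query), and the
#' upper-tail hypergeometric p-value on the background universe; q-values
#' are Benjamini-Hochberg over all tested terms of the namespace.
#'
#' Both the query set and the term sets are restricted to the background
#' universe before testing (the hypergeometric model requires it); terms
#' that fall entirely outside the background are excluded with a message.
#'
#' @param g_comp character vector of query target protein ids.
#' @param namespace an [annotation_namespace()].
#' @param background character vector: the protein universe.  Defaults to
#'   the union of all proteins in the namespace with `g_comp`; in a full
#'   analysis pass it is the interactome's known-target universe.
#' @return data frame of class `enrichment_result`, one row per tested
#'   term, columns `term_id`, `term_name`, `z`, `k`, `r`, `l`, `ratio`,
#'   `p_value`, `q_value`; sorted by (`p_value` asc, `term_id` asc).
#' @export
enrich <- function(g_comp, namespace, background = NULL) {
  stopifnot(inherits(namespace, "annotation_namespace"))
  g_comp <- sort(unique(as.character(g_comp)))
  if (length(namespace$terms) == 0L) {
    ht_abort("annotation namespace has no terms", "ht_domain_error")
  }
  if (is.null(background)) {
    background <- sort(unique(c(unlist(namespace$terms), g_comp)))
  }
  background <- sort(unique(as.character(background)))
  outside <- setdiff(g_comp, background)
  if (length(outside)) {
    ht_abort(sprintf("query protein(s) outside the background universe: %s",
                     paste(outside, collapse = ", ")),
             "ht_integrity_error", ids = outside)
  }
  empty_cols <- data.frame(term_id = character(0), term_name = character(0),
                           z = integer(0), k = integer(0), r = integer(0),
                           l = integer(0), ratio = numeric(0),
                           p_value = numeric(0), q_value = numeric(0),
                           stringsAsFactors = FALSE)
  if (length(g_comp) == 0L) {
    ht_warn("empty query target set: empty enrichment result",
            "ht_empty_query_warning")
    class(empty_cols) <- c("enrichment_result", "data.frame")
    return(empty_cols)
  }
  l <- length(background)
  r <- length(g_comp)
  restricted <- lapply(namespace$terms, intersect, background)
  ks <- lengths(restricted)
  if (any(ks == 0L)) {
    message(sprintf("excluding %d term(s) entirely outside the background",
                    sum(ks == 0L)))
  }
  keep <- names(restricted)[ks > 0L]
  if (length(keep) == 0L) {
    class(empty_cols) <- c("enrichment_result", "data.frame")
    return(empty_cols)
  }
  zs <- vapply(restricted[keep],
               function(tp) length(intersect(tp, g_comp)), integer(1))
  ks <- ks[keep]
  ps <- vapply(seq_along(keep), function(i) {
    hypergeom_tail(l, ks[[i]], r, zs[[i]])
  }, numeric(1))
  out <- data.frame(
    term_id = keep,
    term_name = as.character(namespace$term_names[keep]),
    z = as.integer(zs), k = as.integer(ks), r = r, l = l,
    ratio = zs / ks,
    p_value = ps,
    q_value = bh_fdr(ps),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}
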