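# Sparse substructure-frequency fingerprints and the generalized Jaccard
# similarity that drives the similarity-search target prediction.

#' Construct a sparse feature vector
#'
#' A compound fingerprint is a sparse nonnegative frequency vector over
#' substructure features, stored as a named numeric vector (names are
#' feature identifiers, values are counts or frequencies).  Zero entries
#' are dropped; an empty vector is permitted only for explicitly degenerate
#' compounds (e.g. featureless structures) and is flagged as such.
#'
#' @param counts named numeric vector of feature counts (all `>= 0`).
#' @return a named numeric vector of class `feature_vector` with zero
#'   entries removed, sorted by feature identifier.
#' @examples
#' feature_vector(c(a = 2, b = 1, c = 0))
#' @export
feature_vector <- function(counts) {
  if (length(counts) == 0L) {
    fv <- structure(numeric(0), names = character(0))
    class(fv) <- "feature_vector"
    return(fv)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    ht_abort("feature counts must be named by feature identifier",
             "ht_domain_error")
  }
  if (anyNA(counts) || any(counts < 0)) {
    ht_abort("feature counts must be nonnegative and non-missing",
             "ht_domain_error")
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  counts <- counts[counts > 0]
  if (anyDuplicated(names(counts))) {
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  }
  fv <- counts[order(names(counts))]
  class(fv) <- "feature_vector"
  fv
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector: %d features, total count %g>\n",
              length(x), sum(x)))
  if (length(x)) print(utils::head(stats::setNames(as.numeric(x), names(x)), 10L))
  invisible(x)
}

as_feature_vector <- function(x) {
  if (inherits(x, "feature_vector")) return(x)
  feature_vector(x)
}

#' Generalized Jaccard (Ruzicka) similarity between two frequency vectors
#'
#' Computes \eqn{\sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)} over the
#' union of the two supports.  On binary (0/1) vectors this reduces to the
#' set Jaccard index \eqn{|A \cap B| / |A \cup B|}.  The value is symmetric,
#' lies in \eqn{[0, 1]}, and is invariant to scaling both vectors by the
#' same positive constant.
#'
#' Two empty-support vectors have an undefined ratio; the similarity is
#' defined as 0 (with a warning) so that rankings over a compound library
#' remain total.
#'
#' @param x,y feature vectors (named numeric vectors; see [feature_vector()]).
#' @return similarity in `[0, 1]`.
#' @examples
#' generalized_jaccard(c(a = 2, b = 1), c(a = 1, b = 1, c = 1))  # 0.5
#' @export
generalized_jaccard <- function(x, y) {
  x <- as_feature_vector(x)
  y <- as_feature_vector(y)
  if (length(x) == 0L && length(y) == 0L) {
    ht_warn("similarity of two empty-support vectors is defined as 0",
            "ht_empty_vector_warning")
    return(0)
  }
  if (length(x) == 0L || length(y) == 0L) return(0)
  feats <- union(names(x), names(y))
  xv <- yv <- numeric(length(feats))
  xv[match(names(x), feats)] <- x
  yv[match(names(y), feats)] <- y
  sum(pmin(xv, yv)) / sum(pmax(xv, yv))
}

#' Pairwise similarity matrix between two fingerprint collections
#'
#' @param queries,references lists of feature vectors (named lists; the
#'   names become the dimnames of the result).
#' @return numeric matrix with `length(queries)` rows and
#'   `length(references)` columns; entry `(i, j)` is
#'   `generalized_jaccard(queries[[i]], references[[j]])`.
#' @export
similarity_matrix <- function(queries, references) {
  if (length(queries) == 0L || length(references) == 0L) {
    ht_abort("`queries` and `references` must be non-empty lists",
             "ht_domain_error")
  }
  queries <- lapply(queries, as_feature_vector)
  references <- lapply(references, as_feature_vector)
  # Index fingerprints into a common dense feature space once, rather than
  # re-unioning supports per pair.
  feats <- sort(unique(c(
    unlist(lapply(queries, names), use.names = FALSE),
    unlist(lapply(references, names), use.names = FALSE)
  )))
  densify <- function(fv) {
    v <- numeric(length(feats))
    if (length(fv)) v[match(names(fv), feats)] <- fv
    v
  }
  qm <- vapply(queries, densify, numeric(length(feats)))
  rm_ <- vapply(references, densify, numeric(length(feats)))
  qm <- matrix(qm, nrow = max(length(feats), 0L))
  rm_ <- matrix(rm_, nrow = max(length(feats), 0L))
  out <- matrix(0, nrow = length(queries), ncol = length(references),
                dimnames = list(names(queries), names(references)))
  for (i in seq_along(queries)) {
    qi <- qm[, i]
    if (all(qi == 0)) {
      # empty query: similarity 0 against everything (or 0-with-warning
      # against another empty vector, handled elementwise)
      for (j in seq_along(references)) {
        out[i, j] <- generalized_jaccard(queries[[i]], references[[j]])
      }
      next
    }
    num <- colSums(pmin(rm_, qi))  # matrix first: pmin keeps its dim
    den <- colSums(pmax(rm_, qi))
    zero <- den == 0
    out[i, ] <- ifelse(zero, 0, num / ifelse(zero, 1, den))
  }
  out
}
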