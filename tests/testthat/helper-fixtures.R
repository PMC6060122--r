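# Shared fixture builders.  Everything is generated in code; the oracles
# used against package functions are deliberately naive re-derivations
# (scalar loops, exhaustive enumeration) independent of the implementation.

# random sparse count vector over a small feature pool
rand_fvec <- function(pool = paste0("f", 1:30), support = sample(0:8, 1),
                      max_count = 5) {
  if (support == 0L) return(feature_vector(numeric(0)))
  feats <- sample(pool, support)
  feature_vector(stats::setNames(sample(max_count, support, replace = TRUE),
                                 feats))
}

# scalar generalized Jaccard, written independently of the package path
naive_jaccard <- function(x, y) {
  feats <- union(names(x), names(y))
  if (length(feats) == 0L) return(0)
  xv <- ifelse(feats %in% names(x), x[feats], 0)
  yv <- ifelse(feats %in% names(y), y[feats], 0)
  xv[is.na(xv)] <- 0; yv[is.na(yv)] <- 0
  den <- sum(pmax(xv, yv))
  if (den == 0) 0 else sum(pmin(xv, yv)) / den
}

# naive TESS: explicit double loop over proteins and their ligands
naive_tess <- function(query_fv, index, fingerprints) {
  out <- lapply(names(index), function(p) {
    sims <- vapply(index[[p]], function(cid) {
      naive_jaccard(query_fv, fingerprints[[cid]])
    }, numeric(1))
    best <- which.max(sims)
    data.frame(protein_id = p, score = sims[[best]],
               best_reference_compound_id = index[[p]][[best]],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, out)
  df[order(-df$score, df$protein_id), , drop = FALSE]
}

# exhaustive hypergeometric tail: enumerate all C(l, r) draws from a
# universe whose first k elements form the term set
enum_hyper_tail <- function(l, k, r, z) {
  if (r == 0L) return(as.numeric(z == 0L))
  draws <- utils::combn(l, r)
  inter <- colSums(draws <= k)
  sum(inter >= z) / ncol(draws)
}

# small literal interactome used across tests
toy_interactome <- function() {
  interactome(data.frame(
    compound_id = c("cA", "cA", "cB", "cB", "cC"),
    protein_id  = c("P1", "P2", "P2", "P3", "P3"),
    affinity_nM = c(10, 200, 500, 40, NA),
    active_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    source = "toy",
    stringsAsFactors = FALSE
  ))
}

toy_registry <- function() {
  medicine_registry(
    compounds = data.frame(
      compound_id = c("cA", "cB", "cC", "cZ"),
      name = c("alpha", "beta", "gamma", "zeta"),
      stringsAsFactors = FALSE),
    crude_drugs = data.frame(
      crude_drug_id = c("cd1", "cd1", "cd2", "cd2", "cd3"),
      crude_drug_name = c("herb-one", "herb-one", "herb-two", "herb-two",
                          "herb-three"),
      compound_id = c("cA", "cB", "cB", "cC", "cZ"),
      stringsAsFactors = FALSE),
    formulas = data.frame(
      formula_id = c("form1", "form1", "form2"),
      formula_name = c("formula-one", "formula-one", "formula-two"),
      crude_drug_id = c("cd1", "cd2", "cd3"),
      stringsAsFactors = FALSE))
}
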