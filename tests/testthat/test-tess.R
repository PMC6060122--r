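test_that("activity filter keeps flagged records and strict sub-30uM affinities", {
  rec <- data.frame(
    compound_id = paste0("c", 1:5),
    protein_id = "P1",
    affinity_nM = c(10, 29999, 30000, 50000, NA),
    active_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  it <- filter_interactome(rec)
  expect_setequal(it$records$compound_id, c("c1", "c2", "c5"))
  # boundary: exactly 30000 nM is excluded (strict <)
  expect_false("c3" %in% it$records$compound_id)
  # records with neither evidence are dropped, with a message not an error
  rec2 <- rbind(rec, data.frame(compound_id = "c6", protein_id = "P1",
                                affinity_nM = NA, active_flag = FALSE))
  expect_message(it2 <- filter_interactome(rec2), "1 record")
  expect_false("c6" %in% it2$records$compound_id)
  # empty input
  expect_equal(nrow(filter_interactome(rec[0, ])$records), 0L)
})

test_that("tess_predict scores each protein by the max ligand similarity", {
  fps <- list(
    q  = feature_vector(c(a = 1, b = 1)),
    c1 = feature_vector(c(a = 1, z = 9)),        # low similarity to q
    c2 = feature_vector(c(a = 1, b = 1, c = 1))  # higher similarity
  )
  it <- interactome(data.frame(
    compound_id = c("c1", "c2"), protein_id = "P1",
    affinity_nM = 10, active_flag = FALSE))
  pred <- tess_predict(fps$q, it, fps)
  expect_equal(pred$score, naive_jaccard(fps$q, fps$c2))
  expect_identical(pred$best_reference_compound_id, "c2")
  expect_false(pred$is_known)
})

test_that("a known ligand recovers its protein with score 1 and is_known", {
  it <- toy_interactome()
  fps <- list(cA = feature_vector(c(x = 1)), cB = feature_vector(c(y = 1)),
              cC = feature_vector(c(z = 1)))
  pred <- tess_predict("cA", it, fps)
  expect_equal(pred$score[pred$protein_id == "P1"], 1)
  expect_true(pred$is_known[pred$protein_id == "P1"])
  expect_identical(pred$best_reference_compound_id[pred$protein_id == "P1"],
                   "cA")
  # min_score = 0, no top_n: one prediction per interactome protein
  expect_setequal(pred$protein_id, names(it$index))
})

test_that("missing interactome fingerprints are a configuration error", {
  it <- toy_interactome()
  fps <- list(cA = feature_vector(c(x = 1)))  # cB, cC missing
  err <- expect_error(tess_predict("cA", it, fps), class = "ht_config_error")
  expect_match(conditionMessage(err), "cB")
  expect_match(conditionMessage(err), "cC")
})

test_that("tess_predict equals the naive double loop on random instances", {
  set.seed(99)
  for (inst in 1:100) {
    cids <- paste0("c", 1:15)
    fps <- stats::setNames(
      replicate(15, rand_fvec(pool = paste0("f", 1:25), support = sample(1:6, 1)),
                simplify = FALSE), cids)
    rec <- unique(data.frame(
      compound_id = sample(cids, 30, replace = TRUE),
      protein_id = sample(paste0("P", 1:8), 30, replace = TRUE),
      affinity_nM = 10, active_flag = FALSE, stringsAsFactors = FALSE))
    it <- interactome(rec)
    qid <- sample(cids, 1)
    pred <- tess_predict(qid, it, fps)
    oracle <- naive_tess(fps[[qid]], it$index, fps)
    expect_equal(pred$score, oracle$score)
    expect_identical(pred$protein_id, oracle$protein_id)
    expect_identical(pred$best_reference_compound_id,
                     oracle$best_reference_compound_id)
    # every known (query, protein) pair scores exactly 1
    known_prot <- unique(rec$protein_id[rec$compound_id == qid])
    expect_true(all(pred$score[pred$protein_id %in% known_prot] == 1))
    expect_true(all(pred$is_known[pred$protein_id %in% known_prot]))
  }
})

test_that("min_score filters monotonically and top_n is a ranking prefix", {
  set.seed(5)
  cids <- paste0("c", 1:10)
  fps <- stats::setNames(replicate(10, rand_fvec(), simplify = FALSE), cids)
  it <- interactome(data.frame(
    compound_id = sample(cids, 20, replace = TRUE),
    protein_id = sample(paste0("P", 1:6), 20, replace = TRUE),
    affinity_nM = 10, active_flag = FALSE))
  full <- suppressWarnings(tess_predict("c1", it, fps))
  for (ms in c(0.1, 0.3, 0.7)) {
    sub <- suppressWarnings(tess_predict("c1", it, fps, min_score = ms))
    expect_identical(sub$protein_id, full$protein_id[full$score >= ms])
  }
  for (n in c(1, 3, 5)) {
    top <- suppressWarnings(tess_predict("c1", it, fps, top_n = n))
    expect_identical(top, full[seq_len(min(n, nrow(full))), ],
                     ignore_attr = TRUE)
  }
})

test_that("aggregation takes the union of targets with the max score", {
  pa <- data.frame(compound_id = "A", protein_id = "P1", score = 0.9,
                   is_known = FALSE, best_reference_compound_id = "r1",
                   stringsAsFactors = FALSE)
  pb <- data.frame(compound_id = "B", protein_id = c("P1", "P2"),
                   score = c(0.6, 0.8), is_known = FALSE,
                   best_reference_compound_id = c("r2", "r3"),
                   stringsAsFactors = FALSE)
  agg <- aggregate_predictions(list(A = pa, B = pb))
  expect_identical(agg$protein_id, c("P1", "P2"))
  expect_equal(agg$score, c(0.9, 0.8))
  expect_identical(agg$best_compound_id, c("A", "B"))
  contrib <- attr(agg, "contributions")
  expect_equal(nrow(contrib), 3L)  # every contributing pair retained
  # single-compound identity
  agg1 <- aggregate_predictions(list(A = pa))
  expect_equal(agg1$score, pa$score)
  expect_identical(agg1$protein_id, pa$protein_id)
  # disjoint targets concatenate
  pc <- data.frame(compound_id = "C", protein_id = "P9", score = 0.5,
                   is_known = FALSE, best_reference_compound_id = "r4",
                   stringsAsFactors = FALSE)
  agg2 <- aggregate_predictions(list(A = pa, C = pc))
  expect_equal(nrow(agg2), nrow(pa) + nrow(pc))
  # alternative aggregations (per protein: P1 from A 0.9 and B 0.6)
  agg_mean <- aggregate_predictions(list(A = pa, B = pb), method = "mean")
  expect_equal(agg_mean$score[agg_mean$protein_id == "P1"], 0.75)
  agg_cnt <- aggregate_predictions(list(A = pa, B = pb), method = "count")
  expect_equal(agg_cnt$score[agg_cnt$protein_id == "P1"], 2)
  # empty input
  expect_equal(nrow(aggregate_predictions(list())), 0L)
})
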