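toy_disease_map <- function() {
  disease_target_map(data.frame(
    disease_id = c("D1", "D1", "D2", "D3"),
    disease_name = c("dis-one", "dis-one", "dis-two", "dis-three"),
    protein_id = c("P1", "P2", "P2", "P9"),
    stringsAsFactors = FALSE))
}

pred_row <- function(pid, score, known) {
  data.frame(compound_id = "q", protein_id = pid, score = score,
             is_known = known, best_reference_compound_id = "r",
             stringsAsFactors = FALSE)
}

test_that("known-target links score exactly 1, predicted links keep their score", {
  targets <- rbind(pred_row("P1", 1, TRUE), pred_row("P2", 0.7, FALSE))
  res <- predict_indications(targets, toy_disease_map())
  l1 <- res$links[res$links$protein_id == "P1", ]
  expect_equal(l1$score, 1); expect_true(l1$via_known)
  l2 <- res$links[res$links$protein_id == "P2", ]
  expect_equal(unique(l2$score), 0.7); expect_false(any(l2$via_known))
  # disease ranking: D1 via known P1 (1.0) first, then D2 (0.7)
  expect_identical(res$diseases$disease_id, c("D1", "D2"))
  expect_equal(res$diseases$best_score, c(1, 0.7))
  expect_equal(res$diseases$n_links, c(2L, 1L))
})

test_that("a known target beaten by its own prediction score still scores 1", {
  # is_known overrides whatever score the similarity search produced
  targets <- pred_row("P2", 0.4, TRUE)
  res <- predict_indications(targets, toy_disease_map())
  expect_equal(res$links$score, c(1, 1))
})

test_that("no target overlap yields an empty ranking, not an error", {
  res <- predict_indications(pred_row("PX", 0.9, FALSE), toy_disease_map())
  expect_equal(nrow(res$diseases), 0L)
  expect_equal(nrow(res$links), 0L)
  res0 <- predict_indications(pred_row("P1", 1, TRUE)[0, ], toy_disease_map())
  expect_equal(nrow(res0$diseases), 0L)
})

test_that("every link's protein is in both the target list and the disease map", {
  set.seed(21)
  for (i in 1:30) {
    prots <- paste0("P", 1:12)
    targets <- do.call(rbind, lapply(sample(prots, 6), function(p) {
      pred_row(p, runif(1), sample(c(TRUE, FALSE), 1))
    }))
    dmap <- disease_target_map(data.frame(
      disease_id = sample(paste0("D", 1:4), 10, replace = TRUE),
      disease_name = "d",
      protein_id = sample(prots, 10, replace = TRUE),
      stringsAsFactors = FALSE))
    res <- predict_indications(targets, dmap)
    expect_true(all(res$links$protein_id %in% targets$protein_id))
    expect_true(all(res$links$protein_id %in% dmap$associations$protein_id))
    expect_true(all(
      res$links$score[res$links$via_known] == 1))
    # with all targets known, every matched disease scores exactly 1
    all_known <- targets; all_known$is_known <- TRUE
    resk <- predict_indications(all_known, dmap)
    expect_true(all(resk$diseases$best_score == 1))
  }
})

test_that("adding a disease association never lowers any disease's score", {
  targets <- rbind(pred_row("P1", 1, TRUE), pred_row("P2", 0.6, FALSE),
                   pred_row("P3", 0.3, FALSE))
  base_map <- toy_disease_map()
  before <- predict_indications(targets, base_map)$diseases
  grown <- disease_target_map(rbind(
    base_map$associations,
    data.frame(disease_id = "D2", disease_name = "dis-two",
               protein_id = "P3", stringsAsFactors = FALSE)))
  after <- predict_indications(targets, grown)$diseases
  for (d in before$disease_id) {
    expect_gte(after$best_score[after$disease_id == d],
               before$best_score[before$disease_id == d])
  }
})

test_that("a disease mapping exactly the query's known targets ranks first", {
  b <- simulate_bundle(synth_config(seed = 4))
  g <- b$truth$g_comp
  # construct a single disease whose therapeutic targets are exactly the
  # designated query's known-target set
  dmap <- disease_target_map(
    data.frame(disease_id = "DTRUE", disease_name = "constructed",
               protein_id = g, stringsAsFactors = FALSE))
  targets <- data.frame(compound_id = "agg", protein_id = g, score = 1,
                        is_known = TRUE, best_reference_compound_id = NA,
                        stringsAsFactors = FALSE)
  res <- predict_indications(targets, dmap)
  expect_identical(res$diseases$disease_id[1], "DTRUE")
  expect_equal(res$diseases$best_score[1], 1)
  expect_equal(res$diseases$n_links[1], length(g))
})
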