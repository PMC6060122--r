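test_that("interactome dedups pairs keeping the lowest affinity", {
  it <- interactome(data.frame(
    compound_id = c("c1", "c1", "c1"),
    protein_id = c("P1", "P1", "P2"),
    affinity_nM = c(500, 20, NA),
    active_flag = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE))
  expect_equal(nrow(it$records), 2L)
  kept <- it$records[it$records$protein_id == "P1", ]
  expect_equal(kept$affinity_nM, 20)
  expect_identical(ligands_of(it, "P2"), "c1")
  expect_identical(ligands_of(it, "P9"), character(0))
})

test_that("registry construction enforces referential integrity", {
  reg <- toy_registry()
  expect_s3_class(reg, "medicine_registry")
  bad <- expect_error(
    medicine_registry(
      data.frame(compound_id = "cA", name = "a"),
      data.frame(crude_drug_id = "cd1", crude_drug_name = "h",
                 compound_id = "cMissing"),
      data.frame(formula_id = "f1", formula_name = "f",
                 crude_drug_id = "cd1")),
    class = "ht_integrity_error")
  expect_match(conditionMessage(bad), "cMissing")
})

test_that("constituent compounds resolve at all three levels", {
  reg <- toy_registry()
  expect_identical(constituent_compounds(reg, "form1"), c("cA", "cB", "cC"))
  expect_identical(constituent_compounds(reg, "cd2"), c("cB", "cC"))
  expect_identical(constituent_compounds(reg, "cA"), "cA")
  expect_error(constituent_compounds(reg, "nope"),
               class = "ht_not_found_error")
})

test_that("compound_target_union is the exact set union", {
  it <- toy_interactome()
  # brute-force union oracle
  oracle <- sort(unique(unlist(lapply(c("cA", "cB"), function(cid) {
    it$records$protein_id[it$records$compound_id == cid]
  }))))
  expect_identical(compound_target_union(c("cA", "cB"), it), oracle)
  expect_identical(compound_target_union(character(0), it), character(0))
  expect_identical(compound_target_union("cZ", it), character(0))
  # idempotent union: all compounds targeting the same protein
  it2 <- interactome(data.frame(compound_id = c("x", "y", "z"),
                                protein_id = "P", affinity_nM = 1,
                                active_flag = FALSE))
  expect_identical(compound_target_union(c("x", "y", "z"), it2), "P")
})

test_that("resolve_hierarchy builds the four-layer tree with provenance", {
  reg <- toy_registry()
  it <- toy_interactome()
  h <- resolve_hierarchy(reg, "form1", it)
  expect_s3_class(h, "medicine_hierarchy")
  expect_identical(vapply(h$crude_drugs, `[[`, "", "crude_drug_id"),
                   c("cd1", "cd2"))
  # shared compound cB appears under both crude drugs
  comp_by_cd <- lapply(h$crude_drugs, function(cd)
    vapply(cd$compounds, `[[`, "", "compound_id"))
  expect_true("cB" %in% comp_by_cd[[1]] && "cB" %in% comp_by_cd[[2]])
  # layer 4 equals the union oracle over layer 3
  expect_identical(h$layer4,
                   compound_target_union(constituent_compounds(reg, "form1"),
                                         it))
  # provenance path
  cb_node <- h$crude_drugs[[1]]$compounds[[2]]
  expect_identical(cb_node$path, c("form1", "cd1", "cB"))
  expect_error(resolve_hierarchy(reg, "missing", it),
               class = "ht_not_found_error")
})

test_that("a compound with zero targets yields an empty layer 4", {
  reg <- toy_registry()
  it <- toy_interactome()
  h <- resolve_hierarchy(reg, "form2", it)  # only cZ, no interactions
  expect_identical(h$layer4, character(0))
})

test_that("hierarchy layer 4 equals the union oracle on random instances", {
  set.seed(3)
  for (rep in 1:20) {
    n_c <- 8
    cids <- paste0("c", 1:n_c)
    reg <- medicine_registry(
      data.frame(compound_id = cids, name = cids),
      data.frame(crude_drug_id = rep(c("d1", "d2"), each = 3),
                 crude_drug_name = "d",
                 compound_id = sample(cids, 6, replace = TRUE)),
      data.frame(formula_id = "f", formula_name = "f",
                 crude_drug_id = c("d1", "d2")))
    rec <- data.frame(compound_id = sample(cids, 12, replace = TRUE),
                      protein_id = sample(paste0("P", 1:5), 12, replace = TRUE),
                      affinity_nM = 10, active_flag = FALSE)
    it <- interactome(rec)
    h <- resolve_hierarchy(reg, "f", it)
    expect_identical(
      h$layer4,
      compound_target_union(constituent_compounds(reg, "f"), it))
  }
})

test_that("predicted targets extend layer 4 with scores below 1", {
  reg <- toy_registry()
  it <- toy_interactome()
  preds <- list(cA = data.frame(
    compound_id = "cA", protein_id = c("P9", "P1"), score = c(0.7, 0.9),
    is_known = FALSE, best_reference_compound_id = "cB",
    stringsAsFactors = FALSE))
  h <- resolve_hierarchy(reg, "form1", it, predictions = preds)
  expect_true("P9" %in% h$layer4)
  node <- h$crude_drugs[[1]]$compounds[[1]]  # cA
  tg <- node$targets
  expect_equal(tg$score[tg$protein_id == "P9"], 0.7)
  expect_false(tg$is_known[tg$protein_id == "P9"])
  # known target stays known with score 1 even if also predicted
  expect_true(tg$is_known[tg$protein_id == "P1"])
  expect_equal(tg$score[tg$protein_id == "P1"], 1)
})
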