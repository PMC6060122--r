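test_that("hypergeometric tail matches the enumeration oracle at (10,4,5)", {
  expect_equal(hypergeom_tail(10, 4, 5, 0), 1)
  expect_equal(hypergeom_tail(10, 4, 5, 3), 66 / 252)
  expect_equal(hypergeom_tail(10, 4, 5, 4), 6 / 252)
  expect_equal(enum_hyper_tail(10, 4, 5, 3), 66 / 252)
  expect_equal(enum_hyper_tail(10, 4, 5, 4), 6 / 252)
})

test_that("hypergeometric tail rejects out-of-domain parameters", {
  expect_error(hypergeom_tail(10, 11, 5, 0), class = "ht_domain_error")
  expect_error(hypergeom_tail(10, 4, 11, 0), class = "ht_domain_error")
  expect_error(hypergeom_tail(10, 4, 5, 5), class = "ht_domain_error")
  expect_error(hypergeom_tail(10, 4, 5, -1), class = "ht_domain_error")
})

test_that("tail probability is monotone in z and 1 at z = 0", {
  for (l in c(6, 9, 12)) for (k in c(2, 4)) for (r in c(3, 5)) {
    ps <- vapply(0:min(k, r), function(z) hypergeom_tail(l, k, r, z),
                 numeric(1))
    expect_equal(ps[1], 1)
    expect_true(all(diff(ps) <= 1e-12))
  }
})

test_that("BH adjustment matches the hand-computed step-up", {
  p <- c(0.01, 0.02, 0.04, 0.5)
  expect_equal(bh_fdr(p), c(0.04, 0.04, 0.16 / 3, 0.5))
  expect_equal(bh_fdr(0.2), 0.2)                     # m = 1
  expect_equal(bh_fdr(rep(0.3, 5)), rep(0.3, 5))     # all equal
  expect_error(bh_fdr(c(0.5, 1.2)), class = "ht_domain_error")
  # q >= p, q <= 1, permutation invariance
  set.seed(8)
  for (i in 1:50) {
    pv <- runif(sample(1:12, 1))
    q <- bh_fdr(pv)
    expect_true(all(q >= pv - 1e-15) && all(q <= 1))
    perm <- sample(seq_along(pv))
    expect_equal(bh_fdr(pv[perm]), q[perm])
  }
})

test_that("enrich computes (z, k, r, l), ratio, p and BH q per term", {
  ns <- annotation_namespace(
    list(T1 = c("P1", "P2", "P3", "P4"),
         T2 = c("P5", "P6"),
         T3 = c("P1", "P9", "P10")),
    namespace = "pathway")
  bg <- paste0("P", 1:10)
  g <- c("P1", "P2", "P3", "P5", "P9")
  res <- enrich(g, ns, background = bg)
  expect_s3_class(res, "enrichment_result")
  expect_equal(nrow(res), 3L)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$z, 3L); expect_equal(r1$k, 4L)
  expect_equal(r1$r, 5L); expect_equal(r1$l, 10L)
  expect_equal(r1$ratio, 3 / 4)
  expect_equal(r1$p_value, enum_hyper_tail(10, 4, 5, 3))
  expect_equal(res$q_value, bh_fdr(res$p_value))
  expect_true(all(diff(res$p_value) >= 0))  # sorted by p
})

test_that("degenerate full-overlap namespace gives ratio 1 and p 1", {
  g <- c("P1", "P2", "P3")
  ns <- annotation_namespace(list(ALL = g), namespace = "process")
  res <- enrich(g, ns, background = g)
  expect_equal(res$ratio, 1)
  expect_equal(res$p_value, 1)
  expect_equal(res$z, res$k)
})

test_that("empty query set returns an empty result with a warning", {
  ns <- annotation_namespace(list(T1 = c("P1", "P2")), namespace = "brite")
  expect_warning(res <- enrich(character(0), ns, background = c("P1", "P2")),
                 class = "ht_empty_query_warning")
  expect_equal(nrow(res), 0L)
})

test_that("terms fully outside the background are excluded with a message", {
  ns <- annotation_namespace(list(IN = c("P1", "P2"), OUT = c("X1", "X2")),
                             namespace = "pathway")
  expect_message(res <- enrich("P1", ns, background = c("P1", "P2", "P3")),
                 "outside the background")
  expect_identical(res$term_id, "IN")
})

test_that("adding a term member to the query weakly decreases that term's p", {
  bg <- paste0("P", 1:12)
  ns <- annotation_namespace(list(T = paste0("P", 1:5)), namespace = "pathway")
  p_before <- enrich(c("P1", "P6"), ns, background = bg)$p_value
  p_after <- enrich(c("P1", "P2", "P6"), ns, background = bg)$p_value
  expect_lte(p_after, p_before)
})

test_that("planted enrichment is recovered on synthetic annotations", {
  hits <- 0L
  for (seed in 1:25) {
    b <- simulate_bundle(synth_config(seed = seed))
    res <- enrich(b$truth$g_comp, b$namespaces$pathway,
                  background = sort(names(b$interactome$index)))
    if (res$term_id[1] == b$truth$planted_term[["pathway"]]) hits <- hits + 1L
  }
  expect_gte(hits, 24L)
})
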