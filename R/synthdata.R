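# Seeded generator of synthetic inputs with the statistical structure the
# methods assume: ligand families whose members share a core substructure
# profile (so fingerprint similarity is informative of shared targets), a
# two-level medicine hierarchy over those compounds, annotation namespaces
# with one planted enriched term, and a disease-target map overlapping the
# protein universe.  Everything is deterministic under a fixed seed.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe a desk-scale chemogenomics screen: 60 proteins with 8
#' known ligands each over a library of 150 compounds in 10 structural
#' families, a 4-formula / 3-crude-drugs / 5-compounds hierarchy, 20 terms
#' per annotation namespace with one planted term capturing 80% of the
#' designated query's target set, and 15 diseases.
#'
#' @param seed integer RNG seed; the same seed and configuration give
#'   byte-identical outputs.
#' @param n_proteins,n_compounds,n_features library dimensions.
#' @param n_families number of ligand families (must not exceed
#'   `n_compounds`).
#' @param family_feature_overlap fraction of a compound's features drawn
#'   from its family's shared core profile (1 = identical within family).
#' @param features_per_compound fingerprint support size per compound.
#' @param interactions_per_protein known ligands per protein.
#' @param ligand_family_purity fraction of a protein's ligands drawn from
#'   its primary family (the rest are random library compounds).
#' @param n_formulas,crude_drugs_per_formula,compounds_per_crude_drug
#'   medicine hierarchy dimensions.
#' @param n_terms_per_namespace terms per annotation namespace.
#' @param term_size_range inclusive range of term-set sizes.
#' @param planted_term_effect fraction of the designated query target set
#'   placed into the planted term (0 = no planted signal).
#' @param n_diseases number of diseases in the association map.
#' @param disease_size_range inclusive range of per-disease target counts.
#' @param active_flag_rate fraction of interaction records flagged active
#'   irrespective of affinity.
#' @param affinity_range_nM affinities are drawn log-uniformly over this
#'   range (default 1 nM to 1 mM), straddling the 30 uM activity filter.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         n_proteins = 60L,
                         n_compounds = 150L,
                         n_features = 400L,
                         n_families = 10L,
                         family_feature_overlap = 0.8,
                         features_per_compound = 20L,
                         interactions_per_protein = 8L,
                         ligand_family_purity = 0.8,
                         n_formulas = 4L,
                         crude_drugs_per_formula = 3L,
                         compounds_per_crude_drug = 5L,
                         n_terms_per_namespace = 20L,
                         term_size_range = c(5L, 35L),
                         planted_term_effect = 0.8,
                         n_diseases = 15L,
                         disease_size_range = c(2L, 8L),
                         active_flag_rate = 0.1,
                         affinity_range_nM = c(1, 1e6)) {
  cfg <- list(
    seed = assert_count(seed, "seed"),
    n_proteins = assert_count(n_proteins, "n_proteins", 1L),
    n_compounds = assert_count(n_compounds, "n_compounds", 1L),
    n_features = assert_count(n_features, "n_features", 1L),
    n_families = assert_count(n_families, "n_families", 1L),
    family_feature_overlap = assert_fraction(family_feature_overlap,
                                             "family_feature_overlap"),
    features_per_compound = assert_count(features_per_compound,
                                         "features_per_compound", 1L),
    interactions_per_protein = assert_count(interactions_per_protein,
                                            "interactions_per_protein", 1L),
    ligand_family_purity = assert_fraction(ligand_family_purity,
                                           "ligand_family_purity"),
    n_formulas = assert_count(n_formulas, "n_formulas", 1L),
    crude_drugs_per_formula = assert_count(crude_drugs_per_formula,
                                           "crude_drugs_per_formula", 1L),
    compounds_per_crude_drug = assert_count(compounds_per_crude_drug,
                                            "compounds_per_crude_drug", 1L),
    n_terms_per_namespace = assert_count(n_terms_per_namespace,
                                         "n_terms_per_namespace", 1L),
    term_size_range = c(assert_count(term_size_range[1], "term_size_range", 1L),
                        assert_count(term_size_range[2], "term_size_range", 1L)),
    planted_term_effect = assert_fraction(planted_term_effect,
                                          "planted_term_effect"),
    n_diseases = assert_count(n_diseases, "n_diseases", 1L),
    disease_size_range = c(assert_count(disease_size_range[1],
                                        "disease_size_range", 1L),
                           assert_count(disease_size_range[2],
                                        "disease_size_range", 1L)),
    active_flag_rate = assert_fraction(active_flag_rate, "active_flag_rate"),
    affinity_range_nM = as.numeric(affinity_range_nM)
  )
  if (cfg$n_families > cfg$n_compounds) {
    ht_abort("n_families must not exceed n_compounds", "ht_config_error")
  }
  if (cfg$features_per_compound > cfg$n_features) {
    ht_abort("features_per_compound must not exceed n_features",
             "ht_config_error")
  }
  if (cfg$interactions_per_protein > cfg$n_compounds) {
    ht_abort("interactions_per_protein must not exceed n_compounds",
             "ht_config_error")
  }
  if (cfg$term_size_range[1] > cfg$term_size_range[2] ||
      cfg$disease_size_range[1] > cfg$disease_size_range[2]) {
    ht_abort("size ranges must be non-decreasing", "ht_config_error")
  }
  if (length(cfg$affinity_range_nM) != 2L ||
      any(cfg$affinity_range_nM <= 0) ||
      cfg$affinity_range_nM[1] >= cfg$affinity_range_nM[2]) {
    ht_abort("affinity_range_nM must be an increasing positive pair",
             "ht_config_error")
  }
  class(cfg) <- "synth_config"
  cfg
}

pad_id <- function(prefix, i, n) {
  sprintf(paste0(prefix, "%0", nchar(as.character(n)), "d"), i)
}

with_fixed_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  code
}

#' Simulate fingerprints and a compound-protein interactome
#'
#' Compounds are organised into ligand families: each family has a core
#' feature profile (features with fixed counts) and each member draws
#' `family_feature_overlap` of its support from that core (with the core
#' counts) and the rest from private random features.  Each protein's
#' known ligands are drawn mostly from one family, so fingerprint
#' similarity is informative of shared targets.  Affinities are
#' log-uniform over `affinity_range_nM`, so records fall on both sides of
#' the 30 uM activity filter; a fraction of records is flagged active.
#'
#' @param config a [synth_config()].
#' @return list with elements `fingerprints` (named list of feature
#'   vectors), `records` (raw interaction table, pre-filter), `compounds`
#'   (registry table), and `truth` (list: `compound_family`,
#'   `protein_family`).
#' @export
simulate_interactome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_fixed_rng(config$seed, {
    n_c <- config$n_compounds; n_p <- config$n_proteins
    n_fam <- config$n_families; n_feat <- config$n_features
    m <- config$features_per_compound
    compound_ids <- pad_id("C", seq_len(n_c), n_c)
    protein_ids <- pad_id("P", seq_len(n_p), n_p)
    feature_ids <- pad_id("F", seq_len(n_feat), n_feat)
    compound_family <- rep_len(seq_len(n_fam), n_c)

    # family core profiles: feature subset with fixed counts
    cores <- lapply(seq_len(n_fam), function(f) {
      feats <- sample(feature_ids, m)
      stats::setNames(sample(1:3, m, replace = TRUE), feats)
    })
    n_core <- round(config$family_feature_overlap * m)
    fingerprints <- lapply(seq_len(n_c), function(i) {
      core <- cores[[compound_family[i]]]
      shared <- core[seq_len(n_core)]
      n_priv <- m - n_core
      if (n_priv > 0L) {
        pool <- setdiff(feature_ids, names(shared))
        priv <- stats::setNames(sample(1:3, n_priv, replace = TRUE),
                                sample(pool, n_priv))
        feature_vector(c(shared, priv))
      } else {
        feature_vector(shared)
      }
    })
    names(fingerprints) <- compound_ids

    # protein ligand sets: mostly one family, remainder random
    protein_family <- rep_len(seq_len(n_fam), n_p)
    k <- config$interactions_per_protein
    n_fam_lig <- round(config$ligand_family_purity * k)
    records <- do.call(rbind, lapply(seq_len(n_p), function(p) {
      fam_pool <- compound_ids[compound_family == protein_family[p]]
      fam_lig <- sample(fam_pool, min(n_fam_lig, length(fam_pool)))
      rest_pool <- setdiff(compound_ids, fam_lig)
      rest <- sample(rest_pool, k - length(fam_lig))
      lig <- c(fam_lig, rest)
      lo <- log10(config$affinity_range_nM[1])
      hi <- log10(config$affinity_range_nM[2])
      data.frame(
        compound_id = lig,
        protein_id = protein_ids[p],
        affinity_nM = 10^stats::runif(length(lig), lo, hi),
        active_flag = stats::runif(length(lig)) < config$active_flag_rate,
        source = "synthetic",
        stringsAsFactors = FALSE
      )
    }))
    rownames(records) <- NULL
    compounds <- data.frame(
      compound_id = compound_ids,
      name = paste0("compound-", compound_ids),
      smiles = "",
      stringsAsFactors = FALSE
    )
    list(fingerprints = fingerprints, records = records,
         compounds = compounds,
         truth = list(
           compound_family = stats::setNames(compound_family, compound_ids),
           protein_family = stats::setNames(protein_family, protein_ids)))
  })
}

#' Simulate a two-level medicine hierarchy
#'
#' @param config a [synth_config()].
#' @param compounds compound registry table (from
#'   [simulate_interactome()]).
#' @return a [medicine_registry()].  Crude drugs sample their constituent
#'   compounds independently, so compounds can be shared across crude
#'   drugs and formulas, as in real composition tables.
#' @export
simulate_hierarchy <- function(config, compounds) {
  stopifnot(inherits(config, "synth_config"))
  if (config$compounds_per_crude_drug > nrow(compounds)) {
    ht_abort("compounds_per_crude_drug exceeds the compound library",
             "ht_config_error")
  }
  with_fixed_rng(config$seed + 1L, {
    n_f <- config$n_formulas
    n_cd <- n_f * config$crude_drugs_per_formula
    formula_ids <- pad_id("FORM", seq_len(n_f), n_f)
    crude_ids <- pad_id("CD", seq_len(n_cd), n_cd)
    formulas <- data.frame(
      formula_id = rep(formula_ids, each = config$crude_drugs_per_formula),
      formula_name = rep(paste0("formula-", formula_ids),
                         each = config$crude_drugs_per_formula),
      crude_drug_id = crude_ids,
      stringsAsFactors = FALSE
    )
    crude_drugs <- do.call(rbind, lapply(seq_len(n_cd), function(i) {
      comp <- sort(sample(compounds$compound_id,
                          config$compounds_per_crude_drug))
      data.frame(crude_drug_id = crude_ids[i],
                 crude_drug_name = paste0("crude-", crude_ids[i]),
                 compound_id = comp, stringsAsFactors = FALSE)
    }))
    medicine_registry(compounds, crude_drugs, formulas)
  })
}

#' Simulate annotation namespaces with a planted term, and a disease map
#'
#' Generates the four annotation namespaces (`pathway`, `brite`,
#' `process`, `function`), each with random term sets over the protein
#' universe and one designated term that receives
#' `planted_term_effect * |g_comp|` members of the designated query target
#' set `g_comp` (padded with random non-members up to its nominal size).
#' At `planted_term_effect = 0` the designated term is generated exactly
#' like any other.  The disease map assigns each disease a random target
#' set from the universe.
#'
#' @param config a [synth_config()].
#' @param universe character vector: the protein universe.
#' @param g_comp character vector: target set of the designated query
#'   (subset of `universe`).
#' @return list with `namespaces` (named list of four
#'   [annotation_namespace()]s), `diseases` (a [disease_target_map()]),
#'   and `truth` (list: `planted_term` per namespace, `g_comp`).
#' @export
simulate_annotations_and_diseases <- function(config, universe, g_comp) {
  stopifnot(inherits(config, "synth_config"))
  universe <- sort(unique(as.character(universe)))
  g_comp <- sort(unique(as.character(g_comp)))
  if (length(universe) == 0L) {
    ht_abort("protein universe must be non-empty", "ht_config_error")
  }
  if (!all(g_comp %in% universe)) {
    ht_abort("g_comp must be a subset of the universe", "ht_config_error")
  }
  planted_n <- round(config$planted_term_effect * length(g_comp))
  if (planted_n > config$term_size_range[2]) {
    ht_abort(sprintf(
      "planted_term_effect * |g_comp| = %d exceeds the maximum term size %d",
      planted_n, config$term_size_range[2]), "ht_config_error")
  }
  with_fixed_rng(config$seed + 2L, {
    ns_tags <- c("pathway", "brite", "process", "function")
    nt <- config$n_terms_per_namespace
    namespaces <- lapply(ns_tags, function(tag) {
      sizes <- sample(seq(config$term_size_range[1],
                          config$term_size_range[2]), nt, replace = TRUE)
      sizes <- pmin(sizes, length(universe))
      terms <- lapply(seq_len(nt), function(i) sample(universe, sizes[i]))
      names(terms) <- pad_id(paste0(toupper(substr(tag, 1, 2)), "T"),
                             seq_len(nt), nt)
      # term 1 is the designated (planted) term
      if (planted_n > 0L) {
        members <- sample(g_comp, planted_n)
        pad_pool <- setdiff(universe, members)
        n_pad <- max(0L, sizes[1] - planted_n)
        terms[[1L]] <- c(members, sample(pad_pool, min(n_pad,
                                                       length(pad_pool))))
      }
      annotation_namespace(
        terms,
        term_names = stats::setNames(paste0(tag, "-term-", names(terms)),
                                     names(terms)),
        namespace = tag)
    })
    names(namespaces) <- ns_tags
    planted <- vapply(ns_tags, function(tag) {
      sort(names(namespaces[[tag]]$terms))[1L]
    }, character(1))

    dsz <- config$disease_size_range
    dz <- pmin(sample(seq(dsz[1], dsz[2]), config$n_diseases, replace = TRUE),
               length(universe))
    disease_ids <- pad_id("D", seq_len(config$n_diseases), config$n_diseases)
    diseases <- do.call(rbind, lapply(seq_len(config$n_diseases), function(i) {
      data.frame(disease_id = disease_ids[i],
                 disease_name = paste0("disease-", disease_ids[i]),
                 protein_id = sort(sample(universe, dz[i])),
                 stringsAsFactors = FALSE)
    }))
    list(namespaces = namespaces,
         diseases = disease_target_map(diseases),
         truth = list(planted_term = planted, g_comp = g_comp))
  })
}

#' Simulate a complete input bundle
#'
#' Runs the full generator: interactome (filtered at the 30 uM activity
#' cutoff), medicine hierarchy, annotation namespaces planted around the
#' first formula's known-target set, and the disease map.  The designated
#' query entity is the first formula.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_bundle` with elements `config`,
#'   `fingerprints`, `records` (raw), `interactome` (filtered),
#'   `registry`, `namespaces`, `diseases`, and `truth` (family labels,
#'   planted terms, designated formula and its `g_comp`).
#' @export
simulate_bundle <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  inter <- simulate_interactome(config)
  registry <- simulate_hierarchy(config, inter$compounds)
  filtered <- suppressMessages(filter_interactome(inter$records))
  universe <- sort(names(filtered$index))
  formula_id <- registry$formulas$formula_id[1L]
  g_comp <- compound_target_union(
    constituent_compounds(registry, formula_id), filtered)
  ann <- simulate_annotations_and_diseases(config, universe, g_comp)
  structure(list(
    config = config,
    fingerprints = inter$fingerprints,
    records = inter$records,
    interactome = filtered,
    registry = registry,
    namespaces = ann$namespaces,
    diseases = ann$diseases,
    truth = c(inter$truth, ann$truth,
              list(designated_formula = formula_id))
  ), class = "synth_bundle")
}

#' Leave-one-out ranks of held-out true targets
#'
#' For each sampled known interaction `(c, P)`, removes that record from
#' the interactome, predicts targets for `c` against the reduced
#' interactome, and records the rank of `P` in the full ranked list
#' (1 = best).  Proteins left with no ligands after removal get the
#' worst rank (`n_proteins`).  Under a random-score null the expected
#' median rank is half the number of proteins.
#'
#' @param interactome an [interactome()].
#' @param fingerprints named list of feature vectors for all interactome
#'   compounds.
#' @param n_pairs number of held-out interactions to evaluate (sampled
#'   without replacement from the records).
#' @param seed RNG seed for the pair sample.
#' @return integer vector of ranks, one per evaluated pair.
#' @export
tess_loo_ranks <- function(interactome, fingerprints, n_pairs = 50L,
                           seed = 1L) {
  stopifnot(inherits(interactome, "interactome"))
  rec <- interactome$records
  n_pairs <- min(assert_count(n_pairs, "n_pairs", 1L), nrow(rec))
  n_prot <- length(interactome$index)
  with_fixed_rng(seed, {
    idx <- sample(nrow(rec), n_pairs)
    vapply(idx, function(i) {
      cid <- rec$compound_id[i]; pid <- rec$protein_id[i]
      reduced <- interactome(rec[-i, , drop = FALSE])
      pred <- tess_predict(cid, reduced, fingerprints)
      r <- match(pid, pred$protein_id)
      if (is.na(r)) n_prot else as.integer(r)
    }, integer(1))
  })
}
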