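# herbtarget

Target prediction and mode-of-action analysis for multi-component herbal
medicines.

Traditional multi-herb formulas (such as Japanese Kampo medicines) act
through many constituent compounds hitting many proteins at once, which
makes their pharmacology hard to study one interaction at a time.
`herbtarget` implements the ligand-based half of that problem as a
reusable toolkit for cheminformatics and drug-discovery work:

1. **Similarity-search target prediction (TESS).** A query compound is
   represented as a sparse substructure-frequency fingerprint and compared
   with every compound in a known compound–protein interactome using the
   generalized Jaccard (Ruzicka) similarity
   `sim(x, y) = Σᵢ min(xᵢ, yᵢ) / Σᵢ max(xᵢ, yᵢ)`.
   Each interactome protein *k* with known ligand set *Lₖ* is scored by
   `score(q, k) = max_{c ∈ Lₖ} sim(q, c)`, so a protein is a strong
   candidate target when the query closely resembles any of its known
   ligands. The interactome itself is filtered to confident records:
   flagged-active interactions or measured affinities strictly below
   30 µM.
2. **Hierarchical aggregation.** Predictions for constituent compounds are
   grouped up the 4-layer hierarchy — formula (layer 1) → crude drugs
   (layer 2) → compounds (layer 3) → target proteins (layer 4) — keeping
   the maximum score per protein with full per-compound provenance.
3. **Functional enrichment.** A target set `G_comp` of size *r* is tested
   against each annotation term set `G_path` of size *k* in a universe of
   *l* proteins with the upper-tail hypergeometric probability
   `p = Σ_{i=z}^{min(k,r)} C(k,i)·C(l−k, r−i) / C(l,r)` where
   `z = |G_comp ∩ G_path|`, reported with the enrichment ratio `z/k` and
   Benjamini–Hochberg q-values, for four namespaces (pathway, brite,
   process, function).
4. **Indication prediction by target matching.** Each target shared with a
   disease–target association table links the compound to that disease,
   scored 1 for known targets and by the TESS score for predicted ones.

A seeded synthetic-data generator (`simulate_bundle()`) produces full
input bundles with the statistical structure the methods assume — ligand
families with shared substructure cores, a medicine hierarchy, annotation
namespaces with one planted enriched term, a disease map — so the whole
pipeline is testable offline, without any proprietary interactome.

## Worked example

```r
library(herbtarget)

b <- simulate_bundle(synth_config(seed = 42))

# similarity-search target prediction for one constituent compound
tess_predict("C001", b$interactome, b$fingerprints, top_n = 5)
#>   compound_id protein_id score is_known best_reference_compound_id
#> 1        C001        P11     1     TRUE                       C001
#> 2        C001        P29     1     TRUE                       C001
#> 3        C001        P41     1     TRUE                       C001
#> 4        C001        P42     1     TRUE                       C001
#> 5        C001        P51     1     TRUE                       C001

# pathway enrichment for a whole formula's target set
res <- run_functional_analysis("FORM1", b$registry, b$interactome,
                               b$namespaces$pathway)
head(as.data.frame(res)[, c("term_id", "z", "k", "r", "l",
                            "ratio", "p_value", "q_value")], 3)
#>   term_id  z  k  r  l     ratio      p_value      q_value
#> 1   PAT01 22 22 27 60 1.0000000 5.703575e-12 1.140715e-10
#> 2   PAT02 11 15 27 60 0.7333333 1.202440e-02 1.202440e-01
#> 3   PAT06 16 28 27 60 0.5714286 6.548334e-02 4.365556e-01

# indication prediction from the formula-level target set
agg <- aggregate_predictions(tess_predict_many(
  constituent_compounds(b$registry, "FORM1"),
  b$interactome, b$fingerprints))
head(predict_indications(agg, b$diseases)$diseases, 3)
#>   disease_id disease_name best_score n_links
#> 1        D01  disease-D01          1       4
#> 2        D04  disease-D04          1       7
#> 3        D05  disease-D05          1       4
```

A score of 1 with `is_known = TRUE` is a known interaction recovered from
the interactome; lower scores are similarity-based predictions, with the
reference ligand that produced them. In the enrichment table the first
row is the generator's planted term (`PAT01`): all 22 of its proteins are
targets of the formula (`ratio = 1`), which under the hypergeometric null
on a 60-protein universe has `p ≈ 6e-12`. Diseases with `best_score = 1`
are matched through known targets.

The same stages are available from the shell via the bundled CLI
(`inst/cli/herbtarget.R`) with subcommands `simulate`, `similarity`,
`predict-targets`, `aggregate`, `enrich`, `predict-indications`, and
`hierarchy`.

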