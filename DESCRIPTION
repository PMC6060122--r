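Package: herbtarget
Title: Target Prediction and Mode-of-Action Analysis for Multi-Component
    Herbal Medicines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ligand-based target prediction for the constituent compounds of
    multi-component medicines (e.g. Kampo herbal formulas), built around
    similarity search against a known compound-protein interactome.
    Compounds are represented as sparse substructure-frequency fingerprints
    and compared with the generalized Jaccard (Ruzicka) similarity; each
    candidate protein is scored by the maximum similarity between the query
    and the protein's known ligands (the TESS scheme). Predictions are
    aggregated through the formula -> crude drug -> compound hierarchy,
    characterized by hypergeometric enrichment against pathway and ontology
    term sets with Benjamini-Hochberg FDR control, and matched against a
    disease-target association table to propose indications. A seeded
    synthetic-data generator emulates the statistical structure the methods
    assume (ligand families sharing substructure features, a two-level
    medicine hierarchy, planted enriched terms), so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    ChemmineOB,
    ChemmineR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
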