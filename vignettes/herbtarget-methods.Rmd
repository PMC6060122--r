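---
title: "Methods: similarity-search target prediction and enrichment for multi-component medicines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity-search target prediction and enrichment for multi-component medicines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbtarget)
```

## The problem

A multi-herb formula is a hierarchy: the formula is composed of crude
drugs (single medicinal herbs), each crude drug contributes many
constituent compounds, and each compound may interact with many proteins.
`herbtarget` models this as four layers — formula, crude drug, compound,
target protein — and provides the computational stages needed to
characterize a formula's polypharmacology: predicting targets for each
constituent compound, aggregating them up the hierarchy, asking which
pathways and ontology terms the target set enriches, and matching targets
against disease–target associations to propose indications.

## Target prediction by similarity search

The prediction engine is deliberately simple and interpretable
(the TESS scheme: *target estimation based on similarity search*).
Compounds are sparse nonnegative frequency vectors over substructure
features. Two compounds are compared with the generalized Jaccard
(Ruzicka) similarity

$$\mathrm{sim}(x, y) = \frac{\sum_i \min(x_i, y_i)}{\sum_i \max(x_i, y_i)} \in [0, 1],$$

which reduces to the set Jaccard index on binary vectors and is invariant
to common rescaling. For a query $q$ and an interactome protein $k$ with
known ligand set $L_k$, the prediction score is
$\max_{c \in L_k} \mathrm{sim}(q, c)$, reported with the reference ligand
achieving the maximum. The underlying assumption is the chemogenomics
similar-property principle: compounds with similar substructure content
tend to share targets. A known ligand trivially recovers its own protein
with score 1 (`is_known = TRUE`), so known and predicted targets live on
one scale.

Two defined degeneracies: the similarity of two empty-support vectors is
0 (with a warning) rather than NaN, so rankings over a library remain
total; and ties in the per-protein maximum are broken by the
lexicographically first ligand id, making output deterministic. All
rankings are ordered by (score descending, protein id ascending).

### The interactome and its filter

Interaction records carry activity evidence: an explicit active flag
and/or a binding affinity in nM. A record enters the interactome iff it
is flagged active or its affinity is **strictly** below 30&nbsp;µM
(30000&nbsp;nM; `threshold_nM` is configurable), the conventional cutoff
separating measurable activity from noise in public bioactivity
databases. Records with neither kind of evidence are dropped with a
logged count. Duplicate (compound, protein) pairs are collapsed keeping
the lowest affinity; public sources frequently report several
measurements per pair and no principled reconciliation exists, so we keep
the strongest evidence, which is the conservative choice for a
keep-if-below filter.

### Fingerprints are pluggable

Production descriptor schemes of this kind (counted chemical-substructure
vocabularies built from curated chemical ontologies, with feature spaces
in the 10^5 range) cannot be recomputed without the originating
infrastructure, and the pipeline does not depend on any particular
scheme. Fingerprint TSVs (`compound_id`, `feature_id`, `count`) are
therefore first-class input. The built-in `featurize()` is an honest
default: it parses SMILES via Open Babel and counts canonical linear
paths of the heavy-atom graph up to 3 bonds (element symbols and bond
orders, direction-canonicalized). Scores depend on the descriptor; the
algorithmic pipeline does not.

## Aggregation to crude drugs and formulas

An entity's prediction set is the union over its constituent compounds;
per protein the retained score is the **maximum** across contributing
compounds. The maximum preserves the best single-compound evidence and
matches the max-over-ligands spirit of the scoring rule; `mean` and
`count` are available as options, and the full (protein, compound, score)
contribution table is attached to every aggregate so alternative
summaries are recomputable. A compound shared by two crude drugs appears
under both (the hierarchy is a DAG, not a tree), and layer 4 of a
resolved hierarchy always equals the set union of its layer-3 targets.

## Enrichment analysis

For a query target set $G_{comp}$ (size $r$) and a term set $G_{path}$
(size $k$) in a universe of $l$ proteins, with intersection size $z$, the
p-value is the upper hypergeometric tail

$$p = \sum_{i=z}^{\min(k,r)} \binom{k}{i}\binom{l-k}{r-i}\Big/\binom{l}{r},$$

computed via `stats::phyper` (log-space internally, numerically safe);
$p(z{=}0) = 1$ by construction. The enrichment ratio is $z/k$, the
fraction of the term's proteins hit by the query. Four namespaces are
supported (`pathway`, `brite`, `process`, `function`), each read from a
standard GMT file; p-values are corrected per namespace with
Benjamini–Hochberg (`stats::p.adjust`), the standard reading of "FDR
correction".

**Background choice.** The hypergeometric model requires
$G_{path} \subseteq$ universe, so term sets and the query are restricted
to the background before testing, and the reported $k$ (hence the ratio
denominator) is the restricted size; terms falling entirely outside the
background are excluded with a message. The default background in the
full-analysis path is the interactome's known-target universe, the set
over which targets can actually be observed. Whether a ratio denominator
should count all of a pathway's proteins or only those in the background
is genuinely ambiguous in practice; we chose the restricted $k$ because
it keeps `ratio = 1` exactly when the query covers everything testable,
and both are recomputable from the reported $(z, k, r, l)$ columns.
Curation conventions (e.g. excluding global/overview pathway maps) are
the data's job, not the engine's: the engine tests whatever GMT it is
given.

## Indication prediction

Every target protein of the query found in the disease–target map yields
one link per associated disease. A link through a known target scores
exactly 1; a link through a predicted target carries its TESS score —
known evidence always dominates predicted evidence. Diseases are ranked
by their maximum link score, tie-broken by disease id; disease-level
aggregation is otherwise unspecified territory, so the full link table is
always returned. Prediction is defined at the compound level; rolling up
to a formula via the aggregated (union-max) target set is supported but
should be treated as exploratory. Targets absent from the disease map
contribute nothing, by design.

## The synthetic-data generator

`simulate_bundle()` generates the statistical structure the methods
assume, so every stage is testable offline:

* **Ligand families.** Each of 10 families has a core feature profile
  (20 features with fixed counts); a member compound draws a fraction
  `family_feature_overlap` (default 0.8) of its support from the core
  and the rest privately. At overlap 1 members are identical; at 0 they
  are unrelated. Each protein draws 80% of its 8 ligands from one family
  (`ligand_family_purity`), so fingerprint similarity is informative of
  shared targets — the property leave-one-out evaluation measures.
* **Affinities** are log-uniform over 1&nbsp;nM–1&nbsp;mM, guaranteeing
  records on both sides of the 30&nbsp;µM filter (about a quarter are
  filtered out); 10% of records are flagged active irrespective of
  affinity.
* **Hierarchy**: 4 formulas × 3 crude drugs × 5 compounds, sampled so
  compounds can be shared across crude drugs.
* **Annotations**: 20 terms per namespace with sizes uniform on 5–35;
  one designated term receives `planted_term_effect` (default 0.8) of
  the designated query's target set, padded randomly to its nominal
  size. At effect 0 the designated term is generated exactly like any
  other, giving a null calibration case. The maximum term size must be
  able to hold the planted members: the designated formula's known-target
  set reaches the low 30s on a 60-protein universe, which is why the
  upper bound is 35. Because the hypergeometric statistic is discrete,
  null p-values are mildly super-uniform; mixing over random term and
  query sizes smooths the null distribution, but uniformity checks
  (e.g. a KS test across replicates) remain approximate and their
  p-values fluctuate with the seed list.
* **Diseases**: 15 diseases with 2–8 targets each from the universe.

Scale was chosen as a desk-scale screen — 60 proteins, 150 compounds,
480 raw interactions — large enough for stable rank statistics and
smooth null p-value distributions, small enough that the full test suite
(including 100-replicate recovery runs and the exhaustive hypergeometric
enumeration up to $l = 12$) completes in about a minute. All generation
is integer-seeded (`Mersenne-Twister`, rejection sampling) and
byte-reproducible across platforms; the RNG state is restored afterwards.

What the generator does **not** emulate: real descriptor spaces
(475k-dimensional counted substructures), the extreme skew of real
interactomes (10^6 interactions, hub proteins with thousands of ligands),
correlated pathway membership, or promiscuity differences between protein
families. Passing tests therefore demonstrate algorithmic correctness and
the qualitative statistical behaviour of the pipeline, not expected
performance on any real compound library.

## Numerical and design notes

* Identifiers are opaque strings; nothing is validated against external
  registries, so the toolkit runs fully offline.
* Every ordering (ranked outputs, unions, file writers) is deterministic
  — lexicographic by id with explicit numeric formatting — so repeated
  runs are byte-identical, which the test suite asserts end to end
  through the CLI.
* µM→nM conversion is fixed at 1 µM = 1000 nM; the activity threshold is
  strict (`< 30000 nM`), so a record at exactly 30 µM is excluded.
* `bh_fdr` and `hypergeom_tail` are thin, validated surfaces over
  `p.adjust(..., "BH")` and `phyper`; tests compare them against
  hand-computed step-up values and exhaustive draw enumeration rather
  than trusting the wrappers.
* Degenerate inputs are defined, not exceptional: empty compound sets
  union to the empty target set, empty queries give empty (warned)
  enrichment results, and an empty disease overlap is an empty ranking.

## Limitations

The similarity search inherits the limits of ligand-based methods: it
cannot predict targets with no known ligands, and scores are only as
meaningful as the descriptor. Enrichment over union target sets of a
whole formula tends toward generous p-values (many compounds → large
$G_{comp}$, overlapping terms); expression-weighted analyses would be the
next step but are out of scope. Indication matching is restricted to
proteins present in the disease–target map.
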