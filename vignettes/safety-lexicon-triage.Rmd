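---
title: "Safety-lexicon triage: model, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Safety-lexicon triage: model, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxlexicon)
```

## The problem and the model

A gene accumulates annotations in many vocabularies at once: GO-like
function terms, mouse-phenotype terms, literature headings on the articles
that mention it, genetic disease records, pathway memberships, expression
across tissues. A safety reviewer cares about one concern at a time — is
there cardiovascular signal? immune? — and none of those vocabularies is
organized that way. `toxlexicon` bridges the two with a small controlled
*safety lexicon* (SL) of organ-system/mechanism categories and a set of
manually declared mappings from classification terms (and tissues) to SL
terms. Everything downstream is mechanical: mappings are propagated,
red-flags inferred, flags counted and normalized into scores.

The package is organized as a pipeline around one entry point,
`tox_build()`, returning a classed result object that the report, search
and matrix functions consume; we deliberately did not force the
single-fitting-function modelling idiom, because nothing here is an
estimator with residuals or predictions — the products are inferred
associations and normalized ranks.

## Mapping propagation

A mapping declared on a term applies to the term itself and to every
descendant. Annotation ontologies are DAGs, not trees, so a multi-parent
term inherits the **union** of its parents' mapping sets; union is the
only reading consistent with multiple inheritance, and there are no
override semantics — a mapping declared mid-hierarchy adds to, never
replaces, what is inherited. Propagation runs eagerly at build time in
topological order (each term unions its declared SL terms with its
parents' completed sets), making every later lookup O(1). Tissue mappings
are flat and never propagated. The test-suite oracle recomputes every
term's set by a naive ancestor walk on random DAGs, which the eager pass
must match exactly.

## The five flag rules

Each rule emits `(gene, sl, source, evidence)` tuples; duplicates collapse
to one flag (the evidence id keeps two different findings distinct).

* **Direct annotation.** Every gene-to-term annotation in a non-literature
  namespace whose term maps to SL terms.
* **Literature.** A gene counts as linked to a literature term only when
  `min_mesh_articles` (default **3**) distinct articles carry both the
  gene link and the term. The threshold is an empirical spam gate and is
  configurable; 2 articles never flag, 3 always do.
* **Citation transitivity.** A genetic record (OMIM/GA/GWAS-like) is
  flagged through the mapped literature terms of the articles it cites.
  We key this on the per-article term mappings directly, with no
  3-article gate: a record cites a fixed handful of publications, so a
  per-gene article count has no meaning on this path. The flag attaches to
  the record's gene with the record as evidence, which is why the same
  record can legitimately appear flagged in two different category views.
* **Pathway over-representation.** For every pathway × mapped-phenotype
  gene-set pair we compute the one-sided Fisher exact
  (hypergeometric right tail) p-value and apply Benjamini–Hochberg **once
  across the full test family**, so the threshold `q < 1e-5` has a single
  meaning; a per-phenotype family would make the same q incomparable
  across phenotypes. The background universe is all genes in the store —
  the least arbitrary choice given that pathways may span species. A
  pathway needs both `q < 1e-5` and overlap ≥ **5**; passing pathways fan
  their SL terms out to every member gene, which is what makes pathway
  evidence countable per gene in scoring. The full test table is returned
  for audit.
* **Expression.** The statement "expressed in a tissue" needs an
  operational definition; we use: value positive and at or above the
  per-tissue `expression_quantile` (default **0.9**, i.e. top decile,
  computed with the default type-7 quantile; ties at the cutoff are all
  included). This is an interpretation, stated prominently because other
  definitions (absolute thresholds, tissue-specificity indices) are
  defensible; the quantile is configurable.

## Scoring

Flags are counted per gene and category with per-source weights
(defaults: genetic records 2, expression 0.2, others 1 — human genetics is
deliberately emphasized, expression de-emphasized; all overridable in a
`key = value` config file via `weight.<source>` entries). Because per-gene
counts decay exponentially, counts are taken to log10 before min–max
normalization within each species and category:

$$\mathrm{score} = \frac{GFC - MinFC}{MaxFC - MinFC}$$

with the anchors taken over positive counts only; zero-count genes score
exactly 0. Numerical corner cases, decided once:

* **All positive counts equal** (`MaxFC = MinFC`, a 0/0): positive genes
  score 1 — each holds the maximum.
* **Weighted counts below 1** (a lone expression flag at 0.2) give
  negative `GFC`; this is fine because the anchors live on the same scale.
  Clipping to [0, 1] guards floating-point spill only.
* **Cross-species rows.** Normalization is always within species, so the
  human and mouse rows of one homology group in a matrix come from
  different normalizations; the matrix view is for orientation, not
  cross-species comparison.

A score is a rank of information volume, not a risk prediction, and the
package makes no calibration claim. A rank-percentile description of the
same quantity is almost, but not exactly, the min–max formula; the formula
is authoritative here, with a `score_mode = "percentile"` switch kept only
for comparison.

Display bins partition [0, 1]: ≥ 0.9 red, ≥ 0.5 orange, other positive
yellow, exactly 0 green; zero weighted count, zero score and the green bin
coincide by construction.

## The synthetic generator

`fixture_spec()` describes a complete bundle: two species (1000 genes each
by default, 80% joined in 1:1 homology groups), three 40-term ontologies
(complete 3-ary trees of depth 3 plus a 10% chance of a second parent, so
propagation over true DAGs is exercised), a 7-term lexicon (root + six
organ systems), 2000 articles, literature "topics" that attach a gene to
3+ articles sharing a term (so the article gate is exercised from both
sides), 150 genetic records, 40 random pathways and a 10-tissue expression
panel. Per-gene annotation counts are geometric — the discrete analogue of
the exponential decay the log10 normalization expects — and the tests
check the resulting per-gene-per-category flag histogram is monotone
decreasing.

Two properties matter more than realism: every bundle validates, and
generation is deterministic to the byte (each section draws from its own
sub-seed, so appending a plant never reshuffles unrelated entities).
`plant_*()` helpers insert minimal, exactly-predictable signals for each
rule — e.g. `plant_enriched_pathway()` builds a phenotype set and a
pathway with an exact overlap geometry, so whether it must be flagged is
decided by the hypergeometric tail alone. With `background_signal = FALSE`
the bundle is otherwise signal-free and a plant's expected flags can be
asserted exhaustively.

What the generator does *not* emulate: real ontology topology and term
semantics, citation/co-annotation correlation structure in the literature,
pathway biology (background pathways are null by construction), and
cross-source correlation (a truly cardiotoxic gene shows signal in every
source at once). Passing tests therefore demonstrate the *mechanics* —
rules, statistics, normalization, determinism — not performance on real
annotation corpora.

## Problem sizes and budgets

The test suite runs the full pipeline twice on the default 2,000-gene
bundle for the byte-reproducibility check (about two seconds per build),
enumerates the hypergeometric oracle over every universe up to size 12,
checks BH against a textbook step-up on 1,000 random vectors and
propagation against ancestor walks on 100 random DAGs of up to 50 terms —
sizes chosen so the whole suite stays well under a minute while still
covering every boundary in the rules.

## Known limitations

* The manually curated dominant-mutation annotation is carried as a
  pass-through boolean; nothing is computed from it.
* The safety lexicon itself is user content; the shipped categories are a
  demonstration vocabulary, not a curated lexicon.
* HTML output is static; the interactive tooltip behaviour of a web front
  end is reduced to embedded detail text.
* No negative/protective evidence and no per-article relevance weighting:
  every flag counts the same within its source.
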