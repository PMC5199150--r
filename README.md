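# toxlexicon

Early target-safety assessment ("de-risking") asks a simple question with a
painful answer: of everything ever recorded about a gene — ontology
annotations, thousands of literature articles, genetic disease records,
pathway memberships, tissue expression — which pieces bear on *this*
safety concern? `toxlexicon` is an offline triage engine for that question.
It maps heterogeneous gene annotations onto a controlled **safety lexicon
(SL)** — a small vocabulary of organ-system and mechanism toxicity
categories such as `Cardiovascular_System` — so that evidence can be
red-flagged, filtered and ranked per category, for toxicologists and
target-assessment teams who need to focus on one safety area at a time.

## What it computes

Starting from a *bundle* of plain TSV tables (genes, ontologies,
classification-to-lexicon mappings, articles with MeSH-like headings,
gene–article links, genetic records, pathways, expression), the pipeline:

1. **Propagates mappings.** A mapping declared on an ontology term is
   inherited by every descendant; on a multi-parent term the inherited set
   is the union over all parents.
2. **Infers red-flags** — one `(gene, SL term, source, evidence)`
   association per finding — through five rules:
   * *direct annotation*: the gene is annotated with a mapped term;
   * *literature*: ≥ 3 distinct articles link the gene to a mapped
     literature term (the count gate suppresses spurious one-article links);
   * *citation transitivity*: a genetic (OMIM/GA/GWAS-like) record cites an
     article carrying a mapped literature term;
   * *pathway over-representation*: one-sided Fisher exact test of each
     pathway against each mapped phenotype gene-set, Benjamini–Hochberg
     corrected across the whole test family; pathways with `q < 1e-5` and
     overlap ≥ 5 are flagged, fanning out to their member genes;
   * *expression*: the gene sits in the top decile of a mapped tissue.
3. **Scores genes.** Flags are counted with per-source weights (genetic
   records ×2, expression ×1/5, others ×1) and normalized within each
   species and category:

   `SL score = (GFC − MinFC) / (MaxFC − MinFC)`

   with `GFC = log10(weighted count)` for the gene and `MinFC`/`MaxFC` the
   log10 of the smallest/largest positive weighted count in the category
   (zero-count genes score 0). The log10 is appropriate because per-gene
   flag counts decay exponentially. A score measures *information volume*,
   never safety risk. Scores bin for display: ≥ 0.9 red, ≥ 0.5 orange,
   other positive yellow, exactly 0 green.
4. **Renders** category-filtered gene reports (flagged evidence with
   tooltip detail, everything else merely counted), a per-gene
   "Tox-At-A-Glance" score overview, and multi-gene score matrices expanded
   across human/mouse homology groups — as TSV, JSON or static HTML.

A seeded synthetic-bundle generator with plantable signals
(`fixture_spec()`, `plant_*()`, `generate_bundle()`) makes the whole
pipeline testable without any external download.

## Worked example

```r
library(toxlexicon)
dir <- file.path(tempdir(), "bundle")
spec <- fixture_spec(seed = 42)                      # 2000-gene synthetic bundle
spec <- plant_mesh(spec, "HU0007", "Cardiovascular_System", n_articles = 5)
generate_bundle(spec, dir)
res <- tox_build(dir)
res
#> Safety-lexicon triage result
#> Annotation store
#>   genes: 2000 (human 1000, mouse 1000)
#>   ontologies: go_like[40 terms], mesh_like[41 terms], phenotype_like[40 terms]
#>   SL terms: 7; declared mappings: 42
#>   articles: 2005; gene-article links: 10242
#>   genetic records: 150; pathways: 40; expression rows: 20000
#>   red-flags: 26321 (direct_annotation 14875, mesh_literature 9628,
#>     genetic_record 818, pathway 0, expression 1000)
#>   genes with >=1 flag: 1918 / 2000

gene_report(res, "HU0007", "Cardiovascular_System")
#> Gene view: GENE7 (HU0007, human) - category Cardiovascular_System
#>   Tox-At-A-Glance:
#>     Cardiovascular_System        0.728 [orange]
#>     Hepatic_System               0.358 [yellow]
#>     Immune_System                0.661 [orange]
#>     Nervous_System               0.379 [yellow]
#>     Renal_System                 0.635 [orange]
#>     Reproductive_System          0.396 [yellow]
#>   flagged evidence: 4; unflagged: 13
#>     expression:
#>       heart - expression 18.83392436 in heart (cutoff 9.48510656)
#>     mesh_literature:
#>       MH0035 - 4 article(s) annotated with MH0035
#>       MH0036 - 3 article(s) annotated with MH0036
#>       PLTM001 - 5 article(s) annotated with PLTM001
```

Reading the output: the gene carries 17 evidence items in total; selecting
the cardiovascular category red-flags the 4 of them mapped to it — among
them the planted literature signal `PLTM001` with its 5 linked articles —
and hides the other 13. The at-a-glance row shows the gene's SL score in
every top-level category: 0.728 means its log10 weighted cardiovascular
flag count sits 72.8% of the way between the least- and most-annotated
human gene in that category.

A command-line front end over the same functions ships in
`inst/cli/toxlexicon.R` (`build`, `report`, `matrix`, `search`, `synth`).

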