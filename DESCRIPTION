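Package: toxlexicon
Title: Gene Safety Annotation Triage with a Controlled Safety Lexicon
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps heterogeneous gene annotations (ontology terms, literature
    MeSH-style headings, human genetic records, pathways, tissue expression)
    onto a controlled safety lexicon. Declared classification-to-lexicon
    mappings are propagated down each annotation ontology; genes acquire
    red-flags through direct annotation, literature article-count thresholds,
    citation transitivity of genetic records, gene-set over-representation
    (one-sided Fisher exact with Benjamini-Hochberg correction), and
    tissue-expression quantiles. Weighted flag counts per gene and category
    are normalized to a log10 min-max Safety Lexicon score, rendered as
    category-filtered gene reports and gene-by-category score matrices.
    Ships a seeded synthetic bundle generator with plantable signals for
    fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
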