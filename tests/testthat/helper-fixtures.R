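# In-memory raw-bundle builder mirroring read_bundle()'s output, so unit
# tests construct exactly the tables they need without touching disk.

df <- function(...) data.frame(..., stringsAsFactors = FALSE)

raw_bundle <- function(genes = df(gene_id = c("G1", "G2"),
                                  symbol = c("ALPHA", "BETA"),
                                  aliases = c("A1|A2", ""),
                                  species = "human",
                                  homology_group = ""),
                       ontologies = list(
                         go_like = df(term_id = c("A", "B", "C"),
                                      label = c("a", "b", "c"),
                                      parent_ids = c("", "A", "B")),
                         phenotype_like = df(term_id = c("P1", "P2"),
                                             label = c("p1", "p2"),
                                             parent_ids = c("", "P1")),
                         mesh_like = df(term_id = c("M1", "M2"),
                                        label = c("m1", "m2"),
                                        parent_ids = c("", "M1"))),
                       sl_terms = df(sl_id = c("SL_ROOT", "CV", "IS"),
                                     label = c("root", "cardio", "immune"),
                                     parent_id = c("", "SL_ROOT", "SL_ROOT")),
                       mappings = df(source_kind = character(0),
                                     namespace = character(0),
                                     source_id = character(0),
                                     sl_id = character(0)),
                       articles = df(article_id = character(0),
                                     mesh_terms = character(0)),
                       gene_articles = df(gene_id = character(0),
                                          article_id = character(0)),
                       genetic_records = df(record_id = character(0),
                                            kind = character(0),
                                            gene_id = character(0),
                                            cited_articles = character(0),
                                            potential_dominant = character(0)),
                       pathways = df(pathway_id = character(0),
                                     label = character(0),
                                     member_genes = character(0)),
                       expression = df(gene_id = character(0),
                                       tissue = character(0),
                                       value = character(0)),
                       gene_terms = df(gene_id = character(0),
                                       namespace = character(0),
                                       term_id = character(0))) {
  list(genes = genes, ontologies = ontologies, sl_terms = sl_terms,
       mappings = mappings, articles = articles, gene_articles = gene_articles,
       genetic_records = genetic_records, pathways = pathways,
       expression = expression, gene_terms = gene_terms)
}

map_row <- function(source_id, sl_id, namespace = "go_like",
                    source_kind = "ontology_term") {
  df(source_kind = source_kind,
     namespace = if (source_kind == "tissue") "" else namespace,
     source_id = source_id, sl_id = sl_id)
}

# n genes in one species, useful for scoring tests
gene_table <- function(n, species = "human", prefix = "G") {
  df(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
     symbol = sprintf("SYM%d", seq_len(n)), aliases = "", species = species,
     homology_group = "")
}

flag_row <- function(gene_id, sl_id, source, evidence_id, detail = "") {
  df(gene_id = gene_id, sl_id = sl_id, source = source,
     evidence_id = evidence_id, detail = detail)
}
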