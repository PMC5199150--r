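# Shared small store: gene G1 annotated with term C (chain A->B->C, A
# mapped to CV), G2 unannotated.
direct_store <- function(extra_terms = NULL) {
  gt <- df(gene_id = "G1", namespace = "go_like", term_id = "C")
  if (!is.null(extra_terms)) gt <- rbind(gt, extra_terms)
  validate_store(raw_bundle(mappings = map_row("A", "CV"), gene_terms = gt))
}

test_that("direct annotation flags follow propagated mappings", {
  store <- direct_store()
  flags <- flag_direct(store, build_mapping_index(store))
  expect_identical(nrow(flags), 1L)
  expect_identical(flags$gene_id, "G1")
  expect_identical(flags$sl_id, "CV")
  expect_identical(flags$source, "direct_annotation")
  expect_identical(flags$evidence_id, "C")
})

test_that("unmapped annotations yield no flags; distinct terms keep distinct flags", {
  # only unmapped terms annotated
  store <- validate_store(raw_bundle(
    gene_terms = df(gene_id = "G1", namespace = "go_like", term_id = "C")))
  expect_identical(nrow(flag_direct(store, build_mapping_index(store))), 0L)
  # two distinct terms both mapped (B by declaration, C by inheritance) -> 2 flags
  store2 <- direct_store(df(gene_id = "G1", namespace = "go_like",
                            term_id = "B"))
  flags <- flag_direct(store2, build_mapping_index(store2))
  expect_identical(nrow(flags), 2L)
  expect_setequal(flags$evidence_id, c("B", "C"))
  expect_identical(unique(flags$sl_id), "CV")
})

test_that("expression flags the top quantile, degenerate and zero cases included", {
  # one gene, any positive value: trivially the top fraction
  one <- validate_store(raw_bundle(
    mappings = map_row("heart", "CV", source_kind = "tissue"),
    expression = df(gene_id = "G1", tissue = "heart", value = "0.4")))
  f1 <- flag_expression(one, build_mapping_index(one))
  expect_identical(f1$gene_id, "G1")
  expect_identical(f1$evidence_id, "heart")
  # all-zero expression never flags
  zero <- validate_store(raw_bundle(
    mappings = map_row("heart", "CV", source_kind = "tissue"),
    expression = df(gene_id = c("G1", "G2"), tissue = "heart",
                    value = c("0", "0"))))
  expect_identical(nrow(flag_expression(zero, build_mapping_index(zero))), 0L)
  # 10 genes, quantile 0.9: exactly the top gene (brute-force sorted values)
  g <- gene_table(10)
  ten <- validate_store(raw_bundle(
    genes = g,
    mappings = map_row("heart", "CV", source_kind = "tissue"),
    expression = df(gene_id = g$gene_id, tissue = "heart",
                    value = as.character(1:10))))
  f10 <- flag_expression(ten, build_mapping_index(ten))
  expect_identical(f10$gene_id, "G010")
  expect_identical(nrow(f10), 1L)
})

test_that("a mapped tissue with no expression rows warns rather than errors", {
  store <- validate_store(raw_bundle(
    mappings = map_row("heart", "CV", source_kind = "tissue")))
  expect_warning(flags <- flag_expression(store, build_mapping_index(store)),
                 "heart")
  expect_identical(nrow(flags), 0L)
})

mesh_store <- function(n_articles, term = "M2", mapped = TRUE) {
  arts <- sprintf("A%d", seq_len(n_articles))
  validate_store(raw_bundle(
    mappings = if (mapped) map_row(term, "CV", namespace = "mesh_like")
               else raw_bundle()$mappings,
    articles = df(article_id = arts, mesh_terms = term),
    gene_articles = df(gene_id = "G1", article_id = arts)))
}

test_that("literature rule requires three or more linked articles", {
  idx3 <- build_mapping_index(mesh_store(3))
  f3 <- flag_mesh(mesh_store(3), idx3)
  expect_identical(nrow(f3), 1L)
  expect_identical(f3$source, "mesh_literature")
  expect_identical(f3$evidence_id, "M2")
  expect_match(f3$detail, "3 article")

  f2 <- flag_mesh(mesh_store(2), build_mapping_index(mesh_store(2)))
  expect_identical(nrow(f2), 0L)

  # five articles but the term maps to nothing
  s5 <- mesh_store(5, mapped = FALSE)
  expect_identical(nrow(flag_mesh(s5, build_mapping_index(s5))), 0L)
})

test_that("literature flags are monotone in the gene-article link relation", {
  base <- raw_bundle(
    mappings = map_row("M2", "CV", namespace = "mesh_like"),
    articles = df(article_id = sprintf("A%d", 1:6), mesh_terms = "M2"),
    gene_articles = df(gene_id = "G1", article_id = sprintf("A%d", 1:3)))
  f_before <- flag_mesh(validate_store(base),
                        build_mapping_index(validate_store(base)))
  base$gene_articles <- rbind(base$gene_articles,
                              df(gene_id = "G1", article_id = "A4"),
                              df(gene_id = "G2", article_id = "A5"))
  s2 <- validate_store(base)
  f_after <- flag_mesh(s2, build_mapping_index(s2))
  key <- function(f) paste(f$gene_id, f$sl_id, f$evidence_id)
  expect_true(all(key(f_before) %in% key(f_after)))
})

test_that("citation transitivity flags records through cited articles", {
  mk <- function(mesh_terms_a1 = "M2", extra_records = NULL) {
    recs <- df(record_id = "R1", kind = "omim_like", gene_id = "G1",
               cited_articles = "A1", potential_dominant = "false")
    if (!is.null(extra_records)) recs <- rbind(recs, extra_records)
    validate_store(raw_bundle(
      mappings = rbind(map_row("M2", "CV", namespace = "mesh_like"),
                       map_row("M1", "IS", namespace = "mesh_like")),
      articles = df(article_id = c("A1", "A2"),
                    mesh_terms = c(mesh_terms_a1, "M1")),
      genetic_records = recs))
  }
  s <- mk()
  f <- flag_via_citations(s, build_mapping_index(s))
  expect_identical(nrow(f), 2L)   # M2 -> CV, and M2 inherits IS from M1
  expect_setequal(f$sl_id, c("CV", "IS"))
  expect_identical(unique(f$evidence_id), "R1")
  expect_identical(unique(f$source), "genetic_record")

  # record citing two articles mapped to different categories: both flags,
  # same evidence id (union over citations)
  s2 <- validate_store(raw_bundle(
    mappings = rbind(map_row("M2", "CV", namespace = "mesh_like"),
                     map_row("M1", "IS", namespace = "mesh_like")),
    ontologies = local({
      o <- raw_bundle()$ontologies
      o$mesh_like <- df(term_id = c("M1", "M2"), label = c("m1", "m2"),
                        parent_ids = c("", ""))   # unrelated terms
      o
    }),
    articles = df(article_id = c("A1", "A2"), mesh_terms = c("M2", "M1")),
    genetic_records = df(record_id = "R1", kind = "ga_like", gene_id = "G1",
                         cited_articles = "A1|A2",
                         potential_dominant = "false")))
  f2 <- flag_via_citations(s2, build_mapping_index(s2))
  expect_identical(nrow(f2), 2L)
  expect_setequal(f2$sl_id, c("CV", "IS"))
  expect_identical(unique(f2$evidence_id), "R1")

  # citing only articles with unmapped terms -> nothing
  s3 <- validate_store(raw_bundle(
    articles = df(article_id = "A1", mesh_terms = "M1"),
    genetic_records = df(record_id = "R1", kind = "omim_like", gene_id = "G1",
                         cited_articles = "A1", potential_dominant = "false")))
  expect_identical(nrow(flag_via_citations(s3, build_mapping_index(s3))), 0L)
})

test_that("hypergeometric tail matches hand-enumerated cases", {
  # minimum possible overlap of zero -> full tail
  expect_identical(fisher_right_tail(0, 3, 4, 20), 1)
  # forced complete overlap in a degenerate universe
  expect_identical(fisher_right_tail(5, 5, 5, 5), 1)
  # frozen from the binomial-coefficient enumeration oracle: 216/15504
  expect_equal(fisher_right_tail(4, 5, 6, 20), 0.0139318885448916,
               tolerance = 1e-12)
  expect_error(fisher_right_tail(6, 5, 6, 20), "inconsistent")
  expect_error(fisher_right_tail(2, 25, 6, 20), "inconsistent")
})

test_that("BH q-values match the frozen textbook cases", {
  expect_identical(bh_qvalues(0.37), 0.37)             # m = 1
  expect_identical(bh_qvalues(rep(0.2, 5)), rep(0.2, 5))  # rank-invariance
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_qvalues(c(-0.1)), "\\[0, 1\\]")
})

test_that("BH q-values are permutation-equivariant", {
  set.seed(404)
  p <- runif(50)
  perm <- sample.int(50)
  expect_equal(bh_qvalues(p)[perm], bh_qvalues(p[perm]))
})

# Pathway fixture: a phenotype term annotated to `n_flag` genes, one pathway
# with the requested overlap, in a universe of `n_universe` genes.
pathway_store <- function(overlap, pathway_size, n_flag, n_universe) {
  g <- gene_table(n_universe)
  ids <- g$gene_id
  members <- c(ids[seq_len(overlap)],
               ids[n_flag + seq_len(pathway_size - overlap)])
  validate_store(raw_bundle(
    genes = g,
    mappings = map_row("P1", "CV", namespace = "phenotype_like"),
    gene_terms = df(gene_id = ids[seq_len(n_flag)],
                    namespace = "phenotype_like", term_id = "P1"),
    pathways = df(pathway_id = "PW1", label = "pw",
                  member_genes = paste(members, collapse = "|"))))
}

test_that("a nested pathway is flagged and its flags fan out to members", {
  s <- pathway_store(overlap = 40, pathway_size = 40, n_flag = 40,
                     n_universe = 500)
  res <- flag_pathways(s, build_mapping_index(s))
  expect_identical(nrow(res$enrichment), 1L)
  expect_lt(res$enrichment$q_value, 1e-5)
  expect_identical(sort(unique(res$flags$gene_id)),
                   sort(s$pathway_genes$gene_id))
  expect_identical(unique(res$flags$sl_id), "CV")
  expect_identical(unique(res$flags$evidence_id), "PW1")
  # oracle agreement on the exact geometry
  expect_equal(res$enrichment$p_value, hyper_tail_oracle(40, 40, 40, 500))
})

test_that("overlap below five is never flagged regardless of significance", {
  s <- pathway_store(overlap = 4, pathway_size = 4, n_flag = 4,
                     n_universe = 2000)
  res <- flag_pathways(s, build_mapping_index(s))
  expect_lt(res$enrichment$q_value, 1e-5)   # significance is not the blocker
  expect_identical(nrow(res$flags), 0L)
})

test_that("a disjoint pathway is not flagged", {
  s <- pathway_store(overlap = 0, pathway_size = 10, n_flag = 10,
                     n_universe = 100)
  res <- flag_pathways(s, build_mapping_index(s))
  expect_identical(nrow(res$flags), 0L)
  expect_gt(res$enrichment$p_value, 0.1)
})

test_that("threshold saturation flags every overlapping pathway", {
  s <- pathway_store(overlap = 1, pathway_size = 5, n_flag = 10,
                     n_universe = 50)
  cfg <- tox_config(min_overlap = 1, q_threshold = 1)
  res <- flag_pathways(s, build_mapping_index(s), cfg)
  expect_identical(unique(res$flags$evidence_id), "PW1")
})

test_that("the empty universe is an error for pathway flagging", {
  s <- direct_store()
  s$genes <- s$genes[0, , drop = FALSE]
  expect_error(flag_pathways(s, build_mapping_index(s)), "universe")
})

test_that("build_all_flags is the deduplicated union of the per-rule sets", {
  raw <- raw_bundle(
    mappings = rbind(map_row("A", "CV"),
                     map_row("M2", "IS", namespace = "mesh_like"),
                     map_row("heart", "CV", source_kind = "tissue")),
    gene_terms = df(gene_id = "G1", namespace = "go_like", term_id = "C"),
    articles = df(article_id = sprintf("A%d", 1:3), mesh_terms = "M2"),
    gene_articles = df(gene_id = "G2", article_id = sprintf("A%d", 1:3)),
    genetic_records = df(record_id = "R1", kind = "omim_like", gene_id = "G1",
                         cited_articles = "A1", potential_dominant = "false"),
    expression = df(gene_id = "G1", tissue = "heart", value = "5"))
  store <- validate_store(raw)
  idx <- build_mapping_index(store)
  cfg <- tox_config()
  all <- build_all_flags(store, idx, cfg)
  per_rule <- rbind(flag_direct(store, idx),
                    flag_expression(store, idx, cfg),
                    flag_mesh(store, idx, cfg),
                    flag_via_citations(store, idx),
                    flag_pathways(store, idx, cfg)$flags)
  key <- function(f) sort(paste(f$gene_id, f$sl_id, f$source, f$evidence_id))
  expect_identical(key(all$flags), key(per_rule))
  expect_identical(anyDuplicated(key(all$flags)), 0L)
  # empty store -> empty flag set
  empty <- validate_store(raw_bundle())
  eidx <- build_mapping_index(empty)
  expect_identical(nrow(build_all_flags(empty, eidx, cfg)$flags), 0L)
  # determinism: identical store and config give identical flags
  expect_identical(build_all_flags(store, idx, cfg)$flags, all$flags)
})
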