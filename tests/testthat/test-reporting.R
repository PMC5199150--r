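# One gene with evidence in two categories: CV flags from annotation and
# expression, an IS flag from literature, and a genetic record citing
# articles in both areas (so it must appear flagged in both views).
report_result <- function() {
  raw <- raw_bundle(
    genes = df(gene_id = c("G1", "G2"), symbol = c("ALPHA", "BETA"),
               aliases = c("NOSX|shared", "shared"), species = c("human", "mouse"),
               homology_group = ""),
    ontologies = local({
      o <- raw_bundle()$ontologies
      o$mesh_like <- df(term_id = c("M1", "M2"), label = c("m1", "m2"),
                        parent_ids = c("", ""))
      o
    }),
    mappings = rbind(map_row("A", "CV"),
                     map_row("M1", "IS", namespace = "mesh_like"),
                     map_row("M2", "CV", namespace = "mesh_like"),
                     map_row("heart", "CV", source_kind = "tissue")),
    gene_terms = df(gene_id = "G1", namespace = "go_like", term_id = "C"),
    articles = df(article_id = c("A1", "A2", "A3", "A4"),
                  mesh_terms = c("M1", "M1", "M1", "M2")),
    gene_articles = df(gene_id = "G1", article_id = c("A1", "A2", "A3")),
    genetic_records = df(record_id = "R1", kind = "omim_like", gene_id = "G1",
                         cited_articles = "A1|A4",
                         potential_dominant = "false"),
    expression = df(gene_id = "G1", tissue = "heart", value = "4"))
  tox_build(validate_store(raw))
}

test_that("every evidence item lands in exactly one partition per category", {
  res <- report_result()
  ev <- gene_evidence(res, "G1")
  # annotation C, literature M1, record R1, tissue heart
  expect_identical(nrow(ev), 4L)
  for (sl in c("CV", "IS", "SL_ROOT")) {
    rep <- gene_report(res, "G1", sl)
    expect_identical(nrow(rep$flagged) + rep$unflagged_count,
                     rep$total_evidence)
    expect_identical(rep$total_evidence, nrow(ev))
  }
})

test_that("the category filter partitions flagged versus hidden evidence", {
  res <- report_result()
  cv <- gene_report(res, "G1", "CV")
  # CV view: annotation C, expression heart, record R1 (via M2) = 3 flagged
  expect_setequal(paste(cv$flagged$source, cv$flagged$evidence_id),
                  c("direct_annotation C", "expression heart",
                    "genetic_record R1"))
  expect_identical(cv$unflagged_count, 1L)  # the M1 literature link
  is <- gene_report(res, "G1", "IS")
  # IS view: literature M1, record R1 (via M1) - flagged in BOTH views
  expect_setequal(paste(is$flagged$source, is$flagged$evidence_id),
                  c("mesh_literature M1", "genetic_record R1"))
  expect_identical(is$unflagged_count, 2L)
  # a gene with flags only in CV shows zero flagged under another category
  root <- gene_report(res, "G1", "SL_ROOT")
  expect_identical(nrow(root$flagged), 0L)
  expect_identical(root$unflagged_count, root$total_evidence)
})

test_that("at-a-glance covers the top-level categories and mirrors scores", {
  res <- report_result()
  rep <- gene_report(res, "G1", "CV")
  expect_setequal(rep$at_a_glance$sl_id, c("CV", "IS"))  # children of the root
  sc <- res$scores
  for (i in seq_len(nrow(rep$at_a_glance))) {
    expect_identical(rep$at_a_glance$score[i],
                     sc$score[sc$gene_id == "G1" &
                                sc$sl_id == rep$at_a_glance$sl_id[i]])
  }
  expect_error(gene_report(res, "NOPE", "CV"), "unknown gene")
  expect_error(gene_report(res, "G1", "NOPE"), "unknown SL term")
})

test_that("gene search is case-insensitive over id, symbol and aliases", {
  res <- report_result()
  expect_identical(search_genes(res, "alpha")$gene_id, "G1")
  expect_identical(search_genes(res, "g2")$gene_id, "G2")
  # alias shared across species: both genes, human first (species order)
  hit <- search_genes(res, "SHARED")
  expect_identical(hit$gene_id, c("G1", "G2"))
  expect_identical(hit$species, c("human", "mouse"))
  expect_identical(nrow(search_genes(res, "ZZZZ")), 0L)
  expect_identical(search_genes(res, "nos", prefix = TRUE)$gene_id, "G1")
})

test_that("matrix TSV round-trips and report renderings are deterministic", {
  res <- report_result()
  m <- score_matrix(res, c("G1", "G2"))
  tsv <- render_matrix(m, "tsv")
  back <- utils::read.delim(text = tsv, check.names = FALSE)
  expect_identical(back$gene_id, m$genes$gene_id)
  expect_equal(as.numeric(back$CV), unname(round(m$scores[, "CV"], 10)),
               tolerance = 1e-9)

  rep <- gene_report(res, "G1", "CV")
  j1 <- render_report(rep, "json")
  j2 <- render_report(gene_report(res, "G1", "CV"), "json")
  expect_identical(j1, j2)
  parsed <- jsonlite::fromJSON(j1)
  expect_identical(parsed$gene$gene_id, "G1")
  expect_identical(parsed$unflagged_count, 1L)

  html <- render_report(rep, "html")
  expect_identical(lengths(regmatches(html, gregexpr('class="bar ', html))),
                   nrow(rep$at_a_glance))
  mhtml <- render_matrix(m, "html")
  expect_true(grepl("bin-", mhtml))
  expect_error(render_report(rep, "docx"))
})

test_that("rendered files are written byte-stably", {
  res <- report_result()
  rep <- gene_report(res, "G1", "CV")
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  render_report(rep, "tsv", f1)
  render_report(rep, "tsv", f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
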