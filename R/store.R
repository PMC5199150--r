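#' Read an annotation bundle directory
#'
#' A bundle is a directory of UTF-8 tab-delimited files with header rows:
#' `genes.tsv`, one `ontology_<namespace>.tsv` per annotation ontology
#' (`go_like`, `phenotype_like`, `mesh_like`), `sl_terms.tsv`, `mappings.tsv`,
#' `articles.tsv`, `gene_articles.tsv`, `genetic_records.tsv`, `pathways.tsv`,
#' `expression.tsv` and `gene_terms.tsv`. Multi-valued fields
#' (`aliases`, `parent_ids`, `mesh_terms`, `cited_articles`, `member_genes`)
#' are pipe-separated; the empty string marks an absent optional value.
#'
#' The result is raw (character) tables; pass it to [validate_store()] to
#' obtain the validated container the rest of the pipeline consumes.
#'
#' @param dir path to the bundle directory.
#' @return a named list of raw tables, one element per bundle file, with
#'   ontologies nested under `$ontologies` keyed by namespace.
#' @seealso [validate_store()], [generate_bundle()]
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir, call. = FALSE)
  p <- function(f) file.path(dir, f)
  ont_files <- list.files(dir, pattern = "^ontology_.+\\.tsv$")
  namespaces <- sub("^ontology_(.+)\\.tsv$", "\\1", ont_files)
  ontologies <- lapply(seq_along(ont_files), function(i) {
    read_tsv(p(ont_files[i]), c("term_id", "label", "parent_ids"))
  })
  names(ontologies) <- namespaces
  list(
    genes           = read_tsv(p("genes.tsv"),
                               c("gene_id", "symbol", "aliases", "species", "homology_group")),
    ontologies      = ontologies,
    sl_terms        = read_tsv(p("sl_terms.tsv"), c("sl_id", "label", "parent_id")),
    mappings        = read_tsv(p("mappings.tsv"),
                               c("source_kind", "namespace", "source_id", "sl_id")),
    articles        = read_tsv(p("articles.tsv"), c("article_id", "mesh_terms")),
    gene_articles   = read_tsv(p("gene_articles.tsv"), c("gene_id", "article_id")),
    genetic_records = read_tsv(p("genetic_records.tsv"),
                               c("record_id", "kind", "gene_id", "cited_articles",
                                 "potential_dominant")),
    pathways        = read_tsv(p("pathways.tsv"), c("pathway_id", "label", "member_genes")),
    expression      = read_tsv(p("expression.tsv"), c("gene_id", "tissue", "value")),
    gene_terms      = read_tsv(p("gene_terms.tsv"), c("gene_id", "namespace", "term_id"))
  )
}

#' Validate raw bundle tables into an annotation store
#'
#' Checks referential closure (every foreign key resolves), uniqueness of
#' primary keys, the DAG property of every annotation-ontology namespace and
#' acyclicity of the safety-lexicon tree, then freezes the tables into a
#' `tox_store`. All violations are collected and reported together, each
#' naming the table, offending row and key; a namespace cycle is reported
#' with the member terms of one concrete cycle.
#'
#' Validation is idempotent: re-validating the tables of a valid store
#' reproduces it exactly.
#'
#' @param raw raw tables as returned by [read_bundle()], or a path to a
#'   bundle directory (read for you).
#' @return an object of class `tox_store`: the validated, referentially
#'   closed container with parsed multi-value fields (`articles` flattened to
#'   `article_terms`, citations to `record_citations`, pathway membership to
#'   `pathway_genes`) and numeric `expression$value`.
#' @examples
#' dir <- tempfile()
#' generate_bundle(fixture_spec(seed = 1, n_genes = c(human = 20, mouse = 20),
#'                              n_articles = 30, n_pathways = 4,
#'                              n_genetic_records = 5), dir)
#' store <- validate_store(read_bundle(dir))
#' store
#' @export
validate_store <- function(raw) {
  if (is.character(raw) && length(raw) == 1L) raw <- read_bundle(raw)
  errs <- character(0)
  bad <- function(fmt, ...) errs[[length(errs) + 1L]] <<- sprintf(fmt, ...)

  genes <- raw$genes
  if (anyDuplicated(genes$gene_id)) {
    for (g in unique(genes$gene_id[duplicated(genes$gene_id)]))
      bad("genes.tsv: duplicate gene_id '%s'", g)
  }
  blank <- which(!nzchar(genes$symbol))
  for (i in blank) bad("genes.tsv row %d: empty symbol for gene '%s'", i, genes$gene_id[i])
  gene_ids <- genes$gene_id

  ontologies <- list()
  raw$ontologies <- raw$ontologies[sort(names(raw$ontologies))]
  for (ns in names(raw$ontologies)) {
    tab <- raw$ontologies[[ns]]
    if (anyDuplicated(tab$term_id)) {
      for (t in unique(tab$term_id[duplicated(tab$term_id)]))
        bad("ontology_%s.tsv: duplicate term_id '%s'", ns, t)
    }
    parents <- split_pipe(tab$parent_ids)
    names(parents) <- tab$term_id
    for (i in seq_along(parents)) {
      dangling <- setdiff(parents[[i]], tab$term_id)
      for (d in dangling)
        bad("ontology_%s.tsv row %d: parent '%s' of term '%s' not in namespace",
            ns, i, d, tab$term_id[i])
    }
    cyc <- find_cycle(parents)
    if (!is.null(cyc))
      bad("ontology_%s.tsv: cycle among terms [%s]", ns, paste(cyc, collapse = ", "))
    ontologies[[ns]] <- list(terms = tab[c("term_id", "label")], parents = parents)
  }

  sl <- raw$sl_terms
  if (anyDuplicated(sl$sl_id)) {
    for (s in unique(sl$sl_id[duplicated(sl$sl_id)]))
      bad("sl_terms.tsv: duplicate sl_id '%s'", s)
  }
  for (i in seq_len(nrow(sl))) {
    p <- sl$parent_id[i]
    if (nzchar(p) && !(p %in% sl$sl_id))
      bad("sl_terms.tsv row %d: parent '%s' of SL term '%s' unknown", i, p, sl$sl_id[i])
  }
  sl_adj <- lapply(split_pipe(sl$parent_id), identity)
  names(sl_adj) <- sl$sl_id
  sl_cyc <- find_cycle(sl_adj)
  if (!is.null(sl_cyc))
    bad("sl_terms.tsv: cycle among SL terms [%s]", paste(sl_cyc, collapse = ", "))

  mp <- raw$mappings
  for (i in seq_len(nrow(mp))) {
    kind <- mp$source_kind[i]
    if (!(kind %in% c("ontology_term", "tissue"))) {
      bad("mappings.tsv row %d: unknown source_kind '%s'", i, kind)
      next
    }
    if (!(mp$sl_id[i] %in% sl$sl_id))
      bad("mappings.tsv row %d: unknown sl_id '%s'", i, mp$sl_id[i])
    if (kind == "ontology_term") {
      ns <- mp$namespace[i]
      if (!(ns %in% names(ontologies))) {
        bad("mappings.tsv row %d: unknown namespace '%s'", i, ns)
      } else if (!(mp$source_id[i] %in% names(ontologies[[ns]]$parents))) {
        bad("mappings.tsv row %d: term '%s' not in namespace '%s'",
            i, mp$source_id[i], ns)
      }
    }
  }
  key <- paste(mp$source_kind, mp$namespace, mp$source_id, mp$sl_id)
  if (anyDuplicated(key)) {
    for (i in which(duplicated(key)))
      bad("mappings.tsv row %d: duplicate mapping (%s, %s, %s)",
          i, mp$source_kind[i], mp$source_id[i], mp$sl_id[i])
  }

  art <- raw$articles
  if (anyDuplicated(art$article_id)) {
    for (a in unique(art$article_id[duplicated(art$article_id)]))
      bad("articles.tsv: duplicate article_id '%s'", a)
  }
  mesh_terms_known <- if ("mesh_like" %in% names(ontologies))
    names(ontologies[["mesh_like"]]$parents) else character(0)
  mesh_lists <- split_pipe(art$mesh_terms)
  for (i in seq_along(mesh_lists)) {
    for (d in setdiff(mesh_lists[[i]], mesh_terms_known))
      bad("articles.tsv row %d: mesh term '%s' not in mesh_like ontology", i, d)
  }
  article_terms <- data.frame(
    article_id = rep(art$article_id, lengths(mesh_lists)),
    term_id = unlist(mesh_lists, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE
  )

  ga <- raw$gene_articles
  for (i in which(!(ga$gene_id %in% gene_ids)))
    bad("gene_articles.tsv row %d: unknown gene_id '%s'", i, ga$gene_id[i])
  for (i in which(!(ga$article_id %in% art$article_id)))
    bad("gene_articles.tsv row %d: unknown article_id '%s'", i, ga$article_id[i])

  gr <- raw$genetic_records
  if (anyDuplicated(gr$record_id)) {
    for (r in unique(gr$record_id[duplicated(gr$record_id)]))
      bad("genetic_records.tsv: duplicate record_id '%s'", r)
  }
  for (i in which(!(gr$kind %in% c("omim_like", "ga_like", "gwas_like"))))
    bad("genetic_records.tsv row %d: unknown kind '%s'", i, gr$kind[i])
  for (i in which(!(gr$gene_id %in% gene_ids)))
    bad("genetic_records.tsv row %d: unknown gene_id '%s'", i, gr$gene_id[i])
  cit_lists <- split_pipe(gr$cited_articles)
  for (i in seq_along(cit_lists)) {
    for (d in setdiff(cit_lists[[i]], art$article_id))
      bad("genetic_records.tsv row %d: unknown cited article '%s'", i, d)
  }
  record_citations <- data.frame(
    record_id = rep(gr$record_id, lengths(cit_lists)),
    article_id = unlist(cit_lists, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE
  )

  pw <- raw$pathways
  if (anyDuplicated(pw$pathway_id)) {
    for (p2 in unique(pw$pathway_id[duplicated(pw$pathway_id)]))
      bad("pathways.tsv: duplicate pathway_id '%s'", p2)
  }
  member_lists <- split_pipe(pw$member_genes)
  for (i in seq_along(member_lists)) {
    if (!length(member_lists[[i]]))
      bad("pathways.tsv row %d: pathway '%s' has no member genes", i, pw$pathway_id[i])
    for (d in setdiff(member_lists[[i]], gene_ids))
      bad("pathways.tsv row %d: unknown member gene '%s'", i, d)
  }
  pathway_genes <- data.frame(
    pathway_id = rep(pw$pathway_id, lengths(member_lists)),
    gene_id = unlist(member_lists, use.names = FALSE) %||% character(0),
    stringsAsFactors = FALSE
  )

  ex <- raw$expression
  val <- suppressWarnings(as.numeric(ex$value))
  for (i in which(is.na(val)))
    bad("expression.tsv row %d: non-numeric value '%s'", i, ex$value[i])
  for (i in which(!is.na(val) & val < 0))
    bad("expression.tsv row %d: negative value %s", i, ex$value[i])
  for (i in which(!(ex$gene_id %in% gene_ids)))
    bad("expression.tsv row %d: unknown gene_id '%s'", i, ex$gene_id[i])
  exkey <- paste(ex$gene_id, ex$tissue)
  for (i in which(duplicated(exkey)))
    bad("expression.tsv row %d: duplicate (gene, tissue) pair (%s, %s)",
        i, ex$gene_id[i], ex$tissue[i])

  gt <- raw$gene_terms
  for (i in which(!(gt$gene_id %in% gene_ids)))
    bad("gene_terms.tsv row %d: unknown gene_id '%s'", i, gt$gene_id[i])
  for (i in seq_len(nrow(gt))) {
    ns <- gt$namespace[i]
    if (!(ns %in% names(ontologies))) {
      bad("gene_terms.tsv row %d: unknown namespace '%s'", i, ns)
    } else if (!(gt$term_id[i] %in% names(ontologies[[ns]]$parents))) {
      bad("gene_terms.tsv row %d: unknown term '%s' in namespace '%s'",
          i, gt$term_id[i], ns)
    }
  }

  if (length(errs)) {
    stop("bundle validation failed:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  }

  genes_out <- genes
  genes_out$aliases <- split_pipe(genes$aliases)
  ex_out <- ex
  ex_out$value <- val

  structure(list(
    genes = genes_out,
    ontologies = ontologies,
    sl_terms = sl,
    mappings = mp,
    articles = art["article_id"],
    article_terms = article_terms,
    gene_articles = ga,
    genetic_records = gr[c("record_id", "kind", "gene_id", "potential_dominant")],
    record_citations = record_citations,
    pathways = pw[c("pathway_id", "label")],
    pathway_genes = pathway_genes,
    expression = ex_out,
    gene_terms = gt
  ), class = "tox_store")
}

#' @export
print.tox_store <- function(x, ...) {
  cat("Annotation store\n")
  sp <- table(x$genes$species)
  cat(sprintf("  genes: %d (%s)\n", nrow(x$genes),
              paste(sprintf("%s %d", names(sp), sp), collapse = ", ")))
  cat(sprintf("  ontologies: %s\n",
              paste(sprintf("%s[%d terms]", names(x$ontologies),
                            vapply(x$ontologies, function(o) nrow(o$terms), 0L)),
                    collapse = ", ")))
  cat(sprintf("  SL terms: %d; declared mappings: %d\n",
              nrow(x$sl_terms), nrow(x$mappings)))
  cat(sprintf("  articles: %d; gene-article links: %d\n",
              nrow(x$articles), nrow(x$gene_articles)))
  cat(sprintf("  genetic records: %d; pathways: %d; expression rows: %d\n",
              nrow(x$genetic_records), nrow(x$pathways), nrow(x$expression)))
  invisible(x)
}
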