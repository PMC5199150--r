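# Seeded synthetic bundle generator. Every section of the bundle draws from
# its own sub-seed so appending a plant never reshuffles unrelated entities,
# and the same spec + seed is byte-identical on disk.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
  })
  set.seed(seed)
  force(code)
}

NS_PREFIX <- c(go_like = "GO", phenotype_like = "MP", mesh_like = "MH")

#' Specification of a synthetic annotation bundle
#'
#' Describes a complete bundle: two species with partial 1:1 homology,
#' three annotation ontologies (a GO-like and a phenotype-like namespace for
#' direct gene annotation, a MeSH-like namespace for literature), a small
#' safety lexicon with organ-system categories, declared mappings, articles
#' with literature terms, gene-article links, genetic records, pathways and
#' gene-by-tissue expression. Per-gene annotation counts are drawn from a
#' geometric (discretized exponential) distribution so that red-flag counts
#' per gene decay exponentially, the regime the log10 score normalization
#' is designed for.
#'
#' With `background_signal = FALSE` only structural entities (genes,
#' ontologies, lexicon) are generated and every annotation comes from a
#' plant, so each planted signal can be checked to produce exactly its
#' expected flags and nothing else.
#'
#' @param seed integer master seed.
#' @param n_genes named integer vector, genes per species.
#' @param homolog_fraction fraction of gene pairs joined into 1:1
#'   human-mouse homology groups.
#' @param ontology_depth,ontology_branching shape of each (complete
#'   b-ary tree) ontology before extra parents are added.
#' @param extra_parent_prob probability a non-top term gains a second
#'   parent, turning the tree into a DAG.
#' @param n_articles article count.
#' @param mean_topics_per_gene Poisson mean of literature "topics" per gene;
#'   each topic links the gene to 3+ articles sharing one term.
#' @param mean_noise_links Poisson mean of additional random gene-article
#'   links.
#' @param mean_annotations geometric mean of direct annotations per gene
#'   and namespace.
#' @param n_genetic_records,n_pathways,pathway_size_range sizes of the
#'   genetics and pathway sections.
#' @param tissues tissue panel for the expression table.
#' @param sl_categories top-level safety-lexicon categories (children of a
#'   single root).
#' @param background_signal generate random annotation content (`TRUE`) or
#'   a signal-free skeleton for plant testing (`FALSE`).
#' @param plants list of planted signals; use the `plant_*` helpers.
#' @return a list of class `tox_fixture_spec`.
#' @seealso [generate_bundle()], [plant_direct()], [plant_enriched_pathway()]
#' @export
fixture_spec <- function(seed = 1L,
                         n_genes = c(human = 1000L, mouse = 1000L),
                         homolog_fraction = 0.8,
                         ontology_depth = 3L,
                         ontology_branching = 3L,
                         extra_parent_prob = 0.1,
                         n_articles = 2000L,
                         mean_topics_per_gene = 0.6,
                         mean_noise_links = 2,
                         mean_annotations = 2,
                         n_genetic_records = 150L,
                         n_pathways = 40L,
                         pathway_size_range = c(10L, 60L),
                         tissues = c("liver", "heart", "kidney", "brain",
                                     "lung", "spleen", "muscle", "adipose",
                                     "intestine", "skin"),
                         sl_categories = c("Cardiovascular_System",
                                           "Immune_System", "Hepatic_System",
                                           "Renal_System", "Nervous_System",
                                           "Reproductive_System"),
                         background_signal = TRUE,
                         plants = list()) {
  stopifnot(length(n_genes) >= 1, all(n_genes >= 1), !is.null(names(n_genes)),
            seed == floor(seed), abs(seed) < 2^30,
            ontology_depth >= 1, ontology_branching >= 1,
            n_articles >= 1, length(sl_categories) >= 1)
  structure(as.list(environment()), class = "tox_fixture_spec")
}

gene_ids_for <- function(spec) {
  sp <- names(spec$n_genes)
  out <- lapply(seq_along(sp), function(i) {
    pre <- toupper(substr(sp[i], 1, 2))
    sprintf("%s%04d", pre, seq_len(spec$n_genes[[i]]))
  })
  names(out) <- sp
  out
}

# Complete b-ary tree in breadth-first index order plus random extra
# parents; returns term table and parent list.
gen_ontology <- function(prefix, depth, branching, extra_parent_prob) {
  n <- sum(branching^(0:depth))
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  level <- integer(n)
  parent1 <- integer(n)
  for (i in 2:n) {
    parent1[i] <- (i - 2L) %/% branching + 1L
    level[i] <- level[parent1[i]] + 1L
  }
  parents <- vector("list", n)
  parents[[1]] <- character(0)
  for (i in 2:n) parents[[i]] <- ids[parent1[i]]
  extra <- which(level >= 2 & stats::runif(n) < extra_parent_prob)
  for (i in extra) {
    cand <- which(level < level[i] & seq_len(n) != parent1[i])
    if (length(cand)) {
      parents[[i]] <- sort(unique(c(parents[[i]],
                                    ids[cand[sample.int(length(cand), 1L)]])))
    }
  }
  names(parents) <- ids
  list(terms = data.frame(term_id = ids,
                          label = sprintf("%s term %d", prefix, seq_len(n)),
                          stringsAsFactors = FALSE),
       parents = parents, level = level)
}

TISSUE_SL <- c(heart = "Cardiovascular_System", spleen = "Immune_System",
               liver = "Hepatic_System", kidney = "Renal_System",
               brain = "Nervous_System")

#' Plant a direct-annotation signal
#'
#' Adds a two-term chain to the GO-like ontology (a mapped parent and an
#' annotated child), so that after the build the gene carries exactly one
#' direct-annotation flag for `sl_id`, evidenced by the child term —
#' exercising mapping propagation end to end.
#'
#' @param spec a `tox_fixture_spec`.
#' @param gene_id target gene (must exist in the generated bundle).
#' @param sl_id target SL category.
#' @return the spec with the plant appended.
#' @export
plant_direct <- function(spec, gene_id, sl_id) {
  add_plant(spec, list(type = "direct", gene_id = gene_id, sl_id = sl_id))
}

#' Plant a literature (MeSH-rule) signal
#'
#' Creates a fresh mapped literature term and `n_articles` articles
#' annotated with it, all linked to the gene; with the default
#' `n_articles = 3` the gene sits exactly on the article-count gate.
#'
#' @inheritParams plant_direct
#' @param n_articles number of planted gene-linked articles.
#' @export
plant_mesh <- function(spec, gene_id, sl_id, n_articles = 3L) {
  stopifnot(n_articles >= 1)
  add_plant(spec, list(type = "mesh", gene_id = gene_id, sl_id = sl_id,
                       n_articles = as.integer(n_articles)))
}

#' Plant a citation-transitive genetic-record signal
#'
#' Creates a genetic record for the gene citing one article that carries a
#' freshly mapped literature term; the article is *not* gene-linked, so the
#' only resulting flag is the record's.
#'
#' @inheritParams plant_direct
#' @param kind record kind (`omim_like`, `ga_like`, `gwas_like`).
#' @export
plant_citation <- function(spec, gene_id, sl_id, kind = "omim_like") {
  stopifnot(kind %in% c("omim_like", "ga_like", "gwas_like"))
  add_plant(spec, list(type = "citation", gene_id = gene_id, sl_id = sl_id,
                       kind = kind))
}

#' Plant a tissue-expression signal
#'
#' Adds a dedicated mapped tissue in which only the planted gene is
#' expressed, so the gene is trivially in the top expression fraction and
#' receives one expression flag.
#'
#' @inheritParams plant_direct
#' @param tissue tissue name; must not collide with the background tissue
#'   panel. Defaults to a reserved planted name.
#' @export
plant_expression <- function(spec, gene_id, sl_id, tissue = NULL) {
  if (!is.null(tissue) && tissue %in% spec$tissues) {
    stop("planted tissue must not be in the background tissue panel",
         call. = FALSE)
  }
  add_plant(spec, list(type = "expression", gene_id = gene_id, sl_id = sl_id,
                       tissue = tissue))
}

#' Plant an enriched pathway with exact overlap geometry
#'
#' Creates a mapped phenotype term annotated to `flagged_set_size` genes
#' and a pathway of `pathway_size` genes sharing exactly `overlap` members
#' with that set; successive pathway plants draw disjoint gene blocks.
#' Whether the pathway is red-flagged at the defaults is then decided by
#' the hypergeometric tail of that exact geometry.
#'
#' @inheritParams plant_direct
#' @param overlap,pathway_size,flagged_set_size overlap geometry; must be
#'   satisfiable within the species' gene count or generation errors.
#' @param species species whose genes are used; default the first.
#' @export
plant_enriched_pathway <- function(spec, sl_id, overlap, pathway_size,
                                   flagged_set_size,
                                   species = names(spec$n_genes)[1L]) {
  if (overlap > min(pathway_size, flagged_set_size) || overlap < 0 ||
      pathway_size < 1 || flagged_set_size < 1) {
    stop("inconsistent pathway plant counts", call. = FALSE)
  }
  add_plant(spec, list(type = "pathway", sl_id = sl_id,
                       overlap = as.integer(overlap),
                       pathway_size = as.integer(pathway_size),
                       flagged_set_size = as.integer(flagged_set_size),
                       species = species))
}

add_plant <- function(spec, plant) {
  stopifnot(inherits(spec, "tox_fixture_spec"))
  spec$plants[[length(spec$plants) + 1L]] <- plant
  spec
}

#' Generate a synthetic annotation bundle on disk
#'
#' Writes the complete TSV bundle described by `spec` into `dir`. The
#' output always passes [validate_store()]; the same spec and seed produce
#' byte-identical files; every planted signal manifests as its expected
#' red-flag(s) after [tox_build()]. Unsatisfiable plants (unknown gene,
#' pathway geometry exceeding the gene pool) error at generation time.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created; existing bundle files are
#'   overwritten).
#' @return `dir`, invisibly.
#' @export
generate_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "tox_fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(spec$seed)
  ids_by_sp <- gene_ids_for(spec)
  all_genes <- unlist(ids_by_sp, use.names = FALSE)

  # --- genes ---------------------------------------------------------------
  sp_names <- names(spec$n_genes)
  symbol_case <- function(sym, i) if (i == 1L) toupper(sym) else sym
  genes <- do.call(rbind, lapply(seq_along(sp_names), function(i) {
    n <- spec$n_genes[[i]]
    data.frame(gene_id = ids_by_sp[[i]],
               symbol = symbol_case(sprintf("Gene%d", seq_len(n)), i),
               species = sp_names[i], stringsAsFactors = FALSE)
  }))
  n_hom <- if (length(sp_names) >= 2L)
    floor(spec$homolog_fraction * min(spec$n_genes[1:2])) else 0L
  genes$homology_group <- ""
  if (n_hom > 0) {
    hg <- sprintf("HG%04d", seq_len(n_hom))
    genes$homology_group[match(ids_by_sp[[1L]][seq_len(n_hom)],
                               genes$gene_id)] <- hg
    genes$homology_group[match(ids_by_sp[[2L]][seq_len(n_hom)],
                               genes$gene_id)] <- hg
  }
  genes$aliases <- with_seed(seed + 1L, vapply(seq_len(nrow(genes)),
    function(i) {
      k <- sample(0:2, 1L)
      if (!k) "" else join_pipe(sprintf("%s_AL%d", genes$symbol[i], seq_len(k)))
    }, ""))

  # --- ontologies ----------------------------------------------------------
  onts <- with_seed(seed + 2L, lapply(names(NS_PREFIX), function(ns)
    gen_ontology(NS_PREFIX[[ns]], spec$ontology_depth,
                 spec$ontology_branching, spec$extra_parent_prob)))
  names(onts) <- names(NS_PREFIX)

  # --- safety lexicon ------------------------------------------------------
  sl <- data.frame(
    sl_id = c("Safety_Lexicon", spec$sl_categories),
    label = c("Safety lexicon root", gsub("_", " ", spec$sl_categories)),
    parent_id = c("", rep("Safety_Lexicon", length(spec$sl_categories))),
    stringsAsFactors = FALSE
  )

  # --- declared mappings ---------------------------------------------------
  mappings <- data.frame(source_kind = character(0), namespace = character(0),
                         source_id = character(0), sl_id = character(0),
                         stringsAsFactors = FALSE)
  if (spec$background_signal) {
    mappings <- with_seed(seed + 3L, {
      rows <- list()
      for (ns in names(onts)) {
        mid <- onts[[ns]]$terms$term_id[onts[[ns]]$level %in% c(1L, 2L)]
        for (cat in spec$sl_categories) {
          pick <- sample(mid, min(2L, length(mid)))
          rows[[paste(ns, cat)]] <- data.frame(
            source_kind = "ontology_term", namespace = ns, source_id = pick,
            sl_id = cat, stringsAsFactors = FALSE)
        }
      }
      tis <- TISSUE_SL[names(TISSUE_SL) %in% spec$tissues &
                         TISSUE_SL %in% spec$sl_categories]
      if (length(tis)) {
        rows[["tissue"]] <- data.frame(
          source_kind = "tissue", namespace = "", source_id = names(tis),
          sl_id = unname(tis), stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
    key <- paste(mappings$source_kind, mappings$namespace, mappings$source_id,
                 mappings$sl_id)
    mappings <- mappings[!duplicated(key), , drop = FALSE]
  }

  # --- direct gene-term annotations ---------------------------------------
  gene_terms <- data.frame(gene_id = character(0), namespace = character(0),
                           term_id = character(0), stringsAsFactors = FALSE)
  if (spec$background_signal) {
    gene_terms <- with_seed(seed + 4L, {
      rows <- list()
      for (ns in c("go_like", "phenotype_like")) {
        pool <- onts[[ns]]$terms$term_id[onts[[ns]]$level >= 1L]
        k <- pmin(stats::rgeom(length(all_genes),
                               1 / (1 + spec$mean_annotations)), 15L)
        idx <- which(k > 0)
        rows[[ns]] <- data.frame(
          gene_id = rep(all_genes[idx], k[idx]),
          namespace = ns,
          term_id = unlist(lapply(k[idx], function(m)
            sample(pool, min(m, length(pool)))), use.names = FALSE),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    })
  }

  # --- articles, literature terms, gene-article links ---------------------
  articles <- data.frame(article_id = character(0), mesh_terms = character(0),
                         stringsAsFactors = FALSE)
  gene_articles <- data.frame(gene_id = character(0), article_id = character(0),
                              stringsAsFactors = FALSE)
  if (spec$background_signal) {
    mesh_pool <- onts$mesh_like$terms$term_id[onts$mesh_like$level >= 1L]
    art_ids <- sprintf("A%06d", seq_len(spec$n_articles))
    art_terms <- with_seed(seed + 5L, lapply(seq_len(spec$n_articles),
      function(i) sample(mesh_pool, min(1L + stats::rpois(1L, 1),
                                        length(mesh_pool)))))
    links <- with_seed(seed + 6L, {
      rows <- list()
      for (g in all_genes) {
        n_topics <- stats::rpois(1L, spec$mean_topics_per_gene)
        arts <- character(0)
        for (t in seq_len(n_topics)) {
          term <- sample(mesh_pool, 1L)
          n_art <- min(3L + stats::rpois(1L, 2), spec$n_articles)
          picked <- sample(art_ids, n_art)
          for (a in picked) {
            j <- match(a, art_ids)
            art_terms[[j]] <- unique(c(art_terms[[j]], term))
          }
          arts <- c(arts, picked)
        }
        noise <- stats::rpois(1L, spec$mean_noise_links)
        if (noise) arts <- c(arts, sample(art_ids, min(noise, spec$n_articles)))
        if (length(arts)) {
          rows[[g]] <- data.frame(gene_id = g, article_id = unique(arts),
                                  stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows %||% list())
    })
    articles <- data.frame(
      article_id = art_ids,
      mesh_terms = vapply(art_terms, function(v) join_pipe(sort(v)), ""),
      stringsAsFactors = FALSE)
    if (!is.null(links)) gene_articles <- links
  }

  # --- genetic records -----------------------------------------------------
  genetic_records <- data.frame(record_id = character(0), kind = character(0),
                                gene_id = character(0),
                                cited_articles = character(0),
                                potential_dominant = character(0),
                                stringsAsFactors = FALSE)
  if (spec$background_signal && spec$n_genetic_records > 0 &&
      nrow(articles) > 0) {
    genetic_records <- with_seed(seed + 7L, {
      n <- spec$n_genetic_records
      data.frame(
        record_id = sprintf("GR%04d", seq_len(n)),
        kind = sample(c("omim_like", "ga_like", "gwas_like"), n, replace = TRUE),
        gene_id = sample(all_genes, n, replace = TRUE),
        cited_articles = vapply(seq_len(n), function(i)
          join_pipe(sort(sample(articles$article_id,
                                min(1L + stats::rpois(1L, 1),
                                    nrow(articles))))), ""),
        potential_dominant = ifelse(stats::runif(n) < 0.1, "true", "false"),
        stringsAsFactors = FALSE)
    })
  }

  # --- pathways ------------------------------------------------------------
  pathways <- data.frame(pathway_id = character(0), label = character(0),
                         member_genes = character(0), stringsAsFactors = FALSE)
  if (spec$background_signal && spec$n_pathways > 0) {
    pathways <- with_seed(seed + 8L, {
      n <- spec$n_pathways
      sizes <- sample(seq(spec$pathway_size_range[1L],
                          spec$pathway_size_range[2L]), n, replace = TRUE)
      sizes <- pmin(sizes, length(all_genes))
      data.frame(
        pathway_id = sprintf("PW%04d", seq_len(n)),
        label = sprintf("pathway %d", seq_len(n)),
        member_genes = vapply(sizes, function(s)
          join_pipe(sort(sample(all_genes, s))), ""),
        stringsAsFactors = FALSE)
    })
  }

  # --- expression ----------------------------------------------------------
  expression <- data.frame(gene_id = character(0), tissue = character(0),
                           value = character(0), stringsAsFactors = FALSE)
  if (spec$background_signal && length(spec$tissues)) {
    expression <- with_seed(seed + 9L, {
      grid <- expand.grid(gene_id = all_genes, tissue = spec$tissues,
                          stringsAsFactors = FALSE)
      v <- stats::rlnorm(nrow(grid), meanlog = 1, sdlog = 1)
      v[stats::runif(nrow(grid)) < 0.08] <- 0
      grid$value <- fmt_num(v)
      grid
    })
  }

  # --- plants --------------------------------------------------------------
  pw_gene_offset <- 0L
  ont_extra <- list(go_like = list(), phenotype_like = list(),
                    mesh_like = list())
  for (i in seq_along(spec$plants)) {
    pl <- spec$plants[[i]]
    if (!is.null(pl$gene_id) && !(pl$gene_id %in% all_genes)) {
      stop(sprintf("plant %d references unknown gene '%s'", i, pl$gene_id),
           call. = FALSE)
    }
    if (!(pl$sl_id %in% sl$sl_id)) {
      stop(sprintf("plant %d references unknown SL term '%s'", i, pl$sl_id),
           call. = FALSE)
    }
    tag <- sprintf("%03d", i)
    if (pl$type == "direct") {
      parent <- paste0("PLTD", tag, "P"); child <- paste0("PLTD", tag, "C")
      root <- onts$go_like$terms$term_id[1L]
      ont_extra$go_like[[tag]] <- data.frame(
        term_id = c(parent, child),
        label = sprintf("planted direct term %s", c(parent, child)),
        parent_ids = c(root, parent), stringsAsFactors = FALSE)
      mappings <- rbind(mappings, data.frame(
        source_kind = "ontology_term", namespace = "go_like",
        source_id = parent, sl_id = pl$sl_id, stringsAsFactors = FALSE))
      gene_terms <- rbind(gene_terms, data.frame(
        gene_id = pl$gene_id, namespace = "go_like", term_id = child,
        stringsAsFactors = FALSE))
    } else if (pl$type == "mesh") {
      term <- paste0("PLTM", tag)
      root <- onts$mesh_like$terms$term_id[1L]
      ont_extra$mesh_like[[tag]] <- data.frame(
        term_id = term, label = sprintf("planted literature term %s", term),
        parent_ids = root, stringsAsFactors = FALSE)
      mappings <- rbind(mappings, data.frame(
        source_kind = "ontology_term", namespace = "mesh_like",
        source_id = term, sl_id = pl$sl_id, stringsAsFactors = FALSE))
      art <- sprintf("PLTMA%s_%02d", tag, seq_len(pl$n_articles))
      articles <- rbind(articles, data.frame(
        article_id = art, mesh_terms = term, stringsAsFactors = FALSE))
      gene_articles <- rbind(gene_articles, data.frame(
        gene_id = pl$gene_id, article_id = art, stringsAsFactors = FALSE))
    } else if (pl$type == "citation") {
      term <- paste0("PLTC", tag)
      root <- onts$mesh_like$terms$term_id[1L]
      ont_extra$mesh_like[[paste0("c", tag)]] <- data.frame(
        term_id = term, label = sprintf("planted citation term %s", term),
        parent_ids = root, stringsAsFactors = FALSE)
      mappings <- rbind(mappings, data.frame(
        source_kind = "ontology_term", namespace = "mesh_like",
        source_id = term, sl_id = pl$sl_id, stringsAsFactors = FALSE))
      art <- paste0("PLTCA", tag)
      articles <- rbind(articles, data.frame(
        article_id = art, mesh_terms = term, stringsAsFactors = FALSE))
      genetic_records <- rbind(genetic_records, data.frame(
        record_id = paste0("PLTR", tag), kind = pl$kind, gene_id = pl$gene_id,
        cited_articles = art, potential_dominant = "false",
        stringsAsFactors = FALSE))
    } else if (pl$type == "expression") {
      tissue <- pl$tissue %||% sprintf("planted_tissue_%s", tag)
      mappings <- rbind(mappings, data.frame(
        source_kind = "tissue", namespace = "", source_id = tissue,
        sl_id = pl$sl_id, stringsAsFactors = FALSE))
      expression <- rbind(expression, data.frame(
        gene_id = pl$gene_id, tissue = tissue, value = "100",
        stringsAsFactors = FALSE))
    } else if (pl$type == "pathway") {
      pool <- ids_by_sp[[pl$species]]
      need <- pl$flagged_set_size + pl$pathway_size - pl$overlap
      if (pw_gene_offset + need > length(pool)) {
        stop(sprintf("plant %d: pathway geometry needs %d genes, %d available",
                     i, need, length(pool) - pw_gene_offset), call. = FALSE)
      }
      flagged <- pool[pw_gene_offset + seq_len(pl$flagged_set_size)]
      outside <- pool[pw_gene_offset + pl$flagged_set_size +
                        seq_len(pl$pathway_size - pl$overlap)]
      pw_gene_offset <- pw_gene_offset + need
      members <- c(flagged[seq_len(pl$overlap)], outside)
      term <- paste0("PLTP", tag)
      root <- onts$phenotype_like$terms$term_id[1L]
      ont_extra$phenotype_like[[tag]] <- data.frame(
        term_id = term, label = sprintf("planted phenotype %s", term),
        parent_ids = root, stringsAsFactors = FALSE)
      mappings <- rbind(mappings, data.frame(
        source_kind = "ontology_term", namespace = "phenotype_like",
        source_id = term, sl_id = pl$sl_id, stringsAsFactors = FALSE))
      gene_terms <- rbind(gene_terms, data.frame(
        gene_id = flagged, namespace = "phenotype_like", term_id = term,
        stringsAsFactors = FALSE))
      pathways <- rbind(pathways, data.frame(
        pathway_id = paste0("PLTPW", tag),
        label = sprintf("planted pathway %s", tag),
        member_genes = join_pipe(sort(members)), stringsAsFactors = FALSE))
    } else {
      stop("unknown plant type: ", pl$type, call. = FALSE)
    }
  }

  # --- write ---------------------------------------------------------------
  write_tsv(genes[c("gene_id", "symbol", "aliases", "species",
                    "homology_group")], file.path(dir, "genes.tsv"))
  for (ns in names(onts)) {
    tab <- onts[[ns]]$terms
    tab$parent_ids <- vapply(onts[[ns]]$parents, join_pipe, "")
    extra <- ont_extra[[ns]]
    if (length(extra)) tab <- rbind(tab, do.call(rbind, extra))
    write_tsv(tab[c("term_id", "label", "parent_ids")],
              file.path(dir, sprintf("ontology_%s.tsv", ns)))
  }
  write_tsv(sl, file.path(dir, "sl_terms.tsv"))
  write_tsv(mappings, file.path(dir, "mappings.tsv"))
  write_tsv(articles, file.path(dir, "articles.tsv"))
  write_tsv(gene_articles, file.path(dir, "gene_articles.tsv"))
  write_tsv(genetic_records, file.path(dir, "genetic_records.tsv"))
  write_tsv(pathways, file.path(dir, "pathways.tsv"))
  write_tsv(expression, file.path(dir, "expression.tsv"))
  write_tsv(gene_terms, file.path(dir, "gene_terms.tsv"))
  invisible(dir)
}
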