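FLAG_SOURCES <- c("direct_annotation", "mesh_literature", "genetic_record",
                  "pathway", "expression")

empty_flags <- function() {
  data.frame(gene_id = character(0), sl_id = character(0), source = character(0),
             evidence_id = character(0), detail = character(0),
             stringsAsFactors = FALSE)
}

# Collapse duplicate inferences: one flag per (gene, sl, source, evidence),
# rows sorted so downstream output is byte-reproducible.
dedup_flags <- function(flags) {
  if (!nrow(flags)) return(empty_flags())
  o <- order(flags$gene_id, flags$sl_id, flags$source, flags$evidence_id,
             flags$detail, method = "radix")
  flags <- flags[o, , drop = FALSE]
  key <- paste(flags$gene_id, flags$sl_id, flags$source, flags$evidence_id,
               sep = "\r")
  flags <- flags[!duplicated(key), , drop = FALSE]
  rownames(flags) <- NULL
  flags
}

#' Flag-rule thresholds
#'
#' @param min_mesh_articles minimum number of articles linking a gene to a
#'   literature (MeSH-like) term before the term counts as evidence;
#'   default 3. The threshold is empirical and adjustable.
#' @param q_threshold BH-adjusted significance required to red-flag a
#'   pathway; default `1e-5`.
#' @param min_overlap minimum gene overlap between a pathway and a flagged
#'   phenotype gene-set; default 5.
#' @param expression_quantile per-tissue quantile above which a gene counts
#'   as expressed in that tissue; default 0.9 (top decile, ties at the
#'   cutoff included). Zero expression never flags.
#' @param weights named positive multipliers applied per flag source when
#'   counting (see [weighted_counts()]). Defaults: genetic records 2, tissue
#'   expression 1/5, everything else 1.
#' @param score_mode `"minmax"` (the normalization formula; default) or
#'   `"percentile"` (rank-based comparison mode, see the vignette).
#' @return a list of class `tox_config`.
#' @export
tox_config <- function(min_mesh_articles = 3L, q_threshold = 1e-5,
                       min_overlap = 5L, expression_quantile = 0.9,
                       weights = c(direct_annotation = 1, mesh_literature = 1,
                                   genetic_record = 2, pathway = 1,
                                   expression = 0.2),
                       score_mode = c("minmax", "percentile")) {
  score_mode <- match.arg(score_mode)
  stopifnot(min_mesh_articles >= 1, q_threshold > 0, min_overlap >= 1,
            expression_quantile > 0, expression_quantile < 1,
            all(weights > 0))
  structure(list(min_mesh_articles = as.integer(min_mesh_articles),
                 q_threshold = q_threshold,
                 min_overlap = as.integer(min_overlap),
                 expression_quantile = expression_quantile,
                 weights = weights, score_mode = score_mode),
            class = "tox_config")
}

#' Read a flat key = value configuration file
#'
#' Recognized keys are the arguments of [tox_config()]; weights are set as
#' `weight.<source>` (e.g. `weight.genetic_record = 2`). Unknown keys are an
#' error. Lines starting with `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return a `tox_config`.
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- tox_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (startsWith(key, "weight.")) {
      src <- sub("^weight\\.", "", key)
      if (!(src %in% FLAG_SOURCES)) stop("unknown flag source in config: ", src,
                                         call. = FALSE)
      cfg$weights[[src]] <- as.numeric(val)
    } else if (key %in% c("min_mesh_articles", "min_overlap")) {
      cfg[[key]] <- as.integer(val)
    } else if (key %in% c("q_threshold", "expression_quantile")) {
      cfg[[key]] <- as.numeric(val)
    } else if (key == "score_mode") {
      cfg[[key]] <- match.arg(val, c("minmax", "percentile"))
    } else {
      stop("unknown config key: ", key, call. = FALSE)
    }
  }
  do.call(tox_config, unclass(cfg))
}

#' Red-flags from direct ontology annotation
#'
#' Every gene-to-term annotation in a non-literature namespace whose term
#' maps (directly or by propagation) to SL terms yields one flag per SL
#' term, with the annotation term as evidence.
#'
#' @param store validated `tox_store`.
#' @param index `tox_mapping_index`.
#' @return flag data.frame (`gene_id`, `sl_id`, `source`, `evidence_id`,
#'   `detail`).
#' @export
flag_direct <- function(store, index) {
  gt <- store$gene_terms
  gt <- gt[gt$namespace != "mesh_like", , drop = FALSE]
  out <- list()
  for (ns in unique(gt$namespace)) {
    sets <- index$by_source[[ns]]
    mapped <- sets[lengths(sets) > 0L]
    if (!length(mapped)) next
    map_long <- data.frame(term_id = rep(names(mapped), lengths(mapped)),
                           sl_id = unlist(mapped, use.names = FALSE),
                           stringsAsFactors = FALSE)
    sub <- gt[gt$namespace == ns, c("gene_id", "term_id")]
    hit <- merge(sub, map_long, by = "term_id")
    if (!nrow(hit)) next
    out[[ns]] <- data.frame(
      gene_id = hit$gene_id, sl_id = hit$sl_id, source = "direct_annotation",
      evidence_id = hit$term_id,
      detail = sprintf("annotated with %s [%s]", hit$term_id, ns),
      stringsAsFactors = FALSE
    )
  }
  dedup_flags(if (length(out)) do.call(rbind, out) else empty_flags())
}

#' Red-flags from tissue expression
#'
#' A gene is flagged for the SL terms mapped to tissue `t` when its
#' expression value in `t` is positive and lies in the top
#' `1 - expression_quantile` fraction of all genes' values in `t` (ties at
#' the cutoff included). Mapped tissues absent from the expression table
#' produce a warning, not an error.
#'
#' @inheritParams flag_direct
#' @param config a [tox_config()].
#' @return flag data.frame; evidence is the tissue name, detail carries the
#'   value and cutoff.
#' @export
flag_expression <- function(store, index, config = tox_config()) {
  out <- list()
  ex <- store$expression
  for (tissue in names(index$by_tissue)) {
    rows <- ex[ex$tissue == tissue, , drop = FALSE]
    if (!nrow(rows)) {
      warning("tissue '", tissue, "' is mapped but has no expression rows",
              call. = FALSE)
      next
    }
    cutoff <- stats::quantile(rows$value, probs = config$expression_quantile,
                              names = FALSE, type = 7)
    sel <- rows$value >= cutoff & rows$value > 0
    if (!any(sel)) next
    sls <- index$by_tissue[[tissue]]
    hit <- rows[sel, , drop = FALSE]
    out[[tissue]] <- data.frame(
      gene_id = rep(hit$gene_id, each = length(sls)),
      sl_id = rep(sls, times = nrow(hit)),
      source = "expression", evidence_id = tissue,
      detail = rep(sprintf("expression %s in %s (cutoff %s)",
                           fmt_num(hit$value), tissue, fmt_num(cutoff)),
                   each = length(sls)),
      stringsAsFactors = FALSE
    )
  }
  dedup_flags(if (length(out)) do.call(rbind, out) else empty_flags())
}

# Distinct-article count per (gene, literature term); the evidence base for
# flag_mesh and for the literature part of gene_evidence.
mesh_article_counts <- function(store) {
  m <- merge(store$gene_articles, store$article_terms, by = "article_id")
  if (!nrow(m)) {
    return(data.frame(gene_id = character(0), term_id = character(0),
                      n_articles = integer(0), stringsAsFactors = FALSE))
  }
  m <- unique(m[c("gene_id", "term_id", "article_id")])
  key <- paste(m$gene_id, m$term_id, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(gene_id = vapply(parts, `[`, "", 1L),
             term_id = vapply(parts, `[`, "", 2L),
             n_articles = as.integer(tab), stringsAsFactors = FALSE)
}

#' Red-flags from literature term linkage
#'
#' A gene is linked to a literature (MeSH-like) term when at least
#' `min_mesh_articles` distinct articles are both linked to the gene and
#' annotated with the term; the article-count gate suppresses spurious
#' single-article linkages. Linked terms that map to SL terms yield one flag
#' per SL term, with the article count in the detail.
#'
#' @inheritParams flag_expression
#' @return flag data.frame; evidence is the literature term.
#' @export
flag_mesh <- function(store, index, config = tox_config()) {
  cnt <- mesh_article_counts(store)
  cnt <- cnt[cnt$n_articles >= config$min_mesh_articles, , drop = FALSE]
  sets <- index$by_source[["mesh_like"]] %||% list()
  if (!nrow(cnt) || !length(sets)) return(empty_flags())
  mapped <- sets[lengths(sets) > 0L]
  if (!length(mapped)) return(empty_flags())
  map_long <- data.frame(term_id = rep(names(mapped), lengths(mapped)),
                         sl_id = unlist(mapped, use.names = FALSE),
                         stringsAsFactors = FALSE)
  hit <- merge(cnt, map_long, by = "term_id")
  if (!nrow(hit)) return(empty_flags())
  dedup_flags(data.frame(
    gene_id = hit$gene_id, sl_id = hit$sl_id, source = "mesh_literature",
    evidence_id = hit$term_id,
    detail = sprintf("%d article(s) annotated with %s", hit$n_articles,
                     hit$term_id),
    stringsAsFactors = FALSE
  ))
}

#' Red-flags from genetic records via citation transitivity
#'
#' A genetic (OMIM/GA/GWAS-like) record is flagged with SL term `s` when any
#' article it cites carries a literature term mapped to `s`; the flag is
#' attributed to the record's gene with the record as evidence. The mapping
#' is taken per cited article directly — no article-count gate applies on
#' this path, since a record cites a fixed small set of publications.
#'
#' @inheritParams flag_direct
#' @return flag data.frame; evidence is the record id, detail lists the
#'   record kind and the mapped literature terms behind the flag.
#' @export
flag_via_citations <- function(store, index) {
  m <- merge(store$record_citations, store$article_terms, by = "article_id")
  sets <- index$by_source[["mesh_like"]] %||% list()
  mapped <- sets[lengths(sets) > 0L]
  if (!nrow(m) || !length(mapped)) return(empty_flags())
  map_long <- data.frame(term_id = rep(names(mapped), lengths(mapped)),
                         sl_id = unlist(mapped, use.names = FALSE),
                         stringsAsFactors = FALSE)
  hit <- unique(merge(m[c("record_id", "term_id")], map_long,
                      by = "term_id")[c("record_id", "sl_id", "term_id")])
  if (!nrow(hit)) return(empty_flags())
  # aggregate the supporting terms per (record, sl) into one tooltip detail
  key <- paste(hit$record_id, hit$sl_id, sep = "\r")
  terms_by <- lapply(split(hit$term_id, key), function(v) sort(unique(v)))
  parts <- strsplit(names(terms_by), "\r", fixed = TRUE)
  agg <- data.frame(record_id = vapply(parts, `[`, "", 1L),
                    sl_id = vapply(parts, `[`, "", 2L),
                    terms = vapply(terms_by, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  agg <- merge(agg, store$genetic_records[c("record_id", "kind", "gene_id")],
               by = "record_id")
  dedup_flags(data.frame(
    gene_id = agg$gene_id, sl_id = agg$sl_id, source = "genetic_record",
    evidence_id = agg$record_id,
    detail = sprintf("%s record citing article(s) annotated %s", agg$kind,
                     agg$terms),
    stringsAsFactors = FALSE
  ))
}

#' One-sided over-representation tail probability
#'
#' The probability, under the hypergeometric null, of drawing `overlap` or
#' more flagged genes when a pathway of `pathway_size` genes is sampled
#' without replacement from a universe of `universe_size` genes of which
#' `flagged_set_size` are flagged: `P[X >= overlap]`. This is the one-sided
#' Fisher exact test for over-representation.
#'
#' @param overlap observed shared genes.
#' @param pathway_size genes in the pathway.
#' @param flagged_set_size genes in the flagged phenotype set.
#' @param universe_size genes in the background universe.
#' @return p-value(s) in `[0, 1]`; arguments recycle as in [stats::phyper()].
#' @export
fisher_right_tail <- function(overlap, pathway_size, flagged_set_size,
                              universe_size) {
  n <- max(length(overlap), length(pathway_size), length(flagged_set_size),
           length(universe_size))
  overlap <- rep_len(overlap, n); pathway_size <- rep_len(pathway_size, n)
  flagged_set_size <- rep_len(flagged_set_size, n)
  universe_size <- rep_len(universe_size, n)
  ok <- overlap >= 0 & pathway_size >= 0 & flagged_set_size >= 0 &
    universe_size >= 1 &
    pathway_size <= universe_size & flagged_set_size <= universe_size &
    overlap <= pmin(pathway_size, flagged_set_size)
  if (!all(ok)) {
    i <- which(!ok)[1L]
    stop(sprintf(paste0("inconsistent counts: overlap=%s, pathway_size=%s, ",
                        "flagged_set_size=%s, universe_size=%s"),
                 overlap[i], pathway_size[i], flagged_set_size[i],
                 universe_size[i]), call. = FALSE)
  }
  stats::phyper(overlap - 1, flagged_set_size, universe_size - flagged_set_size,
                pathway_size, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order,
#' monotone-enforced and clipped to `[0, 1]`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same length and order.
#' @export
bh_qvalues <- function(p) {
  if (!is.numeric(p)) stop("p-values must be numeric", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Red-flags from pathway over-representation
#'
#' For every pathway and every flagged phenotype gene-set (a phenotype
#' ontology term mapped to SL terms, with the genes annotated to it), the
#' one-sided Fisher exact tail is computed against the whole-store gene
#' universe, and Benjamini-Hochberg correction is applied once across the
#' full pathway-by-phenotype test family. A pathway passing
#' `q < q_threshold` with `overlap >= min_overlap` is red-flagged with the
#' phenotype's SL terms, and the flag fans out to every member gene of the
#' pathway (that is what makes pathway evidence countable per gene).
#'
#' @inheritParams flag_expression
#' @return list with `flags` (data.frame; evidence is the pathway id) and
#'   `enrichment` (audit data.frame of every test: pathway, phenotype term,
#'   overlap, sizes, p and q).
#' @export
flag_pathways <- function(store, index, config = tox_config()) {
  universe <- unique(store$genes$gene_id)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  enr0 <- data.frame(pathway_id = character(0), phenotype_term_id = character(0),
                     overlap = integer(0), pathway_size = integer(0),
                     flagged_set_size = integer(0), universe_size = integer(0),
                     p_value = numeric(0), q_value = numeric(0),
                     stringsAsFactors = FALSE)
  sets <- index$by_source[["phenotype_like"]] %||% list()
  mapped_terms <- names(sets)[lengths(sets) > 0L]
  gt <- store$gene_terms
  gt <- gt[gt$namespace == "phenotype_like" & gt$term_id %in% mapped_terms, ,
           drop = FALSE]
  pheno_sets <- lapply(split(gt$gene_id, gt$term_id), unique)
  pw_sets <- lapply(split(store$pathway_genes$gene_id,
                          store$pathway_genes$pathway_id), unique)
  if (!length(pheno_sets) || !length(pw_sets)) {
    return(list(flags = empty_flags(), enrichment = enr0))
  }
  pw_ids <- sort(names(pw_sets))
  ph_ids <- sort(names(pheno_sets))
  grid <- expand.grid(pathway_id = pw_ids, phenotype_term_id = ph_ids,
                      stringsAsFactors = FALSE)
  grid$overlap <- mapply(function(pw, ph)
    length(intersect(pw_sets[[pw]], pheno_sets[[ph]])),
    grid$pathway_id, grid$phenotype_term_id, USE.NAMES = FALSE)
  grid$pathway_size <- lengths(pw_sets)[grid$pathway_id]
  grid$flagged_set_size <- lengths(pheno_sets)[grid$phenotype_term_id]
  grid$universe_size <- length(universe)
  grid$p_value <- fisher_right_tail(grid$overlap, grid$pathway_size,
                                    grid$flagged_set_size, grid$universe_size)
  grid$q_value <- bh_qvalues(grid$p_value)
  rownames(grid) <- NULL
  sig <- grid[grid$q_value < config$q_threshold &
                grid$overlap >= config$min_overlap, , drop = FALSE]
  flags <- empty_flags()
  if (nrow(sig)) {
    pieces <- lapply(seq_len(nrow(sig)), function(i) {
      pw <- sig$pathway_id[i]; ph <- sig$phenotype_term_id[i]
      sls <- sets[[ph]]
      members <- sort(pw_sets[[pw]])
      data.frame(
        gene_id = rep(members, each = length(sls)),
        sl_id = rep(sls, times = length(members)),
        source = "pathway", evidence_id = pw,
        detail = sprintf("pathway %s enriched for %s (overlap=%d, q=%s)",
                         pw, ph, sig$overlap[i], fmt_num(sig$q_value[i])),
        stringsAsFactors = FALSE
      )
    })
    flags <- dedup_flags(do.call(rbind, pieces))
  }
  list(flags = flags, enrichment = grid)
}

#' Build the complete red-flag set
#'
#' Runs all five inference rules — direct annotation, tissue expression,
#' literature linkage, citation transitivity, and pathway
#' over-representation — and returns their deduplicated union. Deterministic
#' for a fixed store and configuration.
#'
#' @inheritParams flag_expression
#' @return list with `flags` (the union flag data.frame, sorted) and
#'   `enrichment` (the pathway test audit table).
#' @export
build_all_flags <- function(store, index, config = tox_config()) {
  pw <- flag_pathways(store, index, config)
  flags <- dedup_flags(rbind(
    flag_direct(store, index),
    flag_expression(store, index, config),
    flag_mesh(store, index, config),
    flag_via_citations(store, index),
    pw$flags
  ))
  list(flags = flags, enrichment = pw$enrichment)
}
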