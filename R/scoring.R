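#' Weighted red-flag counts per gene and SL term
#'
#' Each flag contributes its source's multiplier: by default genetic-record
#' flags count double (human genetics is emphasized) and expression flags
#' count one fifth (expression evidence is de-emphasized); direct
#' annotation, literature and pathway flags count once.
#'
#' @param flags flag data.frame from [build_all_flags()].
#' @param weights named positive multipliers, one per flag source present.
#' @return data.frame (`gene_id`, `sl_id`, `weighted_count`).
#' @export
weighted_counts <- function(flags, weights = tox_config()$weights) {
  unknown <- setdiff(unique(flags$source), names(weights))
  if (length(unknown)) {
    stop("no weight defined for flag source(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!nrow(flags)) {
    return(data.frame(gene_id = character(0), sl_id = character(0),
                      weighted_count = numeric(0), stringsAsFactors = FALSE))
  }
  w <- unname(weights[flags$source])
  key <- paste(flags$gene_id, flags$sl_id, sep = "\r")
  tot <- tapply(w, key, sum)
  parts <- strsplit(names(tot), "\r", fixed = TRUE)
  out <- data.frame(gene_id = vapply(parts, `[`, "", 1L),
                    sl_id = vapply(parts, `[`, "", 2L),
                    weighted_count = as.numeric(tot), stringsAsFactors = FALSE)
  out[order(out$gene_id, out$sl_id, method = "radix"), , drop = FALSE]
}

#' Safety Lexicon scores for one category within one species
#'
#' Normalizes the log10 weighted flag counts of all genes of a species for
#' one SL category onto `[0, 1]`:
#' `score = (GFC - MinFC) / (MaxFC - MinFC)`, where GFC is the gene's
#' log10 weighted count and MinFC/MaxFC are the log10 of the smallest and
#' largest *positive* weighted counts in the category (zero-count genes are
#' excluded from the anchors and score 0). When all positive counts are
#' equal the formula degenerates to 0/0; positive-count genes then score 1
#' (each holds the maximum). The optional percentile mode scores a
#' positive-count gene by the fraction of positive-count genes with a
#' count no larger than its own.
#'
#' @param counts numeric vector of weighted counts, one per gene of the
#'   species (zeros included); names are preserved.
#' @param mode `"minmax"` (default) or `"percentile"`.
#' @return numeric vector of scores in `[0, 1]`, same order and names.
#' @examples
#' sl_scores(c(A = 100, B = 10, C = 1, D = 0)) # 1.0 0.5 0.0 0.0
#' @export
sl_scores <- function(counts, mode = c("minmax", "percentile")) {
  mode <- match.arg(mode)
  if (any(counts < 0)) stop("weighted counts must be non-negative", call. = FALSE)
  score <- rep(0, length(counts))
  names(score) <- names(counts)
  pos <- counts > 0
  if (!any(pos)) return(score)
  if (mode == "minmax") {
    gfc <- log10(counts[pos])
    mn <- min(gfc); mx <- max(gfc)
    score[pos] <- if (mx > mn) pmin(pmax((gfc - mn) / (mx - mn), 0), 1) else 1
  } else {
    g <- counts[pos]
    score[pos] <- vapply(g, function(x) mean(g <= x), 0)
  }
  score
}

#' Score every gene of every species against every SL term
#'
#' Normalization is always within species: a mouse gene is scored against
#' all mouse genes. Genes without flags in a category score 0 (green).
#'
#' @param store validated `tox_store`.
#' @param flags flag data.frame.
#' @param config a [tox_config()]; supplies weights and score mode.
#' @return data.frame (`gene_id`, `species`, `sl_id`, `weighted_count`,
#'   `score`, `bin`), sorted by species, SL term, gene.
#' @export
score_all <- function(store, flags, config = tox_config()) {
  wc <- weighted_counts(flags, config$weights)
  sl_ids <- sort(store$sl_terms$sl_id)
  out <- list()
  for (sp in sort(unique(store$genes$species))) {
    g <- sort(store$genes$gene_id[store$genes$species == sp])
    for (sl in sl_ids) {
      counts <- stats::setNames(rep(0, length(g)), g)
      sub <- wc[wc$sl_id == sl & wc$gene_id %in% g, , drop = FALSE]
      counts[sub$gene_id] <- sub$weighted_count
      sc <- sl_scores(counts, mode = config$score_mode)
      out[[paste(sp, sl)]] <- data.frame(
        gene_id = g, species = sp, sl_id = sl,
        weighted_count = unname(counts), score = unname(sc),
        bin = color_bin(unname(sc)), stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Display bin of an SL score
#'
#' Scores of 0.9 and above bin red, 0.5 and above orange, any other positive
#' score yellow; exactly zero (no flagged annotation) bins green. The four
#' bins partition `[0, 1]`.
#'
#' @param score numeric vector in `[0, 1]`.
#' @return character vector: `"red"`, `"orange"`, `"yellow"` or `"green"`.
#' @export
color_bin <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  ifelse(score >= 0.9, "red",
         ifelse(score >= 0.5, "orange",
                ifelse(score > 0, "yellow", "green")))
}

#' Gene-by-category score matrix with homolog expansion
#'
#' Expands the requested genes to every member of their homology groups
#' (the human and mouse homologs), then assembles the score and bin
#' matrices over all SL terms. Row scores come from each gene's own
#' species-wide normalization. Unknown gene ids are collected in
#' `$skipped`, not fatal.
#'
#' @param result a `tox_result` from [tox_build()], or a list with `store`
#'   and `scores`.
#' @param gene_ids character vector of gene ids to look up.
#' @return object of class `tox_score_matrix`: `genes` (row metadata),
#'   `scores` and `bins` (gene x SL matrices), `skipped`.
#' @export
score_matrix <- function(result, gene_ids) {
  store <- result$store
  scores <- result$scores
  gene_ids <- unique(as.character(gene_ids))
  known <- gene_ids[gene_ids %in% store$genes$gene_id]
  skipped <- setdiff(gene_ids, known)
  hg <- store$genes$homology_group[match(known, store$genes$gene_id)]
  hg <- hg[nzchar(hg)]
  expanded <- unique(c(known,
                       store$genes$gene_id[store$genes$homology_group %in% hg]))
  genes <- store$genes[store$genes$gene_id %in% expanded,
                       c("gene_id", "symbol", "species", "homology_group")]
  genes <- genes[order(genes$species, genes$gene_id, method = "radix"), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  sl_ids <- sort(store$sl_terms$sl_id)
  score_m <- matrix(0, nrow = nrow(genes), ncol = length(sl_ids),
                    dimnames = list(genes$gene_id, sl_ids))
  bin_m <- matrix("green", nrow = nrow(genes), ncol = length(sl_ids),
                  dimnames = list(genes$gene_id, sl_ids))
  sub <- scores[scores$gene_id %in% genes$gene_id, , drop = FALSE]
  if (nrow(sub)) {
    i <- match(sub$gene_id, genes$gene_id)
    j <- match(sub$sl_id, sl_ids)
    score_m[cbind(i, j)] <- sub$score
    bin_m[cbind(i, j)] <- sub$bin
  }
  structure(list(genes = genes, scores = score_m, bins = bin_m,
                 skipped = skipped),
            class = "tox_score_matrix")
}

#' @export
print.tox_score_matrix <- function(x, ...) {
  cat(sprintf("SL score matrix: %d gene(s) x %d categories\n",
              nrow(x$genes), ncol(x$scores)))
  if (nrow(x$genes)) {
    df <- cbind(x$genes[c("gene_id", "symbol", "species")],
                as.data.frame(round(x$scores, 3)))
    print(df, row.names = FALSE)
  }
  if (length(x$skipped)) {
    cat("skipped unknown ids:", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
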