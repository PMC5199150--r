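#' Run the full triage pipeline on an annotation bundle
#'
#' Validates the bundle, propagates the classification-to-lexicon mappings,
#' infers the red-flag set through all five rules, and scores every gene of
#' every species against every SL category. The result object carries all
#' intermediate products for reporting and audit.
#'
#' @param bundle a bundle directory path, raw tables from [read_bundle()],
#'   or an already validated `tox_store`.
#' @param config a [tox_config()].
#' @return object of class `tox_result` with elements `store`, `index`,
#'   `config`, `flags`, `enrichment`, `scores`.
#' @examples
#' dir <- tempfile()
#' generate_bundle(fixture_spec(seed = 1, n_genes = c(human = 50, mouse = 50),
#'                              n_articles = 80, n_pathways = 6,
#'                              n_genetic_records = 10), dir)
#' res <- tox_build(dir)
#' res
#' @export
tox_build <- function(bundle, config = tox_config()) {
  store <- if (inherits(bundle, "tox_store")) bundle else validate_store(bundle)
  index <- build_mapping_index(store)
  fl <- build_all_flags(store, index, config)
  scores <- score_all(store, fl$flags, config)
  structure(list(store = store, index = index, config = config,
                 flags = fl$flags, enrichment = fl$enrichment,
                 scores = scores),
            class = "tox_result")
}

#' Write pipeline outputs as TSV files
#'
#' Writes `flags.tsv`, `enrichment.tsv`, `scores.tsv` and `matrix.tsv`
#' (genes x SL terms, wide) into `out_dir`. Rows and columns follow a fixed
#' sorted order and numbers a fixed format, so identical inputs give
#' byte-identical files.
#'
#' @param result a `tox_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "tox_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(result$flags, file.path(out_dir, "flags.tsv"))

  enr <- result$enrichment
  enr <- enr[order(enr$pathway_id, enr$phenotype_term_id, method = "radix"), ,
             drop = FALSE]
  enr$p_value <- fmt_num(enr$p_value)
  enr$q_value <- fmt_num(enr$q_value)
  write_tsv(enr, file.path(out_dir, "enrichment.tsv"))

  sc <- result$scores
  sc <- sc[order(sc$species, sc$sl_id, sc$gene_id, method = "radix"), ,
           drop = FALSE]
  sc$weighted_count <- fmt_num(sc$weighted_count)
  sc$score <- fmt_num(sc$score)
  write_tsv(sc, file.path(out_dir, "scores.tsv"))

  wide <- score_matrix(result, result$store$genes$gene_id)
  mat <- as.data.frame(wide$scores)
  for (j in seq_along(mat)) mat[[j]] <- fmt_num(mat[[j]])
  mat <- cbind(wide$genes[c("gene_id", "symbol", "species")], mat)
  write_tsv(mat, file.path(out_dir, "matrix.tsv"))
  invisible(out_dir)
}

#' @export
print.tox_result <- function(x, ...) {
  cat("Safety-lexicon triage result\n")
  print(x$store)
  src <- table(factor(x$flags$source, levels = FLAG_SOURCES))
  cat(sprintf("  red-flags: %d (%s)\n", nrow(x$flags),
              paste(sprintf("%s %d", names(src), src), collapse = ", ")))
  cat(sprintf("  genes with >=1 flag: %d / %d\n",
              length(unique(x$flags$gene_id)), nrow(x$store$genes)))
  invisible(x)
}

#' @export
summary.tox_result <- function(object, ...) {
  x <- object
  pos <- x$scores[x$scores$score > 0, , drop = FALSE]
  bins <- table(factor(x$scores$bin, levels = c("red", "orange", "yellow",
                                                "green")))
  sig <- x$enrichment[x$enrichment$q_value < x$config$q_threshold &
                        x$enrichment$overlap >= x$config$min_overlap, ,
                      drop = FALSE]
  structure(list(
    n_genes = nrow(x$store$genes),
    n_flags = nrow(x$flags),
    flags_by_source = table(factor(x$flags$source, levels = FLAG_SOURCES)),
    n_flagged_genes = length(unique(x$flags$gene_id)),
    n_pathways_flagged = length(unique(sig$pathway_id)),
    bins = bins,
    median_positive_score = if (nrow(pos)) stats::median(pos$score) else NA_real_
  ), class = "summary.tox_result")
}

#' @export
print.summary.tox_result <- function(x, ...) {
  cat("Triage summary\n")
  cat(sprintf("  genes: %d, red-flags: %d (flagged genes: %d)\n",
              x$n_genes, x$n_flags, x$n_flagged_genes))
  cat("  flags by source:\n")
  for (s in names(x$flags_by_source)) {
    cat(sprintf("    %-18s %d\n", s, x$flags_by_source[[s]]))
  }
  cat(sprintf("  pathways red-flagged: %d\n", x$n_pathways_flagged))
  cat("  score bins:",
      paste(sprintf("%s %d", names(x$bins), x$bins), collapse = ", "), "\n")
  if (!is.na(x$median_positive_score)) {
    cat(sprintf("  median positive score: %.3f\n", x$median_positive_score))
  }
  invisible(x)
}
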