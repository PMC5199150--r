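#' Enumerate every evidence item linked to a gene
#'
#' An evidence item is one unit the gene view can show: a direct ontology
#' annotation, a literature term passing the article-count gate, a genetic
#' record, a pathway membership, or a tissue with positive expression.
#' For any selected category each item is either flagged (a red-flag with
#' that source and evidence exists for the category) or unflagged — never
#' both, and flagged items are always drawn from this set.
#'
#' @param result a `tox_result`.
#' @param gene_id gene to enumerate.
#' @return data.frame (`source`, `evidence_id`), sorted.
#' @export
gene_evidence <- function(result, gene_id) {
  store <- result$store
  if (!(gene_id %in% store$genes$gene_id)) {
    stop("unknown gene: ", gene_id, call. = FALSE)
  }
  gt <- store$gene_terms
  gt <- gt[gt$gene_id == gene_id & gt$namespace != "mesh_like", , drop = FALSE]
  cnt <- mesh_article_counts(store)
  cnt <- cnt[cnt$gene_id == gene_id &
               cnt$n_articles >= result$config$min_mesh_articles, , drop = FALSE]
  rec <- store$genetic_records[store$genetic_records$gene_id == gene_id, ,
                               drop = FALSE]
  pw <- store$pathway_genes[store$pathway_genes$gene_id == gene_id, ,
                            drop = FALSE]
  ex <- store$expression[store$expression$gene_id == gene_id &
                           store$expression$value > 0, , drop = FALSE]
  out <- rbind(
    data.frame(source = rep("direct_annotation", nrow(gt)),
               evidence_id = gt$term_id, stringsAsFactors = FALSE),
    data.frame(source = rep("mesh_literature", nrow(cnt)),
               evidence_id = cnt$term_id, stringsAsFactors = FALSE),
    data.frame(source = rep("genetic_record", nrow(rec)),
               evidence_id = rec$record_id, stringsAsFactors = FALSE),
    data.frame(source = rep("pathway", nrow(pw)),
               evidence_id = pw$pathway_id, stringsAsFactors = FALSE),
    data.frame(source = rep("expression", nrow(ex)),
               evidence_id = ex$tissue, stringsAsFactors = FALSE)
  )
  out <- unique(out)
  out <- out[order(out$source, out$evidence_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Top-level SL categories: the children of the lexicon root when the tree
# has a single root, otherwise the roots themselves.
top_level_sl <- function(sl_terms) {
  roots <- sl_terms$sl_id[!nzchar(sl_terms$parent_id)]
  if (length(roots) == 1L) {
    kids <- sl_terms$sl_id[sl_terms$parent_id == roots]
    if (length(kids)) return(sort(kids))
  }
  sort(roots)
}

#' Category-filtered gene report
#'
#' The single-gene view: a header, the Tox-At-A-Glance score row over every
#' top-level SL category, and the gene's evidence partitioned for the
#' selected category — items red-flagged for it (with their tooltip detail)
#' versus everything else, which is only counted. An item flagged for
#' several categories (e.g. a genetic record citing articles in two areas)
#' appears flagged in each of those category views.
#'
#' @param result a `tox_result`.
#' @param gene_id gene to report.
#' @param sl_id selected SL category.
#' @return object of class `tox_gene_report`.
#' @export
gene_report <- function(result, gene_id, sl_id) {
  store <- result$store
  if (!(gene_id %in% store$genes$gene_id)) {
    stop("unknown gene: ", gene_id, call. = FALSE)
  }
  if (!(sl_id %in% store$sl_terms$sl_id)) {
    stop("unknown SL term: ", sl_id, call. = FALSE)
  }
  g <- store$genes[store$genes$gene_id == gene_id, ]
  glance_ids <- top_level_sl(store$sl_terms)
  sc <- result$scores[result$scores$gene_id == gene_id, , drop = FALSE]
  glance <- data.frame(sl_id = glance_ids,
                       score = sc$score[match(glance_ids, sc$sl_id)],
                       stringsAsFactors = FALSE)
  glance$score[is.na(glance$score)] <- 0
  glance$bin <- color_bin(glance$score)

  evidence <- gene_evidence(result, gene_id)
  fl <- result$flags[result$flags$gene_id == gene_id &
                       result$flags$sl_id == sl_id, , drop = FALSE]
  flagged <- merge(evidence, fl[c("source", "evidence_id", "detail")],
                   by = c("source", "evidence_id"))
  flagged <- flagged[order(flagged$source, flagged$evidence_id,
                           method = "radix"), , drop = FALSE]
  rownames(flagged) <- NULL
  structure(list(
    gene = list(gene_id = g$gene_id, symbol = g$symbol,
                aliases = g$aliases[[1L]], species = g$species),
    selected_sl = sl_id,
    at_a_glance = glance,
    flagged = flagged,
    unflagged_count = nrow(evidence) - nrow(flagged),
    total_evidence = nrow(evidence)
  ), class = "tox_gene_report")
}

#' @export
print.tox_gene_report <- function(x, ...) {
  cat(sprintf("Gene view: %s (%s, %s) - category %s\n", x$gene$symbol,
              x$gene$gene_id, x$gene$species, x$selected_sl))
  cat("  Tox-At-A-Glance:\n")
  for (i in seq_len(nrow(x$at_a_glance))) {
    cat(sprintf("    %-28s %5.3f [%s]\n", x$at_a_glance$sl_id[i],
                x$at_a_glance$score[i], x$at_a_glance$bin[i]))
  }
  cat(sprintf("  flagged evidence: %d; unflagged: %d\n", nrow(x$flagged),
              x$unflagged_count))
  if (nrow(x$flagged)) {
    for (s in unique(x$flagged$source)) {
      sub <- x$flagged[x$flagged$source == s, ]
      cat(sprintf("    %s:\n", s))
      for (i in seq_len(nrow(sub))) {
        cat(sprintf("      %s - %s\n", sub$evidence_id[i], sub$detail[i]))
      }
    }
  }
  invisible(x)
}

#' Search genes by identifier, symbol or alias
#'
#' Case-insensitive exact match against gene id, symbol and every alias;
#' with `prefix = TRUE` a case-insensitive prefix match instead. Results
#' are ordered by species then symbol, so homologs sharing a symbol or
#' alias come out in a deterministic order.
#'
#' @param store a `tox_store` (or a `tox_result`, whose store is used).
#' @param query search string.
#' @param prefix match by prefix instead of exact equality.
#' @return data.frame of matching gene rows (possibly empty).
#' @export
search_genes <- function(store, query, prefix = FALSE) {
  if (inherits(store, "tox_result")) store <- store$store
  stopifnot(inherits(store, "tox_store"))
  q <- tolower(query)
  hits <- function(x) if (prefix) startsWith(tolower(x), q) else tolower(x) == q
  sel <- hits(store$genes$gene_id) | hits(store$genes$symbol) |
    vapply(store$genes$aliases, function(a) any(hits(a)), TRUE)
  out <- store$genes[sel, , drop = FALSE]
  out <- out[order(out$species, out$symbol, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Render a gene report
#'
#' @param report a `tox_gene_report`.
#' @param format `"tsv"`, `"json"` or `"html"`. TSV is a flat evidence
#'   listing preceded by the at-a-glance block; JSON has stable key order;
#'   HTML is a static document with one bar element per top-level category
#'   and the tooltip detail embedded as text.
#' @param path optional file to write (UTF-8); the rendered text is always
#'   returned.
#' @return character scalar, invisibly when `path` is given.
#' @export
render_report <- function(report, format = c("tsv", "json", "html"),
                          path = NULL) {
  stopifnot(inherits(report, "tox_gene_report"))
  format <- match.arg(format)
  txt <- switch(format,
    tsv = {
      lines <- c(
        sprintf("# gene\t%s\t%s\t%s", report$gene$gene_id, report$gene$symbol,
                report$gene$species),
        sprintf("# selected_sl\t%s", report$selected_sl),
        "section\tsl_id\tscore\tbin",
        sprintf("at_a_glance\t%s\t%s\t%s", report$at_a_glance$sl_id,
                fmt_num(report$at_a_glance$score), report$at_a_glance$bin),
        "section\tsource\tevidence_id\tdetail",
        if (nrow(report$flagged))
          sprintf("flagged\t%s\t%s\t%s", report$flagged$source,
                  report$flagged$evidence_id, report$flagged$detail),
        sprintf("unflagged_count\t%d\t\t", report$unflagged_count)
      )
      paste0(paste(lines, collapse = "\n"), "\n")
    },
    json = jsonlite::toJSON(list(
      gene = report$gene,
      selected_sl = report$selected_sl,
      at_a_glance = report$at_a_glance,
      flagged = report$flagged,
      unflagged_count = report$unflagged_count,
      total_evidence = report$total_evidence
    ), auto_unbox = TRUE, digits = NA, pretty = TRUE),
    html = {
      bars <- sprintf(
        '    <div class="bar bin-%s" data-sl="%s" data-score="%s">%s: %s</div>',
        report$at_a_glance$bin, html_escape(report$at_a_glance$sl_id),
        fmt_num(report$at_a_glance$score), html_escape(report$at_a_glance$sl_id),
        fmt_num(report$at_a_glance$score))
      rows <- if (nrow(report$flagged)) sprintf(
        '    <tr><td>%s</td><td>%s</td><td title="%s">%s</td></tr>',
        html_escape(report$flagged$source),
        html_escape(report$flagged$evidence_id),
        html_escape(report$flagged$detail), html_escape(report$flagged$detail))
      paste0(paste(c(
        "<!DOCTYPE html>",
        "<html><head><meta charset=\"utf-8\">",
        sprintf("<title>%s - %s</title>", html_escape(report$gene$symbol),
                html_escape(report$selected_sl)),
        "<style>.bin-red{background:#e33}.bin-orange{background:#f93}",
        ".bin-yellow{background:#ff6}.bin-green{background:#6c6}</style>",
        "</head><body>",
        sprintf("<h1>%s (%s, %s)</h1>", html_escape(report$gene$symbol),
                html_escape(report$gene$gene_id),
                html_escape(report$gene$species)),
        "  <div class=\"at-a-glance\">", bars, "  </div>",
        sprintf("<h2>Red-flagged evidence for %s</h2>",
                html_escape(report$selected_sl)),
        "  <table>", rows, "  </table>",
        sprintf("<p>%d unflagged item(s) hidden.</p>", report$unflagged_count),
        "</body></html>"), collapse = "\n"), "\n")
    })
  txt <- as.character(txt)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Render a score matrix
#'
#' @param matrix a `tox_score_matrix` from [score_matrix()].
#' @param format `"tsv"`, `"json"` or `"html"`. The TSV is wide
#'   (genes x SL terms) and round-trips through [utils::read.delim()];
#'   the HTML table colors each cell by its display bin.
#' @param path optional output file.
#' @return character scalar, invisibly when `path` is given.
#' @export
render_matrix <- function(matrix, format = c("tsv", "json", "html"),
                          path = NULL) {
  stopifnot(inherits(matrix, "tox_score_matrix"))
  format <- match.arg(format)
  sl_ids <- colnames(matrix$scores)
  txt <- switch(format,
    tsv = {
      header <- paste(c("gene_id", "symbol", "species", sl_ids),
                      collapse = "\t")
      body <- vapply(seq_len(nrow(matrix$genes)), function(i)
        paste(c(matrix$genes$gene_id[i], matrix$genes$symbol[i],
                matrix$genes$species[i], fmt_num(matrix$scores[i, ])),
              collapse = "\t"), "")
      paste0(paste(c(header, body), collapse = "\n"), "\n")
    },
    json = jsonlite::toJSON(list(
      genes = matrix$genes,
      sl_terms = sl_ids,
      scores = matrix$scores,
      bins = matrix$bins,
      skipped = matrix$skipped
    ), auto_unbox = TRUE, digits = NA, pretty = TRUE),
    html = {
      head_row <- paste0("    <tr><th>gene</th><th>species</th>",
                         paste(sprintf("<th>%s</th>", html_escape(sl_ids)),
                               collapse = ""), "</tr>")
      rows <- vapply(seq_len(nrow(matrix$genes)), function(i) {
        cells <- paste(sprintf('<td class="bin-%s">%s</td>',
                               matrix$bins[i, ], fmt_num(matrix$scores[i, ])),
                       collapse = "")
        sprintf("    <tr><td>%s</td><td>%s</td>%s</tr>",
                html_escape(matrix$genes$symbol[i]),
                html_escape(matrix$genes$species[i]), cells)
      }, "")
      paste0(paste(c(
        "<!DOCTYPE html>",
        "<html><head><meta charset=\"utf-8\"><title>SL score matrix</title>",
        "<style>.bin-red{background:#e33}.bin-orange{background:#f93}",
        ".bin-yellow{background:#ff6}.bin-green{background:#6c6}</style>",
        "</head><body>",
        "  <table>", head_row, rows, "  </table>",
        "</body></html>"), collapse = "\n"), "\n")
    })
  txt <- as.character(txt)
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(txt, con, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Bar chart of a gene's Tox-At-A-Glance scores
#'
#' @param x a `tox_gene_report`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.tox_gene_report <- function(x, ...) {
  cols <- c(red = "#e03030", orange = "#f09030", yellow = "#f0e060",
            green = "#60c060")
  graphics::barplot(stats::setNames(x$at_a_glance$score, x$at_a_glance$sl_id),
                    col = cols[x$at_a_glance$bin], ylim = c(0, 1), las = 2,
                    ylab = "SL score",
                    main = sprintf("%s (%s)", x$gene$symbol, x$gene$species),
                    ...)
  invisible(x)
}
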