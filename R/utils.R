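# Internal helpers: pipe-delimited multi-value fields, byte-stable TSV io,
# deterministic number formatting.

split_pipe <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, "|", fixed = TRUE), function(v) v[nzchar(v)])
}

join_pipe <- function(v) paste(v, collapse = "|")

# All bundle tables are read as character; numeric columns are converted
# explicitly by the caller so that parse failures are reported per table.
read_tsv <- function(path, cols) {
  if (!file.exists(path)) {
    stop("missing bundle file: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          colClasses = "character", na.strings = NULL,
                          check.names = FALSE, fileEncoding = "UTF-8",
                          stringsAsFactors = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df[cols]
}

# Byte-reproducible writer: fixed column order, no quoting, LF line endings.
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  body <- if (nrow(df)) do.call(paste, c(lapply(df, as.character), sep = "\t"))
  writeLines(c(paste(names(df), collapse = "\t"), body), con,
             sep = "\n", useBytes = TRUE)
  invisible(path)
}

fmt_num <- function(x) {
  out <- formatC(x, format = "g", digits = 10)
  gsub(" ", "", out, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reports a cycle in a directed graph given as an adjacency list
# (node -> vector of successor nodes); NULL when the graph is acyclic.
# Edges pointing outside names(adj) are checked separately by validation.
find_cycle <- function(adj) {
  nodes <- names(adj)
  color <- stats::setNames(integer(length(adj)), nodes)
  path <- character(0)
  cyc <- NULL
  visit <- function(v) {
    if (!is.null(cyc)) return(invisible(NULL))
    color[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]]) {
      if (!is.null(cyc)) break
      if (!(w %in% nodes)) next
      if (color[[w]] == 1L) {
        i <- match(w, path)
        cyc <<- path[i:length(path)]
        break
      }
      if (color[[w]] == 0L) visit(w)
    }
    if (is.null(cyc)) {
      color[[v]] <<- 2L
      path <<- path[-length(path)]
    }
    invisible(NULL)
  }
  for (v in nodes) {
    if (color[[v]] == 0L) visit(v)
    if (!is.null(cyc)) break
  }
  cyc
}
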