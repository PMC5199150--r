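#' Propagate declared mappings down one annotation ontology
#'
#' Classification-to-lexicon mappings are declared manually on (usually
#' high-level) ontology terms; every descendant term inherits the mapping.
#' On a multi-parent term the inherited set is the union over all parents,
#' and a term always carries its own declared mappings (a term is its own
#' ancestor for mapping purposes). Propagation is eager: terms are processed
#' in topological order so each term's set is the union of its declared SL
#' terms and its parents' already-complete sets.
#'
#' @param parents named list: `term_id -> character vector of parent term
#'   ids`, covering every term of the namespace (validated DAG).
#' @param declared data.frame with columns `source_id`, `sl_id`: the
#'   manually declared mappings for this namespace.
#' @return named list `term_id -> sorted character vector of sl_id` (empty
#'   vector for unmapped terms), one entry per ontology term.
#' @keywords internal
propagate_ns <- function(parents, declared) {
  terms <- names(parents)
  if (nrow(declared)) {
    unknown <- setdiff(declared$source_id, terms)
    if (length(unknown)) {
      stop("declared mapping references term(s) absent from the ontology: ",
           paste(sort(unknown), collapse = ", "), call. = FALSE)
    }
  }
  own <- lapply(stats::setNames(terms, terms), function(t)
    sort(unique(declared$sl_id[declared$source_id == t])))
  children <- stats::setNames(vector("list", length(terms)), terms)
  n_par <- stats::setNames(integer(length(terms)), terms)
  for (t in terms) {
    ps <- parents[[t]]
    n_par[[t]] <- length(ps)
    for (p in ps) children[[p]] <- c(children[[p]], t)
  }
  out <- own
  queue <- sort(terms[n_par == 0L])
  while (length(queue)) {
    t <- queue[[1L]]
    queue <- queue[-1L]
    inherited <- unlist(out[parents[[t]]], use.names = FALSE)
    out[[t]] <- sort(unique(c(own[[t]], inherited)))
    for (ch in children[[t]]) {
      n_par[[ch]] <- n_par[[ch]] - 1L
      if (n_par[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  out
}

#' Build the propagated mapping index for a store
#'
#' Expands the store's declared classification mappings down every annotation
#' ontology (see [propagate_ns()]) and collects the flat tissue mappings.
#' Tissues carry no hierarchy and are never propagated.
#'
#' @param store a validated `tox_store`.
#' @return an object of class `tox_mapping_index` with elements:
#'   \describe{
#'     \item{by_source}{per-namespace named list `term_id -> sl_id set`
#'       after propagation (empty set for known unmapped terms).}
#'     \item{by_tissue}{named list `tissue -> sl_id set` (declared only).}
#'     \item{entries}{data.frame of all (namespace, term, sl) pairs with an
#'       `inferred` flag: `FALSE` for declared rows, `TRUE` for rows created
#'       by propagation.}
#'   }
#' @examples
#' \donttest{
#' dir <- tempfile(); generate_bundle(fixture_spec(seed = 1), dir)
#' idx <- build_mapping_index(validate_store(read_bundle(dir)))
#' }
#' @export
build_mapping_index <- function(store) {
  stopifnot(inherits(store, "tox_store"))
  mp <- store$mappings
  by_source <- list()
  entries <- list()
  for (ns in names(store$ontologies)) {
    declared <- mp[mp$source_kind == "ontology_term" & mp$namespace == ns,
                   c("source_id", "sl_id")]
    sets <- propagate_ns(store$ontologies[[ns]]$parents, declared)
    by_source[[ns]] <- sets
    mapped <- sets[lengths(sets) > 0L]
    if (length(mapped)) {
      long <- data.frame(
        namespace = ns,
        term_id = rep(names(mapped), lengths(mapped)),
        sl_id = unlist(mapped, use.names = FALSE),
        stringsAsFactors = FALSE
      )
      decl_key <- paste(declared$source_id, declared$sl_id)
      long$inferred <- !(paste(long$term_id, long$sl_id) %in% decl_key)
      entries[[ns]] <- long
    }
  }
  tis <- mp[mp$source_kind == "tissue", c("source_id", "sl_id")]
  by_tissue <- lapply(split(tis$sl_id, tis$source_id), function(s) sort(unique(s)))
  entries <- if (length(entries)) do.call(rbind, entries) else
    data.frame(namespace = character(0), term_id = character(0),
               sl_id = character(0), inferred = logical(0))
  rownames(entries) <- NULL
  structure(list(by_source = by_source, by_tissue = by_tissue, entries = entries),
            class = "tox_mapping_index")
}

#' Look up the SL terms a classification term maps to
#'
#' Distinguishes "known but unmapped" (empty set) from "unknown term"
#' (an error), so callers never silently query a typo.
#'
#' @param index a `tox_mapping_index` from [build_mapping_index()].
#' @param namespace ontology namespace name.
#' @param term_id term to look up.
#' @return sorted character vector of sl_id (possibly empty).
#' @export
sl_terms_for <- function(index, namespace, term_id) {
  stopifnot(inherits(index, "tox_mapping_index"))
  if (!(namespace %in% names(index$by_source))) {
    stop("unknown namespace: ", namespace, call. = FALSE)
  }
  sets <- index$by_source[[namespace]]
  if (!(term_id %in% names(sets))) {
    stop("unknown term '", term_id, "' in namespace '", namespace, "'",
         call. = FALSE)
  }
  sets[[term_id]]
}

#' @export
print.tox_mapping_index <- function(x, ...) {
  cat("Propagated mapping index\n")
  for (ns in names(x$by_source)) {
    sets <- x$by_source[[ns]]
    cat(sprintf("  %s: %d/%d terms mapped\n", ns, sum(lengths(sets) > 0L),
                length(sets)))
  }
  cat(sprintf("  tissues mapped: %d\n", length(x$by_tissue)))
  invisible(x)
}
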