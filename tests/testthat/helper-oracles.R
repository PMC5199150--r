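# Independent oracles, deliberately written from first principles and kept
# free of any package internals.

# Hypergeometric right tail P[X >= k] by explicit binomial-coefficient sums.
hyper_tail_oracle <- function(k, pathway_size, flagged_set_size, universe) {
  jmax <- min(pathway_size, flagged_set_size)
  if (k > jmax) return(0)
  num <- sum(vapply(k:jmax, function(j)
    choose(flagged_set_size, j) *
      choose(universe - flagged_set_size, pathway_size - j), 0))
  num / choose(universe, pathway_size)
}

# Textbook Benjamini-Hochberg step-up: sort, scale by m/rank, enforce
# monotonicity from the largest p down, restore input order, clip at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# All ancestors of a term (self included) by naive repeated parent walks.
ancestors_walk <- function(parents, term) {
  anc <- term
  frontier <- term
  while (length(frontier)) {
    up <- unique(unlist(parents[frontier], use.names = FALSE))
    up <- setdiff(up, anc)
    anc <- c(anc, up)
    frontier <- up
  }
  anc
}

# Brute-force propagation: per term, union the declared SL terms of every
# ancestor (self included).
propagate_oracle <- function(parents, declared) {
  lapply(stats::setNames(names(parents), names(parents)), function(t) {
    anc <- ancestors_walk(parents, t)
    sort(unique(declared$sl_id[declared$source_id %in% anc]))
  })
}

# Random DAG as a parent list: term i may only point at earlier terms, so
# acyclicity holds by construction.
random_dag <- function(n_terms, max_parents = 3L) {
  ids <- sprintf("T%02d", seq_len(n_terms))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[1L]] <- character(0)
  for (i in seq_len(n_terms)[-1L]) {
    k <- sample(0:min(max_parents, i - 1L), 1L)
    parents[[i]] <- if (k) sort(sample(ids[seq_len(i - 1L)], k)) else character(0)
  }
  parents
}
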