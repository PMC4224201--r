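# Independent oracles: brute-force recursions kept deliberately free
# of the package's topological-order machinery.

# Longest root-to-term path by plain recursion over parents (no
# memoisation, no topological sort).
oracle_depth <- function(dag, t) {
  ps <- dag$parents[[t]]
  if (length(ps) == 0L) return(0L)
  1L + max(vapply(ps, function(p) oracle_depth(dag, p), integer(1)))
}

# Full enumeration of per-gene term combinations via expand.grid, with
# the same tie rules as the search (lower mean weight, then deeper,
# then lexicographically smallest tuple in sorted-gene order).
oracle_exhaustive <- function(network, store, dag) {
  sg <- scorable_subgraph(network, store)
  e <- sg$network$edges
  genes <- sort(unique(c(e$from, e$to)))
  cand <- lapply(genes, function(g) candidates(store, g))
  names(cand) <- genes
  grid <- expand.grid(cand, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)

  objs <- vapply(seq_len(nrow(grid)), function(r) {
    sel <- as.character(unlist(grid[r, ]))
    names(sel) <- genes
    mean(vapply(seq_len(nrow(e)), function(i) {
      term_dissimilarity(dag, sel[[e$from[i]]], sel[[e$to[i]]])
    }, numeric(1)))
  }, numeric(1))
  depths <- vapply(seq_len(nrow(grid)), function(r) {
    sum(dag$depth[as.character(unlist(grid[r, ]))])
  }, numeric(1))

  idx <- which(objs <= min(objs) + 1e-12)
  idx <- idx[depths[idx] == max(depths[idx])]
  if (length(idx) > 1L) {
    ord <- do.call(order, unname(as.list(grid[idx, , drop = FALSE])))
    idx <- idx[ord]
  }
  sel <- as.character(unlist(grid[idx[1L], ]))
  names(sel) <- genes
  list(objective = objs[idx[1L]], selection = sel)
}
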