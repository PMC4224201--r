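# Core of the method: find the per-gene GO-term assignment that makes
# the network most cohesive, weight every edge by the dissimilarity of
# the selected terms, and score the network by the average edge weight.

# Numerical slack for comparing edge-weight sums.  Weights are ratios
# of small integer depths, so distinct sums differ by far more than
# this; it only absorbs floating-point accumulation order.
SUM_EPS <- 1e-9

#' Restrict a network to its scorable part
#'
#' Genes without any candidate annotation cannot take part in the term
#' selection, so the subgraph induced by annotated genes is scored and
#' edges with at least one unannotated endpoint are excluded.  Excluded
#' genes are reported rather than silently dropped.
#'
#' @param network A `gene_network`.
#' @param store An `annotation_store`.
#' @return List with `network` (the induced subgraph) and
#'   `unannotated` (character vector of excluded genes).
#' @export
scorable_subgraph <- function(network, store) {
  annotated <- network$nodes[vapply(network$nodes,
                                    function(g) length(candidates(store, g)) > 0L,
                                    logical(1))]
  unannotated <- setdiff(network$nodes, annotated)
  e <- network$edges
  keep <- e$from %in% annotated & e$to %in% annotated
  sub <- gene_network(e$from[keep], e$to[keep], nodes = annotated)
  if (nrow(sub$edges) == 0L) {
    gfd_error("gfdnet_no_scorable_edges",
              "no scorable edges: every edge has an unannotated endpoint")
  }
  list(network = sub, unannotated = unannotated)
}

# Precompute everything the searches share: sorted scorable genes
# (endpoints of scorable edges), their sorted candidate sets, a
# memoised pairwise dissimilarity, and one candidate-by-candidate
# weight matrix per edge.  The memo cache fulfils the contract that a
# term pair is never measured twice within a run.
prepare_search <- function(network, store, dag, measure = term_dissimilarity) {
  sg <- scorable_subgraph(network, store)
  edges <- sg$network$edges
  genes <- sort(unique(c(edges$from, edges$to)))
  cands <- lapply(genes, function(g) candidates(store, g))
  names(cands) <- genes
  gi <- seq_along(genes)
  names(gi) <- genes

  cache <- new.env(parent = emptyenv())
  pair_dissim <- function(t1, t2) {
    key <- if (t1 <= t2) paste0(t1, "\r", t2) else paste0(t2, "\r", t1)
    v <- cache[[key]]
    if (is.null(v)) {
      v <- measure(dag, t1, t2)
      cache[[key]] <- v
    }
    v
  }

  nE <- nrow(edges)
  eu <- unname(gi[edges$from])
  ev <- unname(gi[edges$to])
  W <- vector("list", nE)
  for (e in seq_len(nE)) {
    cu <- cands[[eu[e]]]
    cv <- cands[[ev[e]]]
    m <- matrix(0, nrow = length(cu), ncol = length(cv))
    for (i in seq_along(cu)) {
      for (j in seq_along(cv)) m[i, j] <- pair_dissim(cu[i], cv[j])
    }
    W[[e]] <- m
  }

  # inc[[j]]: edges whose later endpoint (in sorted-gene order) is j,
  # so a DFS assigning genes 1..n closes each edge exactly once.
  # inc_all[[j]]: all edges touching j (for the greedy local step).
  inc <- rep(list(list()), length(genes))
  inc_all <- rep(list(list()), length(genes))
  for (e in seq_len(nE)) {
    a <- eu[e]; b <- ev[e]
    j <- max(a, b)
    rec <- list(e = e, other = min(a, b), j_is_col = (j == ev[e]))
    inc[[j]] <- c(inc[[j]], list(rec))
    inc_all[[a]] <- c(inc_all[[a]], list(list(e = e, other = b, j_is_col = FALSE)))
    inc_all[[b]] <- c(inc_all[[b]], list(list(e = e, other = a, j_is_col = TRUE)))
  }

  list(genes = genes, cands = cands,
       depths = lapply(cands, function(cc) unname(dag$depth[cc])),
       W = W, inc = inc, inc_all = inc_all,
       edges = edges, eu = eu, ev = ev,
       size = prod(vapply(cands, length, integer(1))),
       subgraph = sg$network, unannotated = sg$unannotated,
       pair_dissim = pair_dissim)
}

# Depth-first enumeration over candidate tuples in lexicographic order
# (genes sorted, candidates sorted).  A combination wins if its
# edge-weight sum is lower; ties go to the larger total depth of the
# selected terms (more specific), then to the first tuple encountered,
# which is the lexicographically smallest.  With `prune = TRUE`,
# branches whose partial sum already exceeds the best complete sum are
# cut; weights are non-negative, so no completion of a pruned branch
# can beat the incumbent.
run_search_dfs <- function(ps, prune) {
  n <- length(ps$genes)
  sel <- integer(n)
  best_sum <- Inf
  best_depth <- -Inf
  best_sel <- NULL
  visited <- 0
  cands <- ps$cands
  depths <- ps$depths
  W <- ps$W
  inc <- ps$inc

  rec <- function(j, psum, pdepth) {
    if (prune && psum > best_sum + SUM_EPS) return(invisible(NULL))
    if (j > n) {
      visited <<- visited + 1
      if (psum < best_sum - SUM_EPS ||
          (abs(psum - best_sum) <= SUM_EPS && pdepth > best_depth)) {
        best_sum <<- psum
        best_depth <<- pdepth
        best_sel <<- sel
      }
      return(invisible(NULL))
    }
    inc_j <- inc[[j]]
    dep_j <- depths[[j]]
    for (k in seq_along(cands[[j]])) {
      s <- psum
      for (ie in inc_j) {
        s <- s + if (ie$j_is_col) W[[ie$e]][sel[ie$other], k]
                 else W[[ie$e]][k, sel[ie$other]]
      }
      if (prune && s > best_sum + SUM_EPS) next
      sel[j] <<- k
      rec(j + 1L, s, pdepth + dep_j[k])
    }
    invisible(NULL)
  }
  rec(1L, 0, 0)
  list(sum = best_sum, depth = best_depth, sel = best_sel, visited = visited)
}

new_assignment <- function(ps, sel_idx, mode, visited = NA_real_) {
  selection <- vapply(seq_along(ps$genes),
                      function(j) ps$cands[[j]][sel_idx[j]], character(1))
  names(selection) <- ps$genes
  obj_sum <- 0
  for (e in seq_len(nrow(ps$edges))) {
    obj_sum <- obj_sum + ps$W[[e]][sel_idx[ps$eu[e]], sel_idx[ps$ev[e]]]
  }
  structure(list(
    selection = selection,
    objective = obj_sum / nrow(ps$edges),
    total_depth = sum(vapply(seq_along(ps$genes),
                             function(j) ps$depths[[j]][sel_idx[j]], numeric(1))),
    search_space = ps$size,
    n_visited = visited,
    mode = mode
  ), class = "gfd_assignment")
}

#' @export
print.gfd_assignment <- function(x, ...) {
  cat(sprintf("<gfd_assignment> %d genes, objective %.6g (%s; %s of %s combinations visited)\n",
              length(x$selection), x$objective, x$mode,
              format(x$n_visited), format(x$search_space)))
  invisible(x)
}

#' Average edge dissimilarity under a given assignment
#'
#' The mean, over all edges of `network`, of the pairwise dissimilarity
#' between the terms selected for the two endpoints.  This is the
#' quantity the searches minimise.
#'
#' @param network A `gene_network` (every endpoint must be assigned).
#' @param assignment A `gfd_assignment` or a named character vector
#'   `gene -> accession`.
#' @param dag A `go_dag`.
#' @param measure Pairwise dissimilarity function
#'   `function(dag, t1, t2)`; defaults to [term_dissimilarity()].
#' @return A number in \[0, 1\].
#' @export
objective <- function(network, assignment, dag, measure = term_dissimilarity) {
  sel <- if (inherits(assignment, "gfd_assignment")) assignment$selection
         else assignment
  e <- network$edges
  if (nrow(e) == 0L) {
    gfd_error("gfdnet_no_scorable_edges", "network has no edges to average over")
  }
  missing <- setdiff(unique(c(e$from, e$to)), names(sel))
  if (length(missing)) {
    gfd_error("gfdnet_incomplete_assignment",
              sprintf("assignment is missing %d edge endpoint(s): %s",
                      length(missing),
                      paste(utils::head(missing, 5L), collapse = ", ")))
  }
  w <- vapply(seq_len(nrow(e)),
              function(i) measure(dag, sel[[e$from[i]]], sel[[e$to[i]]]),
              numeric(1))
  mean(w)
}

#' Exhaustive search over all term combinations
#'
#' Enumerates every combination of one candidate term per scorable gene
#' and returns the assignment minimising the average edge
#' dissimilarity.  Ties are broken by larger total depth of the
#' selected terms (the more specific combination wins), then by the
#' lexicographically smallest accession tuple in sorted-gene order, so
#' the result is fully deterministic.
#'
#' @param network A `gene_network`.
#' @param store An `annotation_store`.
#' @param dag A `go_dag`.
#' @param measure Pairwise dissimilarity function; defaults to
#'   [term_dissimilarity()].
#' @param cap Maximum number of combinations allowed (default `1e7`);
#'   beyond it a `gfdnet_search_space` error names the cap.
#' @return A `gfd_assignment` with elements `selection`, `objective`,
#'   `total_depth`, `search_space`, `n_visited`, `mode`.
#' @export
exhaustive_search <- function(network, store, dag,
                              measure = term_dissimilarity, cap = 1e7) {
  ps <- prepare_search(network, store, dag, measure)
  if (ps$size > cap) {
    gfd_error("gfdnet_search_space",
              sprintf("search space of %s combinations exceeds the cap of %s; use branch_and_bound or greedy",
                      format(ps$size, big.mark = ","), format(cap, big.mark = ",")))
  }
  res <- run_search_dfs(ps, prune = FALSE)
  new_assignment(ps, res$sel, "exhaustive", res$visited)
}

#' Branch-and-bound search over term combinations
#'
#' Explores the same combination tree as [exhaustive_search()] in the
#' same deterministic order, but prunes any partial assignment whose
#' partial edge-weight sum already exceeds the best complete sum found.
#' Because edge weights are non-negative this is an admissible bound:
#' the returned objective (and tie-breaking) equals the exhaustive
#' optimum exactly, usually after visiting far fewer combinations.
#'
#' @inheritParams exhaustive_search
#' @return A `gfd_assignment`; `n_visited` counts complete combinations
#'   actually evaluated.
#' @export
branch_and_bound_search <- function(network, store, dag,
                                    measure = term_dissimilarity) {
  ps <- prepare_search(network, store, dag, measure)
  res <- run_search_dfs(ps, prune = TRUE)
  new_assignment(ps, res$sel, "branch_and_bound", res$visited)
}

#' Greedy coordinate-descent search
#'
#' Deterministic fallback for combination spaces too large to
#' enumerate: each gene starts at its deepest candidate (ties to the
#' smallest accession), then genes are swept in sorted order,
#' re-selecting each gene's term to minimise the summed weight of its
#' incident edges (same tie-breaking as the exact searches), until a
#' full sweep changes nothing or `max_sweeps` is reached.  The returned
#' objective is an upper bound on the exhaustive optimum.
#'
#' @inheritParams exhaustive_search
#' @param max_sweeps Maximum number of full sweeps (default 20).
#' @return A `gfd_assignment`.
#' @export
greedy_search <- function(network, store, dag,
                          measure = term_dissimilarity, max_sweeps = 20L) {
  ps <- prepare_search(network, store, dag, measure)
  n <- length(ps$genes)

  sel <- vapply(seq_len(n), function(j) {
    d <- ps$depths[[j]]
    which(d == max(d))[1L]  # candidates sorted, so first = smallest accession
  }, integer(1))

  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    changed <- FALSE
    for (j in seq_len(n)) {
      inc_j <- ps$inc_all[[j]]
      best_k <- sel[j]
      best_s <- Inf
      best_d <- -Inf
      for (k in seq_along(ps$cands[[j]])) {
        s <- 0
        for (ie in inc_j) {
          s <- s + if (ie$j_is_col) ps$W[[ie$e]][sel[ie$other], k]
                   else ps$W[[ie$e]][k, sel[ie$other]]
        }
        d <- ps$depths[[j]][k]
        # strict argmin of (weight sum, -depth, accession); uniqueness
        # of the argmin makes every sweep deterministic and terminating
        if (s < best_s - SUM_EPS ||
            (abs(s - best_s) <= SUM_EPS && d > best_d)) {
          best_k <- k; best_s <- s; best_d <- d
        }
      }
      if (best_k != sel[j]) {
        sel[j] <- best_k
        changed <- TRUE
      }
    }
    if (!changed || sweeps >= max_sweeps) break
  }
  new_assignment(ps, sel, "greedy", NA_real_)
}

#' Score a gene network's functional dissimilarity
#'
#' Runs the full method: restrict to the scorable subgraph, search for
#' the most cohesive per-gene term assignment, weight every scorable
#' edge by the dissimilarity of the selected terms, and average.  The
#' network score and all edge/component scores lie in \[0, 1\]; 0 means
#' all connected genes agree on one common, specific function.
#' Connected components of the scorable subgraph are additionally
#' scored by the mean of their own edge weights, so the network score
#' equals the edge-count-weighted mean of the component scores.
#'
#' @inheritParams exhaustive_search
#' @param mode `"auto"` (branch-and-bound when the combination count is
#'   within `cap`, greedy otherwise), `"exhaustive"`,
#'   `"branch_and_bound"` or `"greedy"`.
#' @param max_sweeps Passed to [greedy_search()].
#' @return A `gfd_result`: list with `assignment` (named character,
#'   gene -> selected accession), `term_names`, `edge_weights`
#'   (data.frame `from`, `to`, `weight`), `network_score`,
#'   `component_scores` (data.frame `component`, `n_nodes`, `n_edges`,
#'   `score`), `component_nodes` (list of node vectors),
#'   `unannotated_genes`, `isolated_annotated`, `search_mode`,
#'   `search_space`, `n_visited`, `objective`, `measure_name`.
#' @examples
#' cfg <- synth_config(n_genes = 5, cohesion = 1, seed = 7)
#' dag <- random_dag(cfg)
#' ann <- cohesive_annotations(dag, cfg)
#' genes <- names(ann$store$genes)
#' net <- gene_network(genes[-5], genes[-1])  # path through the genes
#' gfd_score(net, ann$store, dag)$network_score  # 0: focal term recovered
#' @export
gfd_score <- function(network, store, dag,
                      mode = c("auto", "exhaustive", "branch_and_bound", "greedy"),
                      measure = term_dissimilarity, cap = 1e7,
                      max_sweeps = 20L) {
  mode <- match.arg(mode)
  ps <- prepare_search(network, store, dag, measure)

  used <- mode
  if (mode == "auto") used <- if (ps$size <= cap) "branch_and_bound" else "greedy"
  asg <- switch(used,
    exhaustive = {
      if (ps$size > cap) {
        gfd_error("gfdnet_search_space",
                  sprintf("search space of %s combinations exceeds the cap of %s",
                          format(ps$size, big.mark = ","),
                          format(cap, big.mark = ",")))
      }
      res <- run_search_dfs(ps, prune = FALSE)
      new_assignment(ps, res$sel, "exhaustive", res$visited)
    },
    branch_and_bound = {
      res <- run_search_dfs(ps, prune = TRUE)
      new_assignment(ps, res$sel, "branch_and_bound", res$visited)
    },
    greedy = {
      # reuse prepared state through the exported function for clarity
      greedy_search(network, store, dag, measure, max_sweeps)
    }
  )

  sel <- asg$selection
  e <- ps$edges
  w <- vapply(seq_len(nrow(e)),
              function(i) ps$pair_dissim(sel[[e$from[i]]], sel[[e$to[i]]]),
              numeric(1))
  edge_weights <- data.frame(from = e$from, to = e$to, weight = w,
                             stringsAsFactors = FALSE)

  g <- igraph::graph_from_data_frame(e, directed = FALSE,
                                     vertices = ps$subgraph$nodes)
  comp <- igraph::components(g)
  membership <- comp$membership
  edge_comp <- membership[e$from]
  comp_ids <- sort(unique(unname(edge_comp)))
  component_nodes <- lapply(comp_ids, function(ci)
    sort(names(membership)[membership == ci]))
  component_scores <- data.frame(
    component = seq_along(comp_ids),
    n_nodes = vapply(component_nodes, length, integer(1)),
    n_edges = vapply(comp_ids, function(ci) sum(edge_comp == ci), integer(1)),
    score = vapply(comp_ids, function(ci) mean(w[edge_comp == ci]), numeric(1))
  )
  isolated <- sort(names(membership)[!(membership %in% comp_ids)])

  structure(list(
    assignment = sel,
    term_names = dag$names,
    edge_weights = edge_weights,
    network_score = mean(w),
    objective = asg$objective,
    component_scores = component_scores,
    component_nodes = component_nodes,
    unannotated_genes = ps$unannotated,
    isolated_annotated = isolated,
    search_mode = used,
    search_space = ps$size,
    n_visited = asg$n_visited,
    measure_name = deparse(substitute(measure))
  ), class = "gfd_result")
}

#' @export
print.gfd_result <- function(x, ...) {
  cat(sprintf("<gfd_result> network dissimilarity %.4f over %d edges (%s search)\n",
              x$network_score, nrow(x$edge_weights), x$search_mode))
  if (nrow(x$component_scores) > 1L) {
    cat(sprintf("  %d components, scores: %s\n", nrow(x$component_scores),
                paste(sprintf("%.4f", x$component_scores$score), collapse = ", ")))
  }
  if (length(x$unannotated_genes)) {
    cat(sprintf("  %d unannotated gene(s) excluded: %s\n",
                length(x$unannotated_genes),
                paste(utils::head(x$unannotated_genes, 5L), collapse = ", ")))
  }
  invisible(x)
}
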