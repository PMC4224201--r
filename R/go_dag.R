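# Ontology DAG: OBO parsing, depth/ancestor queries, deepest common
# ancestor and the pairwise term dissimilarity.

#' Parse an OBO ontology into a GO DAG
#'
#' Reads an OBO 1.2/1.4 flat file and builds a rooted directed acyclic
#' graph over the non-obsolete terms of one namespace.  Only `is_a`
#' edges are used; `part_of`, `regulates` and other relationship types
#' are ignored, matching the usual "GO tree" reading of the ontology.
#' `is_a` references that point outside the selected namespace (or to
#' obsolete terms) are dropped and counted.
#'
#' Depth is the number of edges on the *longest* `is_a` path from the
#' namespace root, so a child is always strictly deeper than each of its
#' parents and depth is a monotone proxy for specificity.  Ancestor sets
#' are reflexive (every term is its own ancestor) and always contain the
#' root.
#'
#' @param path Path to an OBO file (plain or gzip-compressed).
#' @param namespace One of `"biological_process"`,
#'   `"molecular_function"`, `"cellular_component"`.
#'
#' @return A `go_dag` object: a list with elements `ids` (sorted
#'   accessions), `names` (named character), `namespace`, `parents`
#'   (named list of accession vectors), `root`, `depth` (named integer),
#'   `ancestors` (named list, reflexive), and drop counters
#'   `n_obsolete_dropped`, `n_edges_dropped`.
#'
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "namespace: biological_process", "",
#'   "[Term]", "id: GO:0000002", "name: child",
#'   "namespace: biological_process",
#'   "is_a: GO:0000001 ! root"), obo)
#' dag <- parse_obo(obo, "biological_process")
#' dag$depth
#' @export
parse_obo <- function(path,
                      namespace = c("biological_process",
                                    "molecular_function",
                                    "cellular_component")) {
  namespace <- match.arg(namespace)
  lines <- read_text_lines(path)

  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) {
    gfd_error("gfdnet_format_error",
              sprintf("no [Term] stanzas found in OBO file: %s", path))
  }
  # any stanza header ends the current term stanza
  stanza_heads <- which(grepl("^\\[.+\\]$", lines))
  n_all <- 0L
  ids <- character(0)
  nms <- character(0)
  nss <- character(0)
  obs <- logical(0)
  parents <- list()

  for (s in starts) {
    nxt <- stanza_heads[stanza_heads > s]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    block <- lines[seq.int(s + 1L, end)]
    # drop trailing "! comment" and surrounding whitespace
    block <- trimws(sub("\\s*!.*$", "", block))
    block <- block[nzchar(block)]

    pick <- function(key) {
      hit <- block[startsWith(block, paste0(key, ":"))]
      if (!length(hit)) return(character(0))
      trimws(sub(paste0("^", key, ":"), "", hit))
    }
    id <- pick("id")
    if (length(id) != 1L) next
    n_all <- n_all + 1L
    ids <- c(ids, id[1L])
    nm <- pick("name")
    nms <- c(nms, if (length(nm)) nm[1L] else "")
    ns <- pick("namespace")
    nss <- c(nss, if (length(ns)) ns[1L] else "")
    ob <- pick("is_obsolete")
    is_obs <- length(ob) > 0L && tolower(ob[1L]) == "true"
    obs <- c(obs, is_obs)
    # obsolete terms carry no parents
    parents[[id[1L]]] <- if (is_obs) character(0) else pick("is_a")
  }

  keep <- !obs & nss == namespace
  n_obsolete <- sum(obs & nss == namespace)
  if (!any(keep)) {
    gfd_error("gfdnet_empty_ontology",
              sprintf("no non-obsolete terms in namespace '%s' in %s",
                      namespace, path))
  }
  kept_ids <- ids[keep]
  kept_names <- nms[keep]
  kept_parents <- parents[kept_ids]
  # edges crossing out of the namespace (or to obsolete/unknown terms)
  n_edges_dropped <- 0L
  kept_parents <- lapply(kept_parents, function(p) {
    ok <- p %in% kept_ids
    n_edges_dropped <<- n_edges_dropped + sum(!ok)
    p[ok]
  })

  dag <- build_go_dag(kept_ids, kept_names, kept_parents, namespace)
  dag$n_obsolete_dropped <- n_obsolete
  dag$n_edges_dropped <- n_edges_dropped
  dag
}

# Shared DAG builder (used by parse_obo and the synthetic generator):
# validates acyclicity and single-rootedness, computes longest-path
# depth and reflexive ancestor sets by one topological pass.
build_go_dag <- function(ids, term_names, parents, namespace) {
  ids_order <- order(ids)
  ids <- ids[ids_order]
  term_names <- term_names[ids_order]
  names(term_names) <- ids
  parents <- lapply(parents[ids], function(p) sort(unique(p)))
  names(parents) <- ids

  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- ids

  roots <- ids[lengths(parents) == 0L]
  if (length(roots) == 0L) {
    gfd_error("gfdnet_format_error",
              "ontology has no root: every term has a parent (cycle?)")
  }
  if (length(roots) > 1L) {
    gfd_error("gfdnet_format_error",
              sprintf("ontology must have a single root, found %d: %s",
                      length(roots),
                      paste(utils::head(roots, 5L), collapse = ", ")))
  }

  # Kahn's algorithm on parent->child edges; also yields the topological
  # order used for depth and ancestor propagation.
  children <- vector("list", n)
  indeg <- lengths(parents)
  for (i in idx) {
    for (p in parents[[i]]) {
      pi <- idx[[p]]
      children[[pi]] <- c(children[[pi]], i)
    }
  }
  queue <- which(indeg == 0L)
  topo <- integer(0)
  indeg_w <- indeg
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    topo <- c(topo, v)
    for (c in children[[v]]) {
      indeg_w[c] <- indeg_w[c] - 1L
      if (indeg_w[c] == 0L) queue <- c(queue, c)
    }
  }
  if (length(topo) != n) {
    gfd_error("gfdnet_format_error", "is_a graph contains a cycle")
  }

  depth <- integer(n)
  ancestors <- vector("list", n)
  for (v in topo) {
    ps <- parents[[v]]
    if (length(ps) == 0L) {
      depth[v] <- 0L
      ancestors[[v]] <- ids[v]
    } else {
      pidx <- idx[ps]
      depth[v] <- max(depth[pidx]) + 1L
      ancestors[[v]] <- sort(unique(c(ids[v], unlist(ancestors[pidx],
                                                     use.names = FALSE))))
    }
  }
  names(depth) <- ids
  names(ancestors) <- ids

  structure(list(
    ids = ids,
    names = term_names,
    namespace = namespace,
    parents = parents,
    root = roots,
    depth = depth,
    ancestors = ancestors,
    n_obsolete_dropped = 0L,
    n_edges_dropped = 0L
  ), class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, namespace %s, root %s, max depth %d\n",
              length(x$ids), x$namespace, x$root, max(x$depth)))
  invisible(x)
}

check_term <- function(dag, t) {
  if (!t %in% dag$ids) {
    gfd_error("gfdnet_unknown_term",
              sprintf("term %s is not in the ontology DAG", t))
  }
}

#' Deepest common ancestor of two GO terms
#'
#' Among the shared (reflexive) ancestors of `t1` and `t2`, returns the
#' one of maximal depth; ties are broken by the lexicographically
#' smallest accession so the result is deterministic.
#'
#' @param dag A `go_dag` from [parse_obo()] or [random_dag()].
#' @param t1,t2 GO accessions present in `dag`.
#' @return A single accession string.
#' @export
deepest_common_ancestor <- function(dag, t1, t2) {
  check_term(dag, t1)
  check_term(dag, t2)
  if (t1 == t2) return(t1)
  common <- intersect(dag$ancestors[[t1]], dag$ancestors[[t2]])
  d <- dag$depth[common]
  deepest <- common[d == max(d)]
  sort(deepest)[1L]
}

#' Pairwise term dissimilarity
#'
#' The dissimilarity between two terms is
#' \deqn{1 - \frac{2\,\mathrm{depth}(\mathrm{DCA})}{\mathrm{depth}(t_1)+\mathrm{depth}(t_2)},}
#' a Wu–Palmer-style distance based on the deepest common ancestor
#' (DCA).  It is 0 for identical terms, 1 when the only shared ancestor
#' is the root, bounded in \[0, 1\], and rewards deep (specific) shared
#' ancestry.  The degenerate root-vs-root pair (depth sum 0) is defined
#' as 0.
#'
#' This is the default edge measure; [gfd_score()] accepts any function
#' with the same signature through its `measure` argument.
#'
#' @inheritParams deepest_common_ancestor
#' @return A number in \[0, 1\], symmetric in `t1`, `t2`.
#' @examples
#' # a 3-term chain root <- A <- B gives dissimilarity(A, B) = 1/3
#' @export
term_dissimilarity <- function(dag, t1, t2) {
  check_term(dag, t1)
  check_term(dag, t2)
  if (t1 == t2) return(0)
  d1 <- dag$depth[[t1]]
  d2 <- dag$depth[[t2]]
  if (d1 + d2 == 0L) return(0)
  dca <- deepest_common_ancestor(dag, t1, t2)
  1 - 2 * dag$depth[[dca]] / (d1 + d2)
}
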