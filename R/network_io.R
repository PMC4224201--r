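# Gene network I/O: SIF / edge-list readers and writers, result reports.

# Canonical constructor: undirected simple graph, edges stored with
# from < to, everything sorted for determinism.
#' Construct a gene network
#'
#' Builds an undirected simple graph over gene identifiers.  Self-loops
#' and duplicate (unordered) edges are dropped and counted; `nodes` may
#' add isolated nodes beyond the edge endpoints.
#'
#' @param from,to Character vectors of equal length: edge endpoints.
#' @param nodes Optional additional (isolated) node identifiers.
#' @return A `gene_network`: list with `nodes` (sorted character),
#'   `edges` (data.frame `from`, `to` with `from < to`), and drop
#'   counters.
#' @export
gene_network <- function(from = character(0), to = character(0),
                         nodes = character(0)) {
  stopifnot(length(from) == length(to))
  from <- as.character(from); to <- as.character(to)
  a <- pmin(from, to)
  b <- pmax(from, to)
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  a <- a[!dup]; b <- b[!dup]
  o <- order(a, b)
  edges <- data.frame(from = a[o], to = b[o], stringsAsFactors = FALSE)
  structure(list(
    nodes = sort(unique(c(edges$from, edges$to, as.character(nodes), from, to))),
    edges = edges,
    n_self_loops_dropped = n_self,
    n_duplicates_dropped = n_dup
  ), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a gene network from a SIF or edge-list file
#'
#' SIF rows `A rel B [C ...]` fan out to edges A–B, A–C, ...; a
#' single-token row declares an isolated node.  Edge-list rows have two
#' whitespace-separated columns.  Edge direction is discarded (the
#' dissimilarity measure is symmetric); duplicate edges and self-loops
#' are dropped with counts; node identity is the verbatim string, no
#' case folding.
#'
#' @param path Network file, plain or gzipped.
#' @param format `"sif"` or `"edgelist"`.
#' @return A `gene_network`.
#' @export
read_network <- function(path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  lines <- read_text_lines(path)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    gfd_error("gfdnet_empty_network", sprintf("network file is empty: %s", path))
  }
  from <- character(0); to <- character(0); isolated <- character(0)
  for (i in keep) {
    tok <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1L]]
    if (format == "sif") {
      if (length(tok) == 1L) {
        isolated <- c(isolated, tok)
      } else if (length(tok) == 2L) {
        gfd_error("gfdnet_format_error",
                  sprintf("%s line %d: SIF row has a relation but no target", path, i))
      } else {
        targets <- tok[-(1:2)]
        from <- c(from, rep(tok[1L], length(targets)))
        to <- c(to, targets)
      }
    } else {
      if (length(tok) != 2L) {
        gfd_error("gfdnet_format_error",
                  sprintf("%s line %d: expected 2 columns, got %d", path, i, length(tok)))
      }
      from <- c(from, tok[1L]); to <- c(to, tok[2L])
    }
  }
  gene_network(from, to, nodes = isolated)
}

#' Write a gene network to a SIF or edge-list file
#'
#' Inverse of [read_network()]: SIF output round-trips node and edge
#' sets exactly (isolated nodes become single-token rows); edge-list
#' output can only represent edge endpoints.
#'
#' @param network A `gene_network`.
#' @param path Output file path.
#' @param format `"sif"` or `"edgelist"`.
#' @param relation Interaction type written in SIF rows.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("sif", "edgelist"),
                          relation = "pp") {
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    iso <- setdiff(network$nodes, unique(c(e$from, e$to)))
    lines <- c(paste(e$from, relation, e$to, sep = "\t"), iso)
  } else {
    lines <- paste(e$from, e$to, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write the result reports of a dissimilarity analysis
#'
#' Writes three files into `out_dir`: `edge_weights.tsv`
#' (`gene1 gene2 weight`), `gene_terms.tsv`
#' (`gene selected_go_id go_name status`, where unannotated genes get an
#' empty term and status `"unannotated"`), and `summary.json` with the
#' network score, per-component scores, unannotated genes and the
#' settings used.
#'
#' @param result A `gfd_result` from [gfd_score()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    gfd_error("gfdnet_io_error", sprintf("cannot create output directory: %s", out_dir))
  }

  edge_path <- file.path(out_dir, "edge_weights.tsv")
  gene_path <- file.path(out_dir, "gene_terms.tsv")
  json_path <- file.path(out_dir, "summary.json")

  ew <- result$edge_weights
  names(ew) <- c("gene1", "gene2", "weight")
  utils::write.table(ew, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  sel <- result$assignment
  genes <- data.frame(
    gene = c(names(sel), result$unannotated_genes),
    selected_go_id = c(unname(sel), rep("", length(result$unannotated_genes))),
    go_name = c(unname(result$term_names[sel]),
                rep("", length(result$unannotated_genes))),
    status = c(rep("annotated", length(sel)),
               rep("unannotated", length(result$unannotated_genes))),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$gene), , drop = FALSE]
  utils::write.table(genes, gene_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  comp <- lapply(seq_len(nrow(result$component_scores)), function(i) {
    list(nodes = result$component_nodes[[i]],
         n_edges = result$component_scores$n_edges[i],
         score = result$component_scores$score[i])
  })
  jsonlite::write_json(
    list(network_score = result$network_score,
         component_scores = comp,
         unannotated_genes = result$unannotated_genes,
         settings = list(search_mode = result$search_mode,
                         search_space = result$search_space,
                         measure = result$measure_name)),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(edges = edge_path, genes = gene_path, summary = json_path))
}
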