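# Seeded synthetic ontologies, annotation stores and fixture networks,
# so the whole pipeline is testable with no downloads.  Every generator
# is a pure function of its SynthConfig: one global seed drives all
# draws, with fixed per-operation offsets.

SEED_OFFSET_DAG <- 101L
SEED_OFFSET_ANN <- 202L

#' Configuration for the synthetic generators
#'
#' Bundles the sizes and the cohesion level used by [random_dag()] and
#' [cohesive_annotations()].  Defaults describe a small pathway-sized
#' problem: a 40-term ontology, 8 genes with 2 products of 2 terms each
#' (so at most 4 candidate terms per gene), and intermediate cohesion.
#'
#' @param n_terms Number of ontology terms (>= 1).
#' @param max_parents Maximum `is_a` parents drawn per non-root term.
#' @param n_genes Number of genes.
#' @param products_per_gene Gene products per gene.
#' @param terms_per_product Annotation slots per product.
#' @param cohesion Probability in \[0, 1\] that an annotation slot
#'   carries the focal term rather than a uniformly random term.
#' @param seed Integer seed; all generator draws derive from it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_terms = 40L, max_parents = 3L, n_genes = 8L,
                         products_per_gene = 2L, terms_per_product = 2L,
                         cohesion = 0.5, seed = 1L) {
  counts <- c(n_terms = n_terms, max_parents = max_parents,
              n_genes = n_genes, products_per_gene = products_per_gene,
              terms_per_product = terms_per_product)
  if (any(counts < 1L) || any(counts != round(counts))) {
    gfd_error("gfdnet_config_error", "all synthetic counts must be integers >= 1")
  }
  if (!is.numeric(cohesion) || length(cohesion) != 1L ||
      is.na(cohesion) || cohesion < 0 || cohesion > 1) {
    gfd_error("gfdnet_config_error", "cohesion must be a number in [0, 1]")
  }
  structure(list(n_terms = as.integer(n_terms),
                 max_parents = as.integer(max_parents),
                 n_genes = as.integer(n_genes),
                 products_per_gene = as.integer(products_per_gene),
                 terms_per_product = as.integer(terms_per_product),
                 cohesion = cohesion,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate a random rooted GO-like DAG
#'
#' Term 1 is the root; each later term draws between 1 and
#' `max_parents` parents uniformly from the terms generated before it,
#' which guarantees acyclicity and a single root.  Accessions follow
#' the `GO:` + 7-digit pattern; the namespace is `biological_process`.
#' Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return A `go_dag`.
#' @export
random_dag <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  parents <- withr::with_seed(config$seed + SEED_OFFSET_DAG, {
    lapply(seq_len(n), function(i) {
      if (i == 1L) return(character(0))
      k <- min(sample.int(config$max_parents, 1L), i - 1L)
      ids[sort(sample.int(i - 1L, k))]
    })
  })
  names(parents) <- ids
  build_go_dag(ids, sprintf("synthetic term %d", seq_len(n)), parents,
               "biological_process")
}

#' Generate an annotation store with tunable cohesion
#'
#' Picks a focal term of maximal depth (ties to the smallest accession)
#' and fills every annotation slot of every gene product with the focal
#' term with probability `cohesion`, otherwise with a uniformly random
#' term.  At cohesion 1 every gene is annotated only with the focal
#' term, so the scored network recovers it exactly and scores 0; the
#' focal term is returned as ground truth for such recovery checks.
#'
#' @param dag A `go_dag` (needs a term of depth >= 2 when
#'   `cohesion > 0`).
#' @param config A [synth_config()].
#' @return List with `store` (an `annotation_store`) and `focal_term`.
#' @export
cohesive_annotations <- function(dag, config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$cohesion > 0 && max(dag$depth) < 2L) {
    gfd_error("gfdnet_config_error",
              "cohesive annotations need a DAG with a term of depth >= 2")
  }
  deepest <- dag$ids[dag$depth == max(dag$depth)]
  focal <- sort(deepest)[1L]

  ng <- config$n_genes
  np <- config$products_per_gene
  nt <- config$terms_per_product
  genes <- sprintf("g%03d", seq_len(ng))
  slots <- ng * np * nt

  terms <- withr::with_seed(config$seed + SEED_OFFSET_ANN, {
    u <- stats::runif(slots)
    rnd <- dag$ids[sample.int(length(dag$ids), slots, replace = TRUE)]
    take_focal <- if (config$cohesion >= 1) rep(TRUE, slots) else u < config$cohesion
    ifelse(take_focal, focal, rnd)
  })

  rows <- data.frame(
    gene = rep(genes, each = np * nt),
    product = rep(sprintf("%s_p%d", rep(genes, each = np),
                          rep(seq_len(np), times = ng)), each = nt),
    term = terms,
    stringsAsFactors = FALSE
  )
  list(store = new_annotation_store(rows, dag), focal_term = focal)
}

#' Named fixture networks
#'
#' Small deterministic topologies used throughout the tests: a 5-node
#' clique, a 7-node path, and a two-component network (a 5-clique plus
#' a 7-node hub component) echoing a pathway that splits into one
#' tightly cohesive sub-network and one looser one.
#'
#' @return Named list of `gene_network` objects: `clique5`, `path7`,
#'   `two_component`.
#' @export
fixture_networks <- function() {
  clique_edges <- function(nodes) {
    cmb <- utils::combn(nodes, 2L)
    gene_network(cmb[1L, ], cmb[2L, ])
  }
  c5 <- sprintf("c%d", 1:5)
  p7 <- sprintf("p%d", 1:7)
  s5 <- sprintf("s%d", 1:5)
  t7 <- sprintf("t%d", 1:7)
  cmb <- utils::combn(s5, 2L)
  two_from <- c(cmb[1L, ], "t1", "t1", "t2", "t3", "t3", "t3", "t3")
  two_to   <- c(cmb[2L, ], "t2", "t3", "t3", "t4", "t5", "t6", "t7")
  list(
    clique5 = clique_edges(c5),
    path7 = gene_network(p7[-7L], p7[-1L]),
    two_component = gene_network(two_from, two_to)
  )
}

#' Two-component contrast fixture
#'
#' A deterministic end-to-end fixture mirroring the qualitative pattern
#' of a network split into one highly cohesive sub-network and one with
#' divergent, generic annotations: component 1 (the 5-clique `s1..s5`)
#' shares a deep focal term and scores 0; component 2 (`t1..t7`)
#' carries divergent shallow terms whose only common ancestor is the
#' root, so its edges weigh 1.  The global score lies strictly between
#' the two component scores.
#'
#' @return List with `dag`, `store`, `network`, `focal_term`.
#' @export
contrast_fixture <- function() {
  # hand-built DAG: root; three shallow generic siblings; one chain to
  # a deep, specific focal term
  ids <- sprintf("GO:%07d", 1:7)
  parents <- list(character(0),          # 1 root
                  ids[1L],               # 2 shallow sibling
                  ids[1L],               # 3 shallow sibling
                  ids[1L],               # 4 shallow sibling
                  ids[1L],               # 5 chain level 1
                  ids[5L],               # 6 chain level 2
                  ids[6L])               # 7 focal, depth 3
  names(parents) <- ids
  dag <- build_go_dag(
    ids,
    c("root process", "generic process a", "generic process b",
      "generic process c", "pathway level 1", "pathway level 2",
      "specific pathway step"),
    parents, "biological_process")

  net <- fixture_networks()$two_component
  s_genes <- sprintf("s%d", 1:5)
  t_genes <- sprintf("t%d", 1:7)
  rows <- rbind(
    data.frame(gene = s_genes, product = paste0(s_genes, "_p1"),
               term = ids[7L], stringsAsFactors = FALSE),
    # neighbours in the t-component always carry different shallow
    # siblings, so every edge there weighs 1
    data.frame(gene = t_genes, product = paste0(t_genes, "_p1"),
               term = ids[c(2L, 3L, 4L, 2L, 3L, 2L, 3L)],
               stringsAsFactors = FALSE)
  )
  list(dag = dag, store = new_annotation_store(rows, dag),
       network = net, focal_term = ids[7L])
}

#' Write an ontology as an OBO file
#'
#' Serialises a `go_dag` back to OBO 1.2, so generated ontologies can
#' round-trip through [parse_obo()] and exercise the CLI end to end.
#'
#' @param dag A `go_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2",
             sprintf("ontology: synthetic (%s)", dag$namespace))
  for (id in dag$ids) {
    lines <- c(lines, "", "[Term]",
               paste0("id: ", id),
               paste0("name: ", dag$names[[id]]),
               paste0("namespace: ", dag$namespace),
               if (length(dag$parents[[id]]))
                 paste0("is_a: ", dag$parents[[id]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write an annotation store as a 3-column TSV
#'
#' @param store An `annotation_store`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(store, path) {
  lines <- "gene\tproduct\tgo_id"
  for (g in names(store$genes)) {
    for (p in names(store$genes[[g]])) {
      lines <- c(lines, paste(g, p, store$genes[[g]][[p]], sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Generates a DAG, cohesive annotations and a network over the
#' generated genes, and persists them as `ontology.obo`,
#' `annotations.tsv` and `network.sif` in `dir` — a self-contained
#' input set for the `score` command.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if needed).
#' @param network Optional `gene_network` over the generated gene ids
#'   `g001..`; by default a path through all genes.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synth_bundle <- function(config, dir, network = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    gfd_error("gfdnet_io_error", sprintf("cannot create directory: %s", dir))
  }
  dag <- random_dag(config)
  ann <- cohesive_annotations(dag, config)
  if (is.null(network)) {
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    network <- if (config$n_genes == 1L) gene_network(nodes = genes)
               else gene_network(genes[-config$n_genes], genes[-1L])
  }
  paths <- c(obo = file.path(dir, "ontology.obo"),
             annotations = file.path(dir, "annotations.tsv"),
             network = file.path(dir, "network.sif"))
  write_obo(dag, paths[["obo"]])
  write_annotations_tsv(ann$store, paths[["annotations"]])
  write_network(network, paths[["network"]], "sif")
  invisible(paths)
}
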