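# In-code fixtures: tiny OBO/GAF/TSV files written to tempfiles, plus
# a seeded random problem instance built through the exported API.

obo_term <- function(id, name = id, ns = "biological_process",
                     is_a = character(0), obsolete = FALSE) {
  c("[Term]",
    paste0("id: ", id),
    paste0("name: ", name),
    paste0("namespace: ", ns),
    if (length(is_a)) paste0("is_a: ", is_a, " ! parent"),
    if (obsolete) "is_obsolete: true",
    "")
}

obo_file <- function(...) {
  path <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", unlist(list(...))), path)
  path
}

# root GO:0000001 <- GO:0000002 <- GO:0000003 (depths 0, 1, 2)
chain_dag <- function() {
  parse_obo(obo_file(
    obo_term("GO:0000001", "root"),
    obo_term("GO:0000002", "mid", is_a = "GO:0000001"),
    obo_term("GO:0000003", "leaf", is_a = "GO:0000002")
  ), "biological_process")
}

# two leaves GO:0000002, GO:0000003 directly under the root
sibling_dag <- function() {
  parse_obo(obo_file(
    obo_term("GO:0000001", "root"),
    obo_term("GO:0000002", "left", is_a = "GO:0000001"),
    obo_term("GO:0000003", "right", is_a = "GO:0000001")
  ), "biological_process")
}

# R <- A, R <- B, A <- C, B <- C
diamond_dag <- function() {
  parse_obo(obo_file(
    obo_term("GO:0000001", "root"),
    obo_term("GO:0000002", "A", is_a = "GO:0000001"),
    obo_term("GO:0000003", "B", is_a = "GO:0000001"),
    obo_term("GO:0000004", "C", is_a = c("GO:0000002", "GO:0000003"))
  ), "biological_process")
}

tsv_file <- function(rows, header = TRUE) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(if (header) "gene\tproduct\tgo_id", rows), path)
  path
}

tsv_store <- function(rows, dag) load_tsv(tsv_file(rows), dag)

gaf_row <- function(symbol, product, term, qualifier = "", aspect = "P",
                    evidence = "EXP") {
  f <- rep("-", 17L)
  f[1L] <- "DB"; f[2L] <- product; f[3L] <- symbol; f[4L] <- qualifier
  f[5L] <- term; f[6L] <- "PMID:1"; f[7L] <- evidence; f[8L] <- ""
  f[9L] <- aspect; f[10L] <- ""; f[11L] <- ""; f[12L] <- "protein"
  f[13L] <- "taxon:9606"; f[14L] <- "20140501"; f[15L] <- "DB"
  f[16L] <- ""; f[17L] <- ""
  paste(f, collapse = "\t")
}

gaf_file <- function(rows) {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.1", rows), path)
  path
}

# Seeded random problem instance, sized for exhaustive enumeration:
# 2..max_genes genes with at most 4 candidate terms each on a random
# DAG of 15..50 terms, connected by a random edge set.
random_instance <- function(seed, max_genes = 6L) {
  params <- withr::with_seed(seed, list(
    n_genes = sample(2:max_genes, 1L),
    n_terms = sample(15:50, 1L),
    cohesion = sample(c(0, 0.3, 0.6), 1L)
  ))
  cfg <- synth_config(n_terms = params$n_terms, max_parents = 3L,
                      n_genes = params$n_genes, products_per_gene = 2L,
                      terms_per_product = 2L, cohesion = params$cohesion,
                      seed = seed)
  dag <- random_dag(cfg)
  ann <- cohesive_annotations(dag, cfg)
  genes <- names(ann$store$genes)
  net <- withr::with_seed(seed + 7L, {
    pairs <- utils::combn(genes, 2L)
    keep <- stats::runif(ncol(pairs)) < 0.6
    if (!any(keep)) keep[1L] <- TRUE
    gene_network(pairs[1L, keep], pairs[2L, keep])
  })
  list(dag = dag, store = ann$store, network = net, config = cfg,
       focal_term = ann$focal_term)
}
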