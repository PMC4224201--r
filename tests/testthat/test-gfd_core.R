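# Assignment search and network scoring.

test_that("the scorable subgraph excludes edges touching unannotated genes", {
  dag <- chain_dag()
  store <- tsv_store(c("a\tp\tGO:0000002", "b\tp\tGO:0000003"), dag)

  triangle <- gene_network(c("a", "a", "b"), c("b", "x", "x"))
  sg <- scorable_subgraph(triangle, store)
  expect_identical(nrow(sg$network$edges), 1L)
  expect_identical(sg$unannotated, "x")

  full <- gene_network("a", "b")
  sg2 <- scorable_subgraph(full, store)
  expect_identical(sg2$network$edges, full$edges)
  expect_length(sg2$unannotated, 0L)

  star <- gene_network(c("hub", "hub"), c("a", "b"))
  hub_store <- tsv_store(c("a\tp\tGO:0000002", "b\tp\tGO:0000003"), dag)
  expect_error(scorable_subgraph(star, hub_store),
               class = "gfdnet_no_scorable_edges")
})

test_that("the objective is the mean edge dissimilarity of the selected terms", {
  chain <- chain_dag()
  triangle <- gene_network(c("a", "a", "b"), c("b", "c", "c"))
  same <- c(a = "GO:0000003", b = "GO:0000003", c = "GO:0000003")
  expect_identical(objective(triangle, same, chain), 0)

  one_edge <- gene_network("a", "b")
  ab <- c(a = "GO:0000002", b = "GO:0000003")
  expect_equal(objective(one_edge, ab, chain), 1 / 3)

  # weights 1/3 (mid vs leaf) and 1 (siblings of a 4-term DAG)
  dag4 <- parse_obo(obo_file(
    obo_term("GO:0000001", "root"),
    obo_term("GO:0000002", "mid", is_a = "GO:0000001"),
    obo_term("GO:0000003", "leaf", is_a = "GO:0000002"),
    obo_term("GO:0000004", "stray", is_a = "GO:0000001")
  ), "biological_process")
  two <- gene_network(c("a", "c"), c("b", "d"))
  sel <- c(a = "GO:0000002", b = "GO:0000003", c = "GO:0000002", d = "GO:0000004")
  expect_equal(objective(two, sel, dag4), mean(c(1 / 3, 1)))

  expect_error(objective(one_edge, c(a = "GO:0000002"), chain),
               class = "gfdnet_incomplete_assignment")
})

test_that("exhaustive search picks the cohesive combination deterministically", {
  chain <- chain_dag()
  # forced: single candidates
  forced_store <- tsv_store(c("a\tp\tGO:0000002", "b\tp\tGO:0000003"), chain)
  forced <- exhaustive_search(gene_network("a", "b"), forced_store, chain)
  expect_identical(forced$selection, c(a = "GO:0000002", b = "GO:0000003"))

  # 2 genes, candidates {A} and {A, B}: both select A, objective 0
  store <- tsv_store(c("a\tp\tGO:0000002",
                       "b\tp\tGO:0000002", "b\tp\tGO:0000003"), chain)
  res <- exhaustive_search(gene_network("a", "b"), store, chain)
  expect_identical(res$selection, c(a = "GO:0000002", b = "GO:0000002"))
  expect_identical(res$objective, 0)

  # clique of 4 genes sharing one leaf among decoys: shared leaf wins
  dag <- random_dag(synth_config(n_terms = 25L, seed = 5L))
  leaf <- dag$ids[which.max(dag$depth)]
  genes <- c("w", "x", "y", "z")
  rows <- unlist(lapply(genes, function(g) {
    decoys <- withr::with_seed(match(g, genes), sample(setdiff(dag$ids, leaf), 2L))
    sprintf("%s\tp\t%s", g, c(leaf, decoys))
  }))
  cstore <- tsv_store(rows, dag)
  pairs <- utils::combn(genes, 2L)
  clique <- gene_network(pairs[1L, ], pairs[2L, ])
  cres <- exhaustive_search(clique, cstore, dag)
  expect_identical(unname(cres$selection), rep(leaf, 4L))
  expect_identical(cres$objective, 0)
  # and agrees with the independent expand.grid oracle
  oracle <- oracle_exhaustive(clique, cstore, dag)
  expect_identical(cres$selection, oracle$selection)
  expect_equal(cres$objective, oracle$objective)

  expect_error(exhaustive_search(clique, cstore, dag, cap = 10),
               "cap", class = "gfdnet_search_space")
})

test_that("exhaustive search agrees with the independent enumeration oracle", {
  for (seed in 1:12) {
    inst <- random_instance(seed, max_genes = 4L)
    res <- exhaustive_search(inst$network, inst$store, inst$dag)
    oracle <- oracle_exhaustive(inst$network, inst$store, inst$dag)
    expect_equal(res$objective, oracle$objective, tolerance = 1e-12)
    expect_identical(res$selection, oracle$selection)
  }
})

test_that("branch-and-bound reproduces the exhaustive optimum while pruning", {
  for (seed in 21:40) {
    inst <- random_instance(seed)
    exh <- exhaustive_search(inst$network, inst$store, inst$dag)
    bnb <- branch_and_bound_search(inst$network, inst$store, inst$dag)
    expect_identical(bnb$selection, exh$selection)
    expect_identical(bnb$objective, exh$objective)
    expect_identical(exh$n_visited, exh$search_space)
    expect_lte(bnb$n_visited, exh$n_visited)
  }
  # when the first explored branch is optimal (shared leaf sorts before
  # the decoy), everything after it is pruned
  dag4 <- parse_obo(obo_file(
    obo_term("GO:0000001", "root"),
    obo_term("GO:0000002", "mid", is_a = "GO:0000001"),
    obo_term("GO:0000003", "leaf", is_a = "GO:0000002"),
    obo_term("GO:0000004", "stray", is_a = "GO:0000001")
  ), "biological_process")
  genes <- c("a", "b", "c", "d")
  store <- tsv_store(unlist(lapply(genes, function(g)
    sprintf("%s\tp\t%s", g, c("GO:0000003", "GO:0000004")))), dag4)
  pairs <- utils::combn(genes, 2L)
  clique <- gene_network(pairs[1L, ], pairs[2L, ])
  bnb <- branch_and_bound_search(clique, store, dag4)
  expect_identical(bnb$objective, 0)
  expect_lt(bnb$n_visited, bnb$search_space)
})

test_that("greedy descent never beats the optimum and solves cohesive cases", {
  chain <- chain_dag()
  forced_store <- tsv_store(c("a\tp\tGO:0000002", "b\tp\tGO:0000003"), chain)
  net <- gene_network("a", "b")
  expect_identical(greedy_search(net, forced_store, chain)$selection,
                   exhaustive_search(net, forced_store, chain)$selection)

  for (seed in 41:60) {
    inst <- random_instance(seed)
    exh <- exhaustive_search(inst$network, inst$store, inst$dag)
    greedy <- greedy_search(inst$network, inst$store, inst$dag)
    expect_gte(greedy$objective, exh$objective - 1e-12)
  }

  # shared deepest leaf in a clique: greedy's first sweep already hits 0
  cfg <- synth_config(n_genes = 5L, cohesion = 1, seed = 3L)
  dag <- random_dag(cfg)
  ann <- cohesive_annotations(dag, cfg)
  genes <- names(ann$store$genes)
  pairs <- utils::combn(genes, 2L)
  clique <- gene_network(pairs[1L, ], pairs[2L, ])
  expect_identical(greedy_search(clique, ann$store, dag)$objective, 0)
})

test_that("scores are consistent: mean of edges, weighted mean of components, in [0,1]", {
  for (seed in 61:75) {
    inst <- random_instance(seed)
    r <- gfd_score(inst$network, inst$store, inst$dag)
    expect_true(all(r$edge_weights$weight >= 0 & r$edge_weights$weight <= 1))
    expect_gte(r$network_score, 0)
    expect_lte(r$network_score, 1)
    expect_equal(r$network_score, mean(r$edge_weights$weight), tolerance = 1e-12)
    cs <- r$component_scores
    expect_equal(r$network_score,
                 sum(cs$score * cs$n_edges) / sum(cs$n_edges),
                 tolerance = 1e-12)
    expect_identical(sum(cs$n_edges), nrow(r$edge_weights))
  }
})

test_that("two disjoint edges with weights 0 and 1 average to 0.5 with per-component scores", {
  dag <- sibling_dag()
  store <- tsv_store(c("a\tp\tGO:0000002", "b\tp\tGO:0000002",
                       "c\tp\tGO:0000002", "d\tp\tGO:0000003"), dag)
  net <- gene_network(c("a", "c"), c("b", "d"))
  r <- gfd_score(net, store, dag)
  expect_equal(r$network_score, 0.5)
  expect_equal(sort(r$component_scores$score), c(0, 1))
})

test_that("the network score is invariant under gene relabeling", {
  inst <- random_instance(81L)
  rows <- character(0)
  for (g in names(inst$store$genes)) {
    for (p in names(inst$store$genes[[g]])) {
      rows <- c(rows, sprintf("%s\t%s\t%s", g, p, inst$store$genes[[g]][[p]]))
    }
  }
  relabel <- function(x) paste0("ZZ_", x, "_Q")
  rows2 <- rows
  for (g in names(inst$store$genes)) {
    rows2 <- sub(paste0("^", g, "\t"), paste0(relabel(g), "\t"), rows2)
  }
  store2 <- load_tsv(tsv_file(rows2), inst$dag)
  net2 <- gene_network(relabel(inst$network$edges$from),
                       relabel(inst$network$edges$to))
  r1 <- gfd_score(inst$network, inst$store, inst$dag)
  r2 <- gfd_score(net2, store2, inst$dag)
  expect_equal(r1$network_score, r2$network_score, tolerance = 1e-12)
})

test_that("a shared maximal-depth candidate forces a zero-score optimum", {
  for (seed in 91:95) {
    dag <- random_dag(synth_config(n_terms = 30L, seed = seed))
    deep <- dag$ids[which.max(dag$depth)]
    shallow <- dag$ids[dag$depth < max(dag$depth)]
    genes <- sprintf("g%d", 1:4)
    rows <- unlist(lapply(seq_along(genes), function(i) {
      decoys <- withr::with_seed(seed + i, sample(shallow, 2L))
      sprintf("%s\tp\t%s", genes[i], c(deep, decoys))
    }))
    store <- tsv_store(rows, dag)
    net <- gene_network(genes[-4L], genes[-1L])
    r <- gfd_score(net, store, dag)
    expect_identical(r$network_score, 0)
    expect_identical(unname(r$assignment), rep(deep, 4L))
  }
})

test_that("an extra edge between identically-assigned genes cannot raise the score", {
  dag <- chain_dag()
  sel <- c(a = "GO:0000003", b = "GO:0000003", c = "GO:0000002")
  net <- gene_network(c("a", "b"), c("c", "c"))
  with_extra <- gene_network(c("a", "b", "a"), c("c", "c", "b"))
  expect_lte(objective(with_extra, sel, dag), objective(net, sel, dag))
})
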