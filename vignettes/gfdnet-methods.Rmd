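---
title: "Measuring the functional dissimilarity of gene networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the functional dissimilarity of gene networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfdnet)
```

## The problem

Inferred gene and protein interaction networks need validation: do the
genes that the topology connects actually work together?  Semantic
similarity measures over the Gene Ontology (GO) can compare gene sets,
but most ignore *how* the genes are wired to each other.  `gfdnet`
scores a network by asking a joint question: is there a choice of one
GO annotation per gene — each gene picking from the terms its gene
products genuinely carry — under which connected genes agree on a
common, specific function?

Genes are multifunctional, so this is a combinatorial assignment
problem.  The measure is deliberately optimistic: the network is judged
by its *most cohesive* annotation assignment, not by an average over
all annotations, because a network can be biologically coherent even
when each gene also has many unrelated functions.

## The model

Let $G = (V, E)$ be an undirected simple graph over gene identifiers,
and let each gene $v$ have a candidate set $C(v)$: the union of the GO
terms annotated to its gene products, restricted to one namespace.  An
assignment $a$ selects one term $a(v) \in C(v)$ per scorable gene.  The
network dissimilarity is

$$\mathrm{GFD}(G) \;=\; \min_{a} \; \frac{1}{|E|} \sum_{(u,v) \in E} d\big(a(u),\, a(v)\big),$$

where $d$ is a pairwise term dissimilarity in $[0, 1]$.  By default

$$d(t_1, t_2) \;=\; 1 - \frac{2\,\mathrm{depth}(\mathrm{DCA}(t_1, t_2))}{\mathrm{depth}(t_1) + \mathrm{depth}(t_2)},$$

a Wu–Palmer-style distance: $\mathrm{DCA}$ is the deepest common
ancestor of the two terms in the `is_a` DAG, and depth is the number of
edges on the *longest* path from the namespace root.  The measure is 0
for identical terms, 1 when the only shared ancestor is the root, and
it rewards deep (specific) shared ancestry — two terms that agree on a
specific biological process score much closer than two terms whose only
commonality is something generic.  The degenerate root-versus-root pair
is defined as 0.  Both edge weights and the network score therefore lie
in $[0, 1]$, with 0 the best (most cohesive) value.

The depth convention matters: longest-path depth guarantees
$\mathrm{depth}(\text{child}) > \mathrm{depth}(\text{parent})$ on a
DAG, so specificity is monotone along `is_a` paths.  `d` is exposed
behind a function argument (`measure =`) in all scoring entry points,
so an alternative term distance (e.g. a purely path-length-based one)
can be plugged in without touching the search.

Connected components are scored separately as the mean of their own
edge weights; the global score is then exactly the edge-count-weighted
mean of the component scores, which the tests assert on every instance.
A low-scoring component flags a functionally tight sub-network even
when the rest of the graph is noisy.

## What the ontology and annotation layers do

* `parse_obo()` loads one namespace of an OBO 1.2/1.4 file, drops
  obsolete terms and `is_a` edges that cross out of the namespace
  (both counted), and precomputes depth and reflexive ancestor sets.
  Only `is_a` edges are used; `part_of` and `regulates` would blur the
  subsumption semantics the depth argument relies on.
* `load_gaf()` reads GAF 2.1/2.2: rows with a `NOT` qualifier, rows
  whose aspect does not match the DAG's namespace, and (optionally)
  rows with excluded evidence codes are skipped; terms unknown to the
  DAG are dropped with a count.  All evidence codes are accepted by
  default because a validation measure should see the annotations a
  practitioner would see; `exclude_evidence = "IEA"` restricts to
  curated evidence.
* Candidate sets are the per-gene **union over gene products**,
  deduplicated and sorted.  One could instead select a term per
  product and aggregate; we select per gene because the result we
  report — and the one users act on — is a single function per network
  node.  The per-product variant is representable by giving each
  product its own node.

Genes present in the network but absent from the store are excluded
from scoring rather than penalised: an unannotated gene says nothing
about cohesion either way.  They are reported loudly in the result and
the per-gene output (`status = "unannotated"`), and a network with no
scorable edge at all is an error, not a score.

## The search

`exhaustive_search()` enumerates the full product of candidate sets in
lexicographic order (genes sorted, candidates sorted).  Ties on the
objective are broken first toward the larger total depth of the
selected terms — between two equally cohesive assignments the more
specific one is the more informative answer — then toward the
lexicographically smallest accession tuple, making every result fully
deterministic.  A cap (default $10^7$ combinations) guards against
accidental explosion.

`branch_and_bound_search()` walks the same tree in the same order but
prunes any partial assignment whose partial edge-weight sum already
exceeds the best complete sum.  Edge weights are non-negative, so the
bound is admissible and the result — objective, tie-breaking,
selection — equals the exhaustive one exactly; the tests assert this
equivalence on 100 seeded random instances, and the visited-combination
counter shows the pruning.

`greedy_search()` is the fallback beyond the cap: initialise every
gene at its deepest candidate, then sweep genes in sorted order,
re-selecting each gene's term to minimise the summed weight of its
incident edges, until a sweep changes nothing (or 20 sweeps).  Each
accepted move strictly improves the lexicographic key (weight sum,
then depth, then accession), so the descent terminates; its objective
is an upper bound on the optimum, and the observed gap on small random
instances is reported by the acceptance script (about 0.01–0.02 mean
excess under the default generator).

`gfd_score(mode = "auto")` uses branch-and-bound when the combination
count is within the cap and greedy otherwise.

Pairwise dissimilarities are memoised per run and candidate sets are
deduplicated sorted sequences, so repeated term pairs are never
re-measured and all iteration orders are reproducible.

## Numerical choices

Edge-weight sums are compared with an absolute slack of $10^{-9}$.
Weights are ratios of small integer depths, so genuinely different sums
differ by far more than this; the slack only absorbs floating-point
accumulation order, and in particular keeps equal-sum branches alive in
the branch-and-bound so depth tie-breaking sees them.

## What the synthetic generator emulates

Real inputs (a GO release, a GAF, a pathway-derived network) are
external downloads, so the package generates its own study conditions:

* `random_dag()`: term $i$ draws 1–`max_parents` parents uniformly
  from earlier terms — acyclic and single-rooted by construction,
  deterministic given the seed.
* `cohesive_annotations()`: picks a focal term of maximal depth and
  fills each annotation slot with it with probability `cohesion`,
  otherwise with a uniform random term.  The focal term is returned as
  ground truth.  Choosing the focal term at *maximal* depth makes
  `cohesion = 1` provably score 0 (a shared deepest candidate is
  always the optimum), which anchors the recovery tests.
* `fixture_networks()` and `contrast_fixture()` provide fixed
  topologies, including a two-component network whose first component
  shares a deep focal term (component score 0) while the second
  carries divergent shallow terms (component score 1, network score
  strictly between) — the qualitative pattern of a pathway that splits
  into one tight and one loose sub-network.

Defaults (40 terms, max 3 parents, 8 genes, 2 products of 2 terms
each, cohesion 0.5) describe a small pathway-sized problem in which
each gene has at most 4 candidate terms.  The test suite and the
acceptance script run 100 random instances of 2–6 genes on 15–50-term
DAGs for the search-equivalence checks and 200 replicates per cohesion
level (0.1, 0.5, 0.9) for the Monte-Carlo monotonicity of the mean
score; at these sizes the whole suite completes in well under a
minute, and the strict ordering of the three means is reproduced at
every seed we tried.

What the generator does **not** emulate: the real GO's topology
statistics (its fan-in, depth distribution and term density), organism-
or curation-specific annotation biases, and the sheer scale of a full
annotation corpus.  Passing tests therefore demonstrate the
correctness of the machinery — parsing, search optimality, score
algebra, ground-truth recovery — not the biological calibration of any
particular score value on real data.

## Design choices that were genuinely open

* **The edge measure itself.**  The dissimilarity formula is this
  package's choice: bounded, zero for identical terms, rewarding
  specific shared ancestry.  Notably, an identical-term edge always
  weighs 0 under any such measure, so a network in which every gene
  selects the same term scores exactly 0 — published analyses of this
  kind sometimes report small non-zero scores for such networks, which
  suggests measures in the wild may also incorporate per-product
  distances.  We keep the measure pluggable rather than guess.
* **Averaging.**  The network score is the unweighted arithmetic mean
  over scorable edges; isolated annotated nodes contribute nothing.
* **Config file format.**  The CLI merges a YAML file under its flags
  (flags win); YAML is the configuration lingua franca of the R
  ecosystem.

## Limitations

* One namespace per run; no `part_of`/`regulates` closure (a config
  flag could add `part_of` later, at the cost of the depth-monotonicity
  argument).
* Exact search is exponential in the number of genes; beyond the cap
  the greedy answer is an upper bound with no optimality certificate.
* No identifier mapping: network node names must match the annotation
  file's gene keys verbatim.
* Ancestor sets are materialised per term, which is comfortable for
  pathway-scale ontology slices but memory-hungry for a full 30k-term
  namespace.
```{r example}
cfg <- synth_config(n_genes = 6, cohesion = 1, seed = 9)
dag <- random_dag(cfg)
ann <- cohesive_annotations(dag, cfg)
genes <- names(ann$store$genes)
net <- gene_network(genes[-6], genes[-1])
gfd_score(net, ann$store, dag)
```
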