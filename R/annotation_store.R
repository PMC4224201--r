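# Annotation store: gene -> gene products -> GO term sets for one
# namespace, loaded from GAF 2.x or a 3-column TSV.

aspect_letter <- c(biological_process = "P",
                   molecular_function = "F",
                   cellular_component = "C")

# Shared builder.  `rows` is a data.frame(gene, product, term); terms
# absent from the DAG are dropped and counted; everything is stored as
# deduplicated, sorted sequences so iteration order is deterministic
# and loading is independent of input row order.
new_annotation_store <- function(rows, dag,
                                 n_skipped_not = 0L,
                                 n_skipped_aspect = 0L,
                                 n_skipped_evidence = 0L) {
  rows <- rows[nzchar(rows$gene) & nzchar(rows$product), , drop = FALSE]
  known <- rows$term %in% dag$ids
  n_dropped_terms <- sum(!known)
  rows <- rows[known, , drop = FALSE]
  rows <- unique(rows)

  genes <- lapply(
    split(rows[c("product", "term")], rows$gene),
    function(df) lapply(split(df$term, df$product),
                        function(tt) sort(unique(tt)))
  )
  cand <- lapply(genes, function(pp) sort(unique(unlist(pp, use.names = FALSE))))

  structure(list(
    genes = genes,
    candidates = cand,
    namespace = dag$namespace,
    n_dropped_terms = n_dropped_terms,
    n_skipped_not = n_skipped_not,
    n_skipped_aspect = n_skipped_aspect,
    n_skipped_evidence = n_skipped_evidence
  ), class = "annotation_store")
}

#' @export
print.annotation_store <- function(x, ...) {
  cat(sprintf("<annotation_store> %d genes, namespace %s (%d unknown terms dropped)\n",
              length(x$genes), x$namespace, x$n_dropped_terms))
  invisible(x)
}

#' Load gene annotations from a GAF 2.x file
#'
#' Reads a GO Annotation File (tab-separated, 17 columns, `!` comment
#' lines) and keeps the rows matching the DAG's namespace.  Rows whose
#' qualifier contains `NOT` are skipped, as are rows whose aspect column
#' (P/F/C) does not match the DAG and rows whose evidence code is listed
#' in `exclude_evidence`.  Terms absent from the DAG (e.g. obsolete or
#' from another namespace) are dropped with a count.
#'
#' @param path GAF 2.1/2.2 file, plain or gzipped.
#' @param dag A `go_dag`; its namespace selects the aspect.
#' @param gene_key Which column identifies the gene: the DB Object
#'   Symbol (default) or the DB Object ID.
#' @param exclude_evidence Character vector of evidence codes to skip
#'   (e.g. `"IEA"`); none are excluded by default.
#' @return An `annotation_store`.
#' @export
load_gaf <- function(path, dag, gene_key = c("symbol", "id"),
                     exclude_evidence = character(0)) {
  gene_key <- match.arg(gene_key)
  lines <- read_text_lines(path)
  want_aspect <- aspect_letter[[dag$namespace]]

  gene <- character(0); product <- character(0); term <- character(0)
  n_not <- 0L; n_aspect <- 0L; n_evid <- 0L
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(line) || startsWith(line, "!")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L) {
      gfd_error("gfdnet_format_error",
                sprintf("%s line %d: expected >= 15 tab-separated GAF columns, got %d",
                        path, i, length(f)))
    }
    qualifiers <- strsplit(f[4L], "|", fixed = TRUE)[[1L]]
    if ("NOT" %in% qualifiers) { n_not <- n_not + 1L; next }
    if (f[9L] != want_aspect) { n_aspect <- n_aspect + 1L; next }
    if (f[7L] %in% exclude_evidence) { n_evid <- n_evid + 1L; next }
    gene <- c(gene, if (gene_key == "symbol") f[3L] else f[2L])
    product <- c(product, f[2L])
    term <- c(term, f[5L])
  }
  new_annotation_store(
    data.frame(gene = gene, product = product, term = term,
               stringsAsFactors = FALSE),
    dag,
    n_skipped_not = n_not, n_skipped_aspect = n_aspect,
    n_skipped_evidence = n_evid
  )
}

#' Load gene annotations from a 3-column TSV
#'
#' Columns are `gene`, `product`, `go_id` (tab-separated; an optional
#' header row is detected by its third field not being a GO accession).
#' Same semantics as [load_gaf()] without qualifier/aspect filtering:
#' unknown terms are dropped with a count, duplicate rows are collapsed.
#'
#' @inheritParams load_gaf
#' @return An `annotation_store`.
#' @export
load_tsv <- function(path, dag) {
  lines <- read_text_lines(path)
  lines_idx <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  gene <- character(0); product <- character(0); term <- character(0)
  first <- TRUE
  for (i in lines_idx) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      gfd_error("gfdnet_format_error",
                sprintf("%s line %d: expected 3 tab-separated columns, got %d",
                        path, i, length(f)))
    }
    if (first && !is_go_accession(f[3L])) { first <- FALSE; next }  # header
    first <- FALSE
    gene <- c(gene, f[1L]); product <- c(product, f[2L]); term <- c(term, f[3L])
  }
  new_annotation_store(
    data.frame(gene = gene, product = product, term = term,
               stringsAsFactors = FALSE),
    dag
  )
}

#' Candidate GO terms of a gene
#'
#' The union of all the gene's products' terms, deduplicated and sorted
#' by accession.  An unknown or unannotated gene yields an empty vector
#' (a valid answer, not an error).
#'
#' @param store An `annotation_store`.
#' @param gene_id Gene identifier as it appears in the network file.
#' @return Sorted character vector of GO accessions (possibly empty).
#' @export
candidates <- function(store, gene_id) {
  store$candidates[[gene_id]] %||% character(0)
}
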