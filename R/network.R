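# The bipartite gene-disease network (the "diseasome"): construction, degree
# tables, the collagen sub-diseasome, shared-disease clustering of genes, and
# matrisome screening of protein-protein interaction pair lists.

#' Build the bipartite gene-disease network
#'
#' Nodes are genes and diseases; each unique `(gene, disease)` association
#' is one edge. The two sides are typed, so the same string can never occur
#' both as a gene and as a disease: a record whose gene symbol equals its
#' (normalized) disease name is self-contradictory and is rejected and
#' counted. Duplicated associations collapse, so construction is idempotent.
#'
#' @param associations Tibble with `gene` and `disease` columns (normalized,
#'   as the readers produce).
#' @return An object of class `diseasome`: a list with `edges` (unique pair
#'   tibble), `genes`, `diseases`, `n_rejected`, and an igraph
#'   representation in `graph`.
#' @export
build_bipartite <- function(associations) {
  df <- as_tibble(associations)
  if (nrow(df) == 0) {
    df <- tibble(gene = character(), disease = character())
  }
  bad <- df$gene == toupper(df$disease) & !is.na(df$gene)
  n_rejected <- sum(bad)
  edges <- dplyr::distinct(df[!bad, c("gene", "disease")])
  genes <- sort(unique(edges$gene))
  diseases <- sort(unique(edges$disease))
  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(genes) + length(diseases) > 0) {
    g <- igraph::add_vertices(g, length(genes) + length(diseases),
                              name = c(paste0("g:", genes), paste0("d:", diseases)),
                              type = rep(c(FALSE, TRUE), c(length(genes), length(diseases))))
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(g, rbind(match(paste0("g:", edges$gene),
                                            igraph::V(g)$name),
                                      match(paste0("d:", edges$disease),
                                            igraph::V(g)$name)))
    }
  }
  structure(
    list(edges = edges, genes = genes, diseases = diseases,
         n_rejected = n_rejected, graph = g),
    class = "diseasome"
  )
}

#' @export
print.diseasome <- function(x, ...) {
  cat("Bipartite diseasome: ", length(x$genes), " genes, ",
      length(x$diseases), " diseases, ", nrow(x$edges), " associations\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.diseasome <- function(x, ...) {
  x$edges
}

#' @export
glance.diseasome <- function(x, ...) {
  tibble(n_genes = length(x$genes), n_diseases = length(x$diseases),
         n_edges = nrow(x$edges), n_rejected = x$n_rejected)
}

#' Degree tables of the diseasome
#'
#' `genes_per_disease()` counts, for each disease, how many genes it is
#' linked to; `diseases_per_gene()` the converse. Both satisfy the handshake
#' identity: either degree column sums to the edge count.
#'
#' @param graph A `diseasome` from [build_bipartite()].
#' @return A tibble `(disease, degree)` or `(gene, degree)` sorted by
#'   descending degree, ties alphabetical.
#' @export
genes_per_disease <- function(graph) {
  out <- dplyr::count(graph$edges, .data$disease, name = "degree")
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$disease)
}

#' @rdname genes_per_disease
#' @export
diseases_per_gene <- function(graph) {
  out <- dplyr::count(graph$edges, .data$gene, name = "degree")
  dplyr::arrange(out, dplyr::desc(.data$degree), .data$gene)
}

#' Extract the collagen sub-diseasome
#'
#' Restricts the network to genes in the catalog's collagen category and to
#' the diseases that keep at least one edge. The operation is idempotent.
#'
#' @param graph A `diseasome`.
#' @param catalog A matrisome catalog from [read_matrisome_list()].
#' @return A `diseasome` over collagen genes only.
#' @export
collagen_subnetwork <- function(graph, catalog) {
  collagens <- catalog$symbol[catalog$category == "collagens"]
  build_bipartite(graph$edges[graph$edges$gene %in% collagens, , drop = FALSE])
}

#' Cluster genes by shared disease neighborhoods
#'
#' Genes whose disease sets overlap belong together: similarity between two
#' genes is the Jaccard index of their disease neighbor sets, and clusters
#' are formed by average-linkage agglomerative clustering on the Jaccard
#' distance, cut where between-cluster similarity falls below `cut`. Genes
#' with identical disease sets always co-cluster (distance 0); genes sharing
#' no disease with anything else end up as singletons. Genes are processed
#' in sorted order, so the result is invariant to input ordering.
#'
#' @param graph A `diseasome` (non-empty).
#' @param cut Similarity threshold in (0, 1); clusters are cut at Jaccard
#'   distance `1 - cut`.
#' @return A tibble `(gene, cluster)` with deterministic integer cluster
#'   ids (clusters numbered by their first gene in sorted order).
#' @export
shared_disease_clusters <- function(graph, cut = 0.5) {
  if (length(graph$genes) == 0) {
    abort("cannot cluster an empty diseasome", class = "ecm_domain_error")
  }
  genes <- graph$genes
  if (length(genes) == 1) {
    return(tibble(gene = genes, cluster = 1L))
  }
  inc <- table(factor(graph$edges$gene, levels = genes),
               factor(graph$edges$disease, levels = graph$diseases))
  inc <- (unclass(inc) > 0) * 1L
  inter <- inc %*% t(inc)
  sizes <- rowSums(inc)
  uni <- outer(sizes, sizes, "+") - inter
  jac <- ifelse(uni > 0, inter / uni, 0)
  d <- as.dist(1 - jac)
  hc <- hclust(d, method = "average")
  memb <- cutree(hc, h = 1 - cut)
  # renumber clusters by first occurrence over sorted gene names
  ids <- match(memb, unique(memb[order(genes)]))
  tibble(gene = genes, cluster = as.integer(ids))
}

#' Screen protein-protein interaction pairs for matrisome-matrisome edges
#'
#' Keeps the pairs whose both endpoints are matrisome genes and counts the
#' distinct genes involved.
#'
#' @param pairs Canonicalized pair tibble from [read_ppi_table()].
#' @param catalog A matrisome catalog.
#' @return A list with `pairs` (the surviving tibble), `n_pairs` and
#'   `n_genes` (distinct symbols over surviving pairs).
#' @export
matrisome_ppi_pairs <- function(pairs, catalog) {
  df <- as_tibble(pairs)
  keep <- df$gene_a %in% catalog$symbol & df$gene_b %in% catalog$symbol
  surv <- df[keep, , drop = FALSE]
  list(pairs = surv, n_pairs = nrow(surv),
       n_genes = length(unique(c(surv$gene_a, surv$gene_b))))
}
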