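# Shared helpers: in-code fixture writers and independent oracles.

write_tmp_tsv <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  readr::write_tsv(df, path, progress = FALSE, na = "")
  path
}

tiny_catalog <- function() {
  tibble::tibble(
    symbol = c("COL2A1", "COL6A1", "FBN1", "ACAN", "MMP2", "TNC"),
    division = c("core_matrisome", "core_matrisome", "core_matrisome",
                 "core_matrisome", "matrisome_associated", "core_matrisome"),
    category = c("collagens", "collagens", "glycoproteins", "proteoglycans",
                 "ecm_regulators", "glycoproteins")
  )
}

# Independent clustering oracle: threshold pairwise Jaccard similarity of
# disease neighbor sets, then take connected components.
oracle_clusters <- function(edges, cut) {
  genes <- sort(unique(edges$gene))
  sets <- lapply(genes, function(g) unique(edges$disease[edges$gene == g]))
  n <- length(genes)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      jac <- length(intersect(sets[[i]], sets[[j]])) /
        length(union(sets[[i]], sets[[j]]))
      adj[i, j] <- jac >= cut
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  tibble::tibble(gene = genes, cluster = as.integer(memb))
}

# Canonical form of a partition: sorted list of sorted member sets, so two
# partitions can be compared independent of cluster numbering.
partition_sets <- function(assign) {
  sets <- split(assign$gene, assign$cluster)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[`, "", 1))])
}
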