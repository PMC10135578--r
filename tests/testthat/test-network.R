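stickler_edges <- function() {
  tibble::tibble(gene = collagenopathy_genes()$stickler,
                 disease = "stickler syndrome")
}

test_that("bipartite construction deduplicates and rejects contradictions", {
  assoc <- tibble::tibble(
    gene = c("COL2A1", "COL2A1", "FBN1", "XYZZY"),
    disease = c("stickler syndrome", "stickler syndrome", "marfan syndrome",
                "xyzzy")
  )
  net <- build_bipartite(assoc)
  expect_equal(nrow(net$edges), 2)
  expect_equal(net$n_rejected, 1)
  expect_equal(glance(net)$n_genes, 2)
  # idempotent on duplicated input
  net2 <- build_bipartite(dplyr::bind_rows(assoc, assoc))
  expect_equal(net2$edges, net$edges)
  # empty input gives an empty graph
  empty <- build_bipartite(assoc[0, ])
  expect_equal(glance(empty)$n_edges, 0)
  expect_equal(length(empty$genes), 0)
})

test_that("planted biclique gives closed-form node and edge counts", {
  g <- sprintf("GENE%02d", 1:5)
  d <- sprintf("disease %02d", 1:7)
  net <- build_bipartite(tidyr::expand_grid(gene = g, disease = d))
  expect_equal(length(net$genes), 5)
  expect_equal(length(net$diseases), 7)
  expect_equal(nrow(net$edges), 35)
  expect_equal(igraph::vcount(net$graph), 12)
  expect_equal(igraph::ecount(net$graph), 35)
  expect_true(igraph::is_bipartite(net$graph))
})

test_that("degree tables satisfy the handshake identity", {
  withr::with_seed(37, {
    assoc <- dplyr::distinct(tibble::tibble(
      gene = sample(sprintf("G%02d", 1:15), 60, replace = TRUE),
      disease = sample(sprintf("d %02d", 1:12), 60, replace = TRUE)
    ))
    net <- build_bipartite(assoc)
    gpd <- genes_per_disease(net)
    dpg <- diseases_per_gene(net)
    expect_equal(sum(gpd$degree), nrow(net$edges))
    expect_equal(sum(dpg$degree), nrow(net$edges))
  })
})

test_that("printed collagenopathy fixtures give degrees six and four", {
  fx <- write_example_fixtures(tempfile())
  catalog <- read_matrisome_list(fx[["catalog"]])
  st <- build_bipartite(read_association_table(fx[["stickler"]]))
  ul <- build_bipartite(read_association_table(fx[["ullrich"]]))
  expect_equal(genes_per_disease(st)$degree[
    genes_per_disease(st)$disease == "stickler syndrome"], 6L)
  expect_equal(genes_per_disease(ul)$degree[1], 4L)
  expect_equal(diseases_per_gene(st)$degree, rep(1L, 6))
})

test_that("collagen subnetwork keeps collagen edges only and is idempotent", {
  cat <- tiny_catalog()
  assoc <- tibble::tibble(
    gene = c("COL2A1", "COL6A1", "FBN1", "MMP2"),
    disease = c("d one", "d one", "d two", "d three")
  )
  net <- build_bipartite(assoc)
  sub <- collagen_subnetwork(net, cat)
  expect_setequal(sub$genes, c("COL2A1", "COL6A1"))
  expect_equal(sub$diseases, "d one")
  sub2 <- collagen_subnetwork(sub, cat)
  expect_equal(sub2$edges, sub$edges)
  # graph with no collagens gives an empty subnetwork
  none <- collagen_subnetwork(build_bipartite(assoc[3:4, ]), cat)
  expect_equal(nrow(none$edges), 0)
})

test_that("genes with identical or disjoint disease sets cluster as required", {
  assoc <- tibble::tibble(
    gene = c("A1", "A1", "A2", "A2", "B1"),
    disease = c("d1", "d2", "d1", "d2", "d9")
  )
  net <- build_bipartite(assoc)
  cl <- shared_disease_clusters(net, cut = 0.3)
  ids <- setNames(cl$cluster, cl$gene)
  expect_equal(ids[["A1"]], ids[["A2"]])
  expect_false(ids[["A1"]] == ids[["B1"]])
  # identical sets co-cluster at any cut below 1
  cl99 <- shared_disease_clusters(net, cut = 0.99)
  ids99 <- setNames(cl99$cluster, cl99$gene)
  expect_equal(ids99[["A1"]], ids99[["A2"]])
  expect_error(shared_disease_clusters(build_bipartite(assoc[0, ])),
               class = "ecm_domain_error")
})

test_that("clustering is invariant to input ordering", {
  withr::with_seed(43, {
    assoc <- dplyr::distinct(tibble::tibble(
      gene = sample(sprintf("G%02d", 1:10), 40, replace = TRUE),
      disease = sample(sprintf("d%02d", 1:8), 40, replace = TRUE)
    ))
    c1 <- shared_disease_clusters(build_bipartite(assoc), cut = 0.4)
    c2 <- shared_disease_clusters(build_bipartite(assoc[sample(nrow(assoc)), ]),
                                  cut = 0.4)
    expect_equal(c1, c2)
  })
})

test_that("planted separated blocks match the brute-force oracle", {
  withr::with_seed(47, {
    # two gene blocks sharing no diseases; within-block Jaccard >= 0.6
    block <- function(genes, diseases, common) {
      dplyr::bind_rows(lapply(genes, function(g) {
        tibble::tibble(gene = g, disease = c(common,
                                             sample(diseases, 1)))
      }))
    }
    b1 <- block(sprintf("A%d", 1:4), sprintf("ad%d", 1:2),
                sprintf("acommon%d", 1:4))
    b2 <- block(sprintf("B%d", 1:3), sprintf("bd%d", 1:2),
                sprintf("bcommon%d", 1:4))
    assoc <- dplyr::distinct(dplyr::bind_rows(b1, b2))
    net <- build_bipartite(assoc)
    cl <- shared_disease_clusters(net, cut = 0.5)
    expect_equal(length(unique(cl$cluster)), 2)
    expect_equal(partition_sets(cl), partition_sets(oracle_clusters(assoc, 0.5)))
  })
})

test_that("matrisome PPI screening keeps pairs with both endpoints in catalog", {
  cat <- tiny_catalog()
  pairs <- tibble::tibble(gene_a = c("COL2A1", "COL2A1", "ACAN"),
                          gene_b = c("FBN1", "TP53", "MMP2"))
  mm <- matrisome_ppi_pairs(pairs, cat)
  expect_equal(mm$n_pairs, 2)
  expect_equal(mm$n_genes, 4)
  expect_equal(matrisome_ppi_pairs(pairs[0, ], cat)$n_pairs, 0)
})
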