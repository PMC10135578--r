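test_that("annotate_genes filters to catalog genes and tags them", {
  records <- tibble::tibble(gene = c("COL2A1", "TP53"), x = 1:2)
  out <- annotate_genes(records, tiny_catalog())
  expect_equal(nrow(out), 1)
  expect_equal(out$gene, "COL2A1")
  expect_equal(out$division, "core_matrisome")
  expect_equal(out$category, "collagens")
  # no overlap is empty output, not an error
  none <- annotate_genes(tibble::tibble(gene = "TP53"), tiny_catalog())
  expect_equal(nrow(none), 0)
  expect_error(annotate_genes(records, tiny_catalog()[0, ]),
               class = "ecm_config_error")
})

test_that("annotate_genes is an idempotent order-preserving filter", {
  withr::with_seed(3, {
    records <- tibble::tibble(
      gene = sample(c(tiny_catalog()$symbol, "TP53", "BRCA1"), 50, replace = TRUE),
      id = 1:50
    )
    once <- annotate_genes(records, tiny_catalog())
    twice <- annotate_genes(once, tiny_catalog())
    expect_equal(once, twice)
    expect_true(all(diff(once$id) > 0))
    expect_true(all(once$gene %in% tiny_catalog()$symbol))
  })
})

test_that("planted matrisome fraction is recovered exactly", {
  withr::with_seed(5, {
    cat <- tiny_catalog()
    n_in <- 120
    n_out <- 80
    records <- tibble::tibble(
      gene = c(sample(cat$symbol, n_in, replace = TRUE),
               sample(c("TP53", "MYC", "EGFR"), n_out, replace = TRUE))
    )
    records <- records[sample(nrow(records)), , drop = FALSE]
    out <- annotate_genes(records, cat)
    expect_equal(nrow(out), n_in)
  })
})

test_that("composition summary computes half-up percentages and conserves counts", {
  withr::with_seed(9, {
    cat <- tiny_catalog()
    genes <- cat[c(1, 3, 5), ]
    cs <- composition_summary(genes, nrow(cat))
    expect_equal(cs$total_genes, 3)
    expect_equal(cs$fraction_of_catalog, 50.0)
    expect_equal(sum(cs$by_division$n_genes), cs$total_genes)
    joined <- dplyr::left_join(cs$by_category,
                               dplyr::rename(cs$by_division, div_n = n_genes),
                               by = "division")
    per_div <- dplyr::summarise(dplyr::group_by(cs$by_category, division),
                                n = sum(n_genes), .groups = "drop")
    expect_equal(per_div$n,
                 cs$by_division$n_genes[match(per_div$division,
                                              cs$by_division$division)])
    # full catalog is exactly 100.0; empty set is 0 with zero counts
    expect_equal(composition_summary(cat, nrow(cat))$fraction_of_catalog, 100.0)
    empty <- composition_summary(cat[0, ], nrow(cat))
    expect_equal(empty$total_genes, 0)
    expect_equal(empty$fraction_of_catalog, 0.0)
  })
})

test_that("composition glance/tidy expose the summary", {
  cs <- composition_summary(tiny_catalog()[1:2, ], 6)
  g <- glance(cs)
  expect_equal(g$total_genes, 2)
  expect_equal(g$fraction_of_catalog, 33.3)
  expect_s3_class(tidy(cs), "tbl_df")
})

test_that("disease_matrisome merges sources with pair-level dedup", {
  cat <- tiny_catalog()
  s1 <- tibble::tibble(gene = c("COL2A1", "FBN1"),
                       disease = c("stickler syndrome", "marfan syndrome"),
                       source = "clinvar_like")
  s2 <- tibble::tibble(gene = c("COL2A1", "ACAN"),
                       disease = c("stickler syndrome", "osteoarthritis"),
                       source = "monarch_like")
  dm <- disease_matrisome(s1, s2, catalog = cat)
  expect_equal(dm$n_pairs, 3)
  expect_equal(dm$n_genes, 3)
  expect_equal(dm$n_diseases, 3)
  # merging is commutative at the unique-pair level
  dm2 <- disease_matrisome(s2, s1, catalog = cat)
  expect_equal(dm2$n_pairs, dm$n_pairs)
  expect_setequal(paste(dm$associations$gene, dm$associations$disease),
                  paste(dm2$associations$gene, dm2$associations$disease))
})

test_that("fully crossed gene x disease sets give closed-form counts", {
  cat <- tiny_catalog()
  g <- cat$symbol[1:4]
  d <- sprintf("crossed disease %d", 1:7)
  crossed <- tidyr::expand_grid(gene = g, disease = d)
  crossed$source <- "curated"
  dm <- disease_matrisome(crossed, catalog = cat)
  expect_equal(dm$n_pairs, length(g) * length(d))
  expect_equal(dm$n_genes, length(g))
  expect_equal(dm$n_diseases, length(d))
})
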