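test_that("matrisome reader normalizes, deduplicates and infers division", {
  path <- write_tmp_tsv(tibble::tibble(
    symbol = c("col2a1", "COL2A1 ", "FBN1", "MMP2", "ACAN"),
    division = c("Core matrisome", NA, NA, NA, NA),
    category = c("Collagens", "Collagens", "ECM Glycoproteins",
                 "ECM Regulators", "Proteoglycans")
  ))
  cat <- read_matrisome_list(path)
  expect_equal(nrow(cat), 4)
  expect_setequal(cat$symbol, c("COL2A1", "FBN1", "MMP2", "ACAN"))
  expect_equal(cat$division[cat$symbol == "COL2A1"], "core_matrisome")
  expect_equal(cat$division[cat$symbol == "MMP2"], "matrisome_associated")
  rep <- load_report(cat)
  expect_equal(rep$rows_in, rep$records_out + rep$dropped + rep$rejected)
  expect_equal(rep$dropped_duplicate, 1)
})

test_that("matrisome reader rejects bad files with named errors", {
  no_col <- write_tmp_tsv(tibble::tibble(symbol = "A", other = "x"))
  expect_error(read_matrisome_list(no_col), class = "ecm_format_error")
  expect_error(read_matrisome_list(no_col), "category")
  conflict <- write_tmp_tsv(tibble::tibble(
    symbol = c("COL2A1", "COL2A1"),
    category = c("Collagens", "Proteoglycans")
  ))
  expect_error(read_matrisome_list(conflict), class = "ecm_conflict_error")
  expect_error(read_matrisome_list(conflict), "COL2A1")
  expect_error(read_matrisome_list(tempfile()), class = "ecm_io_error")
})

test_that("variant reader drops blank rows, collapses duplicates, reports both counts", {
  path <- write_tmp_tsv(tibble::tibble(
    gene = c("COL2A1", "", "FBN1", "FBN1"),
    variant_id = c("rs1", "rs2", "rs3", "rs3"),
    protein_change = c("p.Gly661Arg", NA, "p.Arg123Cys", "p.Arg123Cys"),
    condition = c("Stickler syndrome", "x", "Marfan syndrome", "Marfan syndrome")
  ))
  v <- read_variant_table(path)
  expect_equal(nrow(v), 2)
  rep <- load_report(v)
  expect_equal(rep$dropped_missing, 1)
  expect_equal(rep$dropped_duplicate, 1)
  expect_equal(rep$unique_variant_ids, 2)
  expect_equal(rep$rows_in, rep$records_out + rep$dropped + rep$rejected)
})

test_that("absent protein_change column yields NA protein changes", {
  path <- write_tmp_tsv(tibble::tibble(
    gene = "COL2A1", variant_id = "rs1", condition = "Stickler syndrome"
  ))
  v <- read_variant_table(path)
  expect_true(all(is.na(v$protein_change)))
})

test_that("phewas reader parses scientific notation and rejects invalid p", {
  path <- write_tmp_tsv(tibble::tibble(
    snp = c("rs1", "rs2", "rs3", "rs4"),
    gene = c("TNXB", "TNXB", "EYS", "EYS"),
    phenotype = c("a", "b", "c", "d"),
    category = "x",
    p = c("5e-8", "0.03", "1.7", "-1")
  ))
  ph <- read_phewas_table(path)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$p[ph$snp == "rs1"], 5e-8)
  expect_equal(load_report(ph)$rejected, 2)
})

test_that("ppi reader canonicalizes unordered pairs and rejects self-pairs", {
  path <- write_tmp_tsv(tibble::tibble(
    gene_a = c("FBN1", "COL1A1", "TNC"),
    gene_b = c("COL1A1", "FBN1", "TNC")
  ))
  ppi <- read_ppi_table(path)
  expect_equal(nrow(ppi), 1)
  expect_equal(ppi$gene_a, "COL1A1")
  expect_equal(ppi$gene_b, "FBN1")
  expect_equal(load_report(ppi)$rejected, 1)
})

test_that("association writer sorts stably and round-trips", {
  assoc <- tibble::tibble(
    gene = c("FBN1", "COL2A1", "ACAN"),
    disease = c("marfan syndrome", "stickler syndrome", "osteoarthritis"),
    source = "curated"
  )
  path <- tempfile(fileext = ".tsv")
  write_association_table(assoc, path)
  back <- read_association_table(path)
  expect_equal(back$gene, c("ACAN", "COL2A1", "FBN1"))
  expect_setequal(paste(back$gene, back$disease), paste(assoc$gene, assoc$disease))
  # empty input gives a header-only file
  p2 <- tempfile(fileext = ".tsv")
  write_association_table(assoc[0, ], p2)
  expect_equal(readLines(p2), "gene\tdisease\tsource")
})

test_that("readers are idempotent and dedup is order-independent", {
  withr::with_seed(11, {
    assoc <- tibble::tibble(
      gene = sample(c("COL2A1", "FBN1", "ACAN"), 30, replace = TRUE),
      disease = sample(c("d one", "d two", "d three"), 30, replace = TRUE),
      source = "curated"
    )
    p1 <- write_tmp_tsv(assoc)
    p2 <- write_tmp_tsv(assoc[sample(nrow(assoc)), ])
    a1 <- read_association_table(p1)
    a2 <- read_association_table(p2)
    key <- function(x) sort(paste(x$gene, x$disease, x$source))
    expect_equal(key(a1), key(a2))
    # read -> write -> read is the identity
    p3 <- tempfile(fileext = ".tsv")
    write_association_table(a1, p3)
    a3 <- read_association_table(p3)
    expect_equal(key(a3), key(a1))
  })
})

test_that("synthetic duplicate planting is recovered by set-based dedup", {
  withr::with_seed(7, {
    base <- tibble::tibble(
      gene = sprintf("G%02d", 1:40),
      variant_id = sprintf("rs%03d", 1:40),
      protein_change = NA_character_,
      condition = sprintf("disease %02d", sample(1:8, 40, replace = TRUE))
    )
    d <- 6
    dup <- base[sample(40, d), ]
    tbl <- dplyr::slice_sample(dplyr::bind_rows(base, dup), prop = 1)
    # independent oracle: count of distinct full rows
    oracle_n <- nrow(unique(as.data.frame(tbl)))
    v <- read_variant_table(write_tmp_tsv(tbl))
    expect_equal(nrow(v), oracle_n)
    expect_equal(nrow(v), nrow(tbl) - d)
  })
})
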