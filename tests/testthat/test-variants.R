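test_that("protein-change parser handles both dialects and event notations", {
  p <- parse_protein_change(c(
    "p.Gly661Arg", "p.Gly852Arg", "G661R", "p.GLY325ARG",
    "p.Gly661=", "p.Arg123fs", "p.Val7del", "p.Ala310dup", "p.Trp24Ter",
    "W24*", "p.Ter110GlnextTer17", "nonsense", "", NA
  ))
  expect_equal(p$status[1:4], rep("missense", 4))
  expect_equal(p$ref[1], "Gly")
  expect_equal(p$position[1:2], c(661L, 852L))
  expect_equal(p$alt[2], "Arg")
  expect_equal(p$canonical[3], "p.Gly661Arg")
  expect_equal(p$canonical[4], "p.Gly325Arg")
  expect_equal(p$status[5:11], rep("not_missense", 7))
  expect_equal(p$subtype[5], "synonymous")
  expect_equal(p$subtype[6], "frameshift")
  expect_equal(p$subtype[9], "stop_gain")
  expect_equal(p$subtype[10], "stop_gain")
  expect_equal(p$status[12:14], rep("unparseable", 3))
})

test_that("parse -> render -> parse is the identity on missense outcomes", {
  withr::with_seed(21, {
    aa <- amino_acids()$code3[1:20]
    ref <- sample(aa, 200, replace = TRUE)
    alt <- sample(aa, 200, replace = TRUE)
    keep <- ref != alt
    txt <- render_protein_change(ref[keep], seq_len(sum(keep)), alt[keep])
    p1 <- parse_protein_change(txt)
    expect_true(all(p1$status == "missense"))
    p2 <- parse_protein_change(p1$canonical)
    expect_equal(p2$ref, p1$ref)
    expect_equal(p2$alt, p1$alt)
    expect_equal(p2$position, p1$position)
    expect_equal(p2$canonical, p1$canonical)
  })
})

test_that("substitution matrix counts one increment per missense record", {
  rec <- tibble::tibble(
    gene = c("COL3A1", "COL4A5", "COL4A5", "FBN1", "COL3A1"),
    protein_change = c("p.Gly661Arg", "p.Gly852Arg", "p.Gly325Arg",
                       "p.Arg123fs", NA)
  )
  m <- substitution_matrix(rec)
  expect_equal(sum(m), 3)
  expect_equal(m["Gly", "Arg"], 3L)
  expect_true(all(diag(unclass(m)) == 0))
  # gene filter restricts contributing records
  m2 <- substitution_matrix(rec, genes = "COL3A1")
  expect_equal(sum(m2), 1)
  # stop gains excluded by default, counted under Ter on request
  rec3 <- tibble::tibble(gene = "COL1A1",
                         protein_change = c("p.Gly661Arg", "p.Trp24Ter"))
  expect_equal(sum(substitution_matrix(rec3)), 1)
  m3 <- substitution_matrix(rec3, include_stop_gain = TRUE)
  expect_equal(sum(m3), 2)
  expect_equal(m3["Trp", "Ter"], 1L)
  # empty input gives the all-zero matrix
  expect_equal(sum(substitution_matrix(rec[0, ])), 0)
})

test_that("matrix total is invariant under input shuffling", {
  withr::with_seed(31, {
    dist <- default_substitution_distribution()
    idx <- sample(nrow(dist), 300, replace = TRUE, prob = dist$prob)
    rec <- tibble::tibble(
      gene = "COL1A1",
      protein_change = render_protein_change(dist$ref[idx], 1:300, dist$alt[idx])
    )
    m1 <- substitution_matrix(rec)
    m2 <- substitution_matrix(rec[sample(nrow(rec)), ])
    expect_identical(unclass(m1), unclass(m2))
    expect_equal(sum(m1), 300)
  })
})

test_that("rankings are descending with alphabetical tie-break", {
  rec <- tibble::tibble(
    gene = "COL1A1",
    protein_change = c(rep("p.Gly661Arg", 6), rep("p.Gly661Asp", 3),
                       rep("p.Pro10Leu", 4), rep("p.Arg20Cys", 3))
  )
  m <- substitution_matrix(rec)
  rs <- rank_substituted(m)
  expect_equal(rs$ref[1:3], c("Gly", "Pro", "Arg"))
  rt <- rank_targets(m, "Gly")
  expect_equal(rt$alt[1:2], c("Arg", "Asp"))
  expect_equal(rank_targets(m, "G"), rt)
  # all-zero matrix: ties broken alphabetically by three-letter code
  zero <- substitution_matrix(rec[0, ])
  expect_equal(rank_substituted(zero)$ref[1:3], c("Ala", "Arg", "Asn"))
  expect_error(rank_targets(m, "Zzz"), class = "ecm_domain_error")
})

test_that("planted substitution distribution is recovered from the emission log", {
  withr::with_seed(41, {
    dist <- default_substitution_distribution()
    n <- 2000
    idx <- sample(nrow(dist), n, replace = TRUE, prob = dist$prob)
    rec <- tibble::tibble(
      gene = "COL1A1",
      protein_change = render_protein_change(
        dist$ref[idx], sample(1:1500, n, replace = TRUE), dist$alt[idx])
    )
    m <- substitution_matrix(rec)
    # oracle: recount the emission log directly
    log_counts <- table(paste(dist$ref[idx], dist$alt[idx]))
    for (key in names(log_counts)) {
      parts <- strsplit(key, " ")[[1]]
      expect_equal(m[parts[1], parts[2]], as.integer(log_counts[[key]]))
    }
    expect_equal(sum(m), n)
    expect_equal(rank_substituted(m)$ref[1], "Gly")
    top_cell <- tidy(m)[which.max(tidy(m)$n), ]
    expect_equal(c(top_cell$ref, top_cell$alt), c("Gly", "Arg"))
  })
})

test_that("triplet positions follow Gly-X-Y periodicity", {
  tp <- triplet_position(1:30, helix_start = 1, offset = 0, glycine_slot = 1)
  # brute force over positions 1..30
  expect_equal(tp$triplet_slot, rep(1:3, 10))
  expect_equal(tp$position[tp$is_glycine_slot], seq(1, 28, by = 3))
  # positions p and p+3 share a slot
  withr::with_seed(13, {
    p <- sample(5:500, 50)
    a <- triplet_position(p, helix_start = 4, offset = 1)
    b <- triplet_position(p + 3, helix_start = 4, offset = 1)
    expect_equal(a$triplet_slot, b$triplet_slot)
  })
  expect_equal(triplet_position(17, helix_start = 17)$triplet_slot, 1L)
  expect_error(triplet_position(3, helix_start = 10), class = "ecm_domain_error")
  expect_error(triplet_position(5, offset = 5), class = "ecm_domain_error")
})

test_that("variants per disease counts unique ids per normalized disease", {
  rec <- tibble::tibble(
    gene = "COL4A5",
    variant_id = c("rs1", "rs1", "rs2"),
    protein_change = NA_character_,
    condition = c("Alport Syndrome", " alport  syndrome", "Marfan syndrome"),
    condition_norm = normalize_disease(c("Alport Syndrome", " alport  syndrome",
                                         "Marfan syndrome"))
  )
  vpd <- variants_per_disease(rec)
  expect_equal(vpd$n_variants[vpd$disease == "alport syndrome"], 1L)
  expect_equal(nrow(vpd), 2)
  expect_equal(nrow(variants_per_disease(rec[0, ])), 0)
})

test_that("planted top disease ranks first", {
  withr::with_seed(17, {
    rec <- tibble::tibble(
      gene = "COL4A5",
      variant_id = sprintf("rs%04d", 1:300),
      protein_change = NA_character_,
      condition = c(rep("alport syndrome", 150),
                    sample(sprintf("other disease %d", 1:20), 150,
                           replace = TRUE))
    )
    vpd <- variants_per_disease(rec)
    expect_equal(vpd$disease[1], "alport syndrome")
    expect_equal(vpd$n_variants[1], 150L)
    expect_true(sum(vpd$n_variants) >= length(unique(rec$variant_id)))
  })
})
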