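# Seeded generator for every input dialect the pipeline reads, with a
# machine-readable ground-truth manifest. Every count any pipeline stage can
# compute is recorded as *realized* (not expected) in the manifest, so
# downstream checks are exact: the only randomness is in generation, all
# counting stages are deterministic.

#' Default planted substitution distribution
#'
#' Probability distribution over (ref, alt) residue pairs used for synthetic
#' missense changes: glycine carries 0.6 of the reference mass, with
#' Gly-to-Arg at 0.25 — the glycine-dominant pattern characteristic of
#' collagen disease variants, where the obligatory Gly of the Gly-X-Y repeat
#' cannot tolerate a bulkier side chain.
#'
#' @return A tibble `(ref, alt, prob)` with `prob` summing to 1.
#' @export
default_substitution_distribution <- function() {
  tibble(
    ref = c("Gly", "Gly", "Gly", "Gly",
            "Pro", "Arg", "Arg", "Asp", "Ser", "Val"),
    alt = c("Arg", "Asp", "Ser", "Val",
            "Leu", "Cys", "His", "Asn", "Leu", "Met"),
    prob = c(0.25, 0.15, 0.12, 0.08,
             0.10, 0.08, 0.07, 0.05, 0.05, 0.05)
  )
}

#' Generator configuration
#'
#' Fixes every knob of the synthetic-data generator. Defaults describe a
#' desk-scale study: a 2000-gene universe of which half (about the scale of
#' the 1027-gene published matrisome catalog) is matrisome, with matrisome
#' category proportions matching the published catalog composition
#' (44 collagens, 195 glycoproteins, 35 proteoglycans, 171 ECM-affiliated,
#' 238 ECM regulators, 344 secreted factors of 1027); 5000 variant records;
#' 10000 PheWAS hits with log-uniform p-values over (1e-12, 1); 800
#' diseases whose names embed category terms by controlled insertion; 3000
#' gene-disease associations; 150 drug links; 600 PPI pairs; 400
#' rare-disease links.
#'
#' @param seed Integer seed (mandatory).
#' @param n_genes Size of the gene universe.
#' @param matrisome_fraction Fraction of the universe in the matrisome
#'   catalog.
#' @param category_proportions Named numeric over the six matrisome
#'   categories, summing to 1.
#' @param n_variants Variant records (before planted duplicates).
#' @param duplicate_variants Exact duplicate rows appended to the variant
#'   table (collapse on read).
#' @param missense_fraction Fraction of variant records with a missense
#'   protein change.
#' @param substitution Tibble `(ref, alt, prob)` for missense changes.
#' @param n_diseases Number of synthetic diseases.
#' @param term_insertion Named probabilities (`A`, `B`, `C`) that a disease
#'   name embeds a term of each category list.
#' @param n_phewas PheWAS hit rows with valid p.
#' @param invalid_p_rows Extra PheWAS rows with p > 1 (rejected on read).
#' @param p_log10_range Range of log10(p) for the log-uniform p draw.
#' @param n_associations Gene-disease association rows drawn.
#' @param n_drugs Drug-gene link rows.
#' @param n_ppi PPI pair rows.
#' @param ppi_matrisome_fraction Fraction of PPI pairs with both endpoints
#'   matrisome.
#' @param n_rare Rare-disease association rows.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed,
                             n_genes = 2000,
                             matrisome_fraction = 0.5,
                             category_proportions = c(
                               collagens = 44, glycoproteins = 195,
                               proteoglycans = 35, ecm_affiliated = 171,
                               ecm_regulators = 238, secreted_factors = 344
                             ) / 1027,
                             n_variants = 5000,
                             duplicate_variants = 0,
                             missense_fraction = 0.7,
                             substitution = default_substitution_distribution(),
                             n_diseases = 800,
                             term_insertion = c(A = 0.20, B = 0.25, C = 0.40),
                             n_phewas = 10000,
                             invalid_p_rows = 0,
                             p_log10_range = c(-12, 0),
                             n_associations = 3000,
                             n_drugs = 150,
                             n_ppi = 600,
                             ppi_matrisome_fraction = 0.4,
                             n_rare = 400) {
  if (missing(seed) || is.null(seed)) {
    abort("seed is mandatory", class = "ecm_config_error")
  }
  fracs <- c(matrisome_fraction, missense_fraction, ppi_matrisome_fraction,
             term_insertion)
  if (any(fracs < 0 | fracs > 1)) {
    abort("all fractions must lie in [0, 1]", class = "ecm_config_error")
  }
  if (abs(sum(category_proportions) - 1) > 1e-8) {
    abort("category_proportions must sum to 1", class = "ecm_config_error")
  }
  if (!setequal(names(category_proportions), MATRISOME_CATEGORIES)) {
    abort("category_proportions must name the six matrisome categories",
          class = "ecm_config_error")
  }
  if (abs(sum(substitution$prob) - 1) > 1e-8 || any(substitution$ref == substitution$alt)) {
    abort("substitution distribution must sum to 1 with ref != alt",
          class = "ecm_config_error")
  }
  structure(as.list(environment()), class = "generator_config")
}

sample_p <- function(n, range) 10^stats::runif(n, range[1], range[2])

#' Generate all synthetic input files with planted ground truth
#'
#' Emits the seven canonical dialect files (matrisome catalog, variants,
#' PheWAS hits, associations, drugs, PPI pairs, rare-disease links) into
#' `outdir`, plus `manifest.json` recording the realized value of every
#' quantity the pipeline computes. Every stochastic choice is drawn from the
#' seeded stream, so the same config reproduces the same bytes; the manifest
#' is written last, after all data files.
#'
#' @param config A [generator_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with `files` (named paths), `manifest`, and
#'   `data` (the generated tibbles).
#' @export
generate_synthetic_data <- function(config, outdir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  terms <- default_category_terms()

  ## gene universe and matrisome catalog
  universe <- sprintf("GENE%04d", seq_len(config$n_genes))
  n_mat <- round(config$n_genes * config$matrisome_fraction)
  mat_symbols <- sort(sample(universe, n_mat))
  categories <- sample(names(config$category_proportions), n_mat,
                       replace = TRUE, prob = config$category_proportions)
  catalog <- tibble(
    symbol = mat_symbols,
    division = unname(DIVISION_FOR_CATEGORY[categories]),
    category = categories
  )

  ## diseases with controlled category-term insertion
  base <- sprintf("condition %04d", seq_len(config$n_diseases))
  ins <- vapply(c("A", "B", "C"), function(k) {
    stats::runif(config$n_diseases) < config$term_insertion[[k]]
  }, logical(config$n_diseases))
  pick_term <- function(k, hit) {
    out <- rep("", length(hit))
    out[hit] <- sample(terms[[k]], sum(hit), replace = TRUE)
    out
  }
  parts_a <- pick_term("A", ins[, "A"])
  parts_b <- pick_term("B", ins[, "B"])
  parts_c <- pick_term("C", ins[, "C"])
  disease_names <- stringr::str_squish(paste(parts_a, parts_b, parts_c, base))
  disease_truth <- tibble(
    disease = disease_names,
    in_A = ins[, "A"], in_B = ins[, "B"], in_C = ins[, "C"]
  )

  ## variant records (unique rs ids; duplicates planted on top)
  missense_n <- round(config$n_variants * config$missense_fraction)
  is_missense <- seq_len(config$n_variants) <= missense_n
  sub_idx <- sample(nrow(config$substitution), missense_n, replace = TRUE,
                    prob = config$substitution$prob)
  pchange <- rep(NA_character_, config$n_variants)
  pchange[is_missense] <- render_protein_change(
    config$substitution$ref[sub_idx],
    sample(20:1500, missense_n, replace = TRUE),
    config$substitution$alt[sub_idx]
  )
  other_forms <- c(NA, "p.Arg123fs", "p.Val7del", "p.Gly661=", "p.Trp24Ter",
                   "p.Ala310dup")
  pchange[!is_missense] <- sample(other_forms, config$n_variants - missense_n,
                                  replace = TRUE)
  variants <- tibble(
    gene = sample(universe, config$n_variants, replace = TRUE),
    variant_id = sprintf("rs%07d", sample.int(10 * config$n_variants,
                                              config$n_variants)),
    protein_change = pchange,
    condition = sample(disease_names, config$n_variants, replace = TRUE)
  )
  variants_written <- variants
  if (config$duplicate_variants > 0) {
    dup <- variants[sample.int(nrow(variants), config$duplicate_variants,
                               replace = FALSE), ]
    variants_written <- dplyr::slice_sample(dplyr::bind_rows(variants, dup),
                                            prop = 1)
  }

  ## phewas hits
  phewas <- tibble(
    snp = sprintf("rs%07d", sample.int(10 * config$n_phewas, config$n_phewas)),
    gene = sample(universe, config$n_phewas, replace = TRUE),
    phenotype = sample(disease_names, config$n_phewas, replace = TRUE),
    category = sample(c("circulatory system", "endocrine/metabolic",
                        "musculoskeletal", "neurological", "respiratory"),
                      config$n_phewas, replace = TRUE),
    p = sample_p(config$n_phewas, config$p_log10_range)
  )
  phewas_written <- phewas
  if (config$invalid_p_rows > 0) {
    bad <- phewas[sample.int(nrow(phewas), config$invalid_p_rows, replace = TRUE), ]
    bad$p <- stats::runif(config$invalid_p_rows, 1.01, 10)
    bad$snp <- sprintf("rsbad%04d", seq_len(config$invalid_p_rows))
    phewas_written <- dplyr::bind_rows(phewas, bad)
  }

  ## gene-disease associations
  assoc <- dplyr::distinct(tibble(
    gene = sample(universe, config$n_associations, replace = TRUE),
    disease = sample(disease_names, config$n_associations, replace = TRUE),
    source = sample(c("clinvar_like", "monarch_like", "curated"),
                    config$n_associations, replace = TRUE)
  ), .data$gene, .data$disease, .keep_all = TRUE)

  ## drug links
  drugs <- dplyr::distinct(tibble(
    drug = sprintf("drug-%03d", sample.int(round(config$n_drugs * 0.8) + 1,
                                           config$n_drugs, replace = TRUE)),
    gene = sample(universe, config$n_drugs, replace = TRUE),
    snp = sprintf("rs%07d", sample.int(10 * config$n_phewas, config$n_drugs))
  ), .data$drug, .data$gene, .keep_all = TRUE)

  ## ppi pairs
  n_mm <- if (length(mat_symbols) > 0) {
    round(config$n_ppi * config$ppi_matrisome_fraction)
  } else 0L
  a1 <- sample(mat_symbols, n_mm, replace = TRUE)
  b1 <- sample(mat_symbols, n_mm, replace = TRUE)
  non_mat <- setdiff(universe, mat_symbols)
  a2 <- sample(non_mat, config$n_ppi - n_mm, replace = TRUE)
  b2 <- sample(universe, config$n_ppi - n_mm, replace = TRUE)
  ppi <- tibble(gene_a = c(a1, a2), gene_b = c(b1, b2))
  ppi <- ppi[ppi$gene_a != ppi$gene_b, , drop = FALSE]
  ppi <- dplyr::distinct(tibble(gene_a = pmin(ppi$gene_a, ppi$gene_b),
                                gene_b = pmax(ppi$gene_a, ppi$gene_b)))

  ## rare-disease links
  rare_names <- sprintf("rare %s %04d",
                        sample(c("deficiency", "dysplasia", "atrophy"),
                               config$n_rare, replace = TRUE),
                        sample.int(5 * config$n_rare, config$n_rare,
                                   replace = TRUE))
  rare <- dplyr::distinct(tibble(
    gene = sample(universe, config$n_rare, replace = TRUE),
    disease = rare_names,
    source = "rare_disease"
  ), .data$gene, .data$disease, .keep_all = TRUE)

  ## ---- realized ground truth -------------------------------------------
  missense_parsed <- parse_protein_change(variants$protein_change)
  miss <- missense_parsed$status == "missense"
  sub_counts <- dplyr::count(
    tibble(ref = missense_parsed$ref[miss], alt = missense_parsed$alt[miss]),
    .data$ref, .data$alt, name = "n"
  )
  ref_rank <- dplyr::arrange(
    dplyr::summarise(dplyr::group_by(sub_counts, .data$ref),
                     n = sum(.data$n), .groups = "drop"),
    dplyr::desc(.data$n), .data$ref
  )
  vpd <- variants_per_disease(
    tibble(condition_norm = normalize_disease(variants$condition),
           variant_id = variants$variant_id)
  )
  mat_assoc <- assoc[assoc$gene %in% mat_symbols, , drop = FALSE]
  mat_ppi <- ppi[ppi$gene_a %in% mat_symbols & ppi$gene_b %in% mat_symbols, ,
                 drop = FALSE]
  # pipeline joins drugs against the matrisome-restricted association set
  triad <- drugs[drugs$gene %in% unique(mat_assoc$gene), , drop = FALSE]
  rare_mat <- rare[rare$gene %in% mat_symbols, , drop = FALSE]
  disease_norm_truth <- tibble(
    disease = normalize_disease(disease_truth$disease),
    in_A = disease_truth$in_A, in_B = disease_truth$in_B,
    in_C = disease_truth$in_C
  )

  manifest <- list(
    seed = config$seed,
    catalog = list(
      n_genes = nrow(catalog),
      symbols = catalog$symbol,
      category_counts = as.list(table(catalog$category))
    ),
    diseases = list(
      membership = as.data.frame(disease_norm_truth),
      marginals = list(A = sum(disease_truth$in_A), B = sum(disease_truth$in_B),
                       C = sum(disease_truth$in_C))
    ),
    variants = list(
      n_records = nrow(variants),
      n_rows_written = nrow(variants_written),
      n_missense = sum(miss),
      n_matrisome_records = sum(variants$gene %in% mat_symbols),
      substitution_counts = as.data.frame(sub_counts),
      ref_ranking = ref_rank$ref,
      per_disease = as.data.frame(vpd)
    ),
    phewas = list(
      n_valid = nrow(phewas),
      n_rows_written = nrow(phewas_written),
      n_invalid_p = config$invalid_p_rows,
      n_matrisome = sum(phewas$gene %in% mat_symbols),
      n_below_0_05 = sum(phewas$p < 0.05)
    ),
    associations = list(
      n_pairs = nrow(assoc),
      matrisome = list(
        n_pairs = nrow(mat_assoc),
        n_genes = length(unique(mat_assoc$gene)),
        n_diseases = length(unique(normalize_disease(mat_assoc$disease)))
      ),
      genes_per_disease = as.data.frame(
        dplyr::arrange(dplyr::count(
          tibble(disease = normalize_disease(mat_assoc$disease),
                 gene = mat_assoc$gene), .data$disease, name = "degree"),
          dplyr::desc(.data$degree), .data$disease)
      )
    ),
    ppi = list(
      n_pairs = nrow(ppi),
      n_matrisome_pairs = nrow(mat_ppi),
      n_matrisome_genes = length(unique(c(mat_ppi$gene_a, mat_ppi$gene_b)))
    ),
    drugs = list(
      n_links = nrow(drugs),
      n_candidates = nrow(triad),
      n_candidate_drugs = length(unique(triad$drug)),
      n_candidate_genes = length(unique(triad$gene))
    ),
    rare = list(
      n_pairs = nrow(rare),
      n_matrisome_genes = length(unique(rare_mat$gene)),
      n_matrisome_rare_diseases = length(unique(normalize_disease(rare_mat$disease)))
    )
  )

  files <- c(
    matrisome = file.path(outdir, "matrisome.tsv"),
    variants = file.path(outdir, "variants.tsv"),
    phewas = file.path(outdir, "phewas.tsv"),
    associations = file.path(outdir, "associations.tsv"),
    drugs = file.path(outdir, "drugs.tsv"),
    ppi = file.path(outdir, "ppi.tsv"),
    rare = file.path(outdir, "rare_diseases.tsv")
  )
  readr::write_tsv(catalog, files[["matrisome"]], progress = FALSE)
  readr::write_tsv(variants_written, files[["variants"]], progress = FALSE, na = "")
  readr::write_tsv(phewas_written, files[["phewas"]], progress = FALSE)
  readr::write_tsv(assoc, files[["associations"]], progress = FALSE)
  readr::write_tsv(drugs, files[["drugs"]], progress = FALSE)
  readr::write_tsv(ppi, files[["ppi"]], progress = FALSE)
  readr::write_tsv(rare, files[["rare"]], progress = FALSE)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files <- c(files, manifest = manifest_path)

  invisible(list(
    files = files, manifest = manifest,
    data = list(catalog = catalog, variants = variants, phewas = phewas,
                associations = assoc, drugs = drugs, ppi = ppi, rare = rare,
                disease_truth = disease_norm_truth)
  ))
}
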