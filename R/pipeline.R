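# End-to-end orchestration: read -> annotate -> (variants | phewas |
# associations | rare | ppi) -> categorize -> network -> repurpose -> report.
# A failure in any branch aborts with the stage named; the report re-asserts
# the upstream conservation identities.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)),
          class = "ecm_stage_error", parent = e)
  })
}

#' Run the full diseasome pipeline
#'
#' Orchestrates every stage over a named list of input paths in the
#' canonical dialects. Only `matrisome` is mandatory; any other input may be
#' `NULL`, in which case its branch is skipped. The run is deterministic:
#' identical inputs and settings give an identical report.
#'
#' @param inputs Named list of paths: `matrisome` (required), and optionally
#'   `variants`, `phewas`, `associations` (character vector of one or more
#'   paths), `rare`, `drugs`, `ppi`.
#' @param terms Disease category terms ([default_category_terms()]).
#' @param alpha Significance threshold for PheWAS filtering (strict `<`).
#' @param top_n How many top PheWAS hits to keep.
#' @param top_alpha Threshold for the top-hit selection (default `1e-6`).
#' @param label_threshold Labelling threshold for per-gene summaries.
#' @param cluster_cut Jaccard similarity cut for collagen gene clustering.
#' @param substitution_genes `"collagens"` (default) to restrict the
#'   substitution matrix to the catalog's collagen category, or `"all"` for
#'   the whole matrisome.
#' @return An object of class `diseasome_report`.
#' @export
run_pipeline <- function(inputs,
                         terms = default_category_terms(),
                         alpha = 0.05,
                         top_n = 1000,
                         top_alpha = 1e-6,
                         label_threshold = 1e-5,
                         cluster_cut = 0.5,
                         substitution_genes = c("collagens", "all")) {
  substitution_genes <- rlang::arg_match(substitution_genes)
  if (is.null(inputs$matrisome)) {
    abort("stage 'read' failed: a matrisome catalog path is required",
          class = "ecm_stage_error")
  }
  report <- list(settings = list(alpha = alpha, top_n = top_n,
                                 top_alpha = top_alpha,
                                 label_threshold = label_threshold,
                                 cluster_cut = cluster_cut,
                                 substitution_genes = substitution_genes))

  catalog <- run_stage("read", read_matrisome_list(inputs$matrisome))
  report$catalog <- list(n_genes = nrow(catalog), load = load_report(catalog))

  ## variants branch
  if (!is.null(inputs$variants)) {
    variants <- run_stage("variants", read_variant_table(inputs$variants))
    mat_var <- run_stage("variants", annotate_genes(variants, catalog))
    sub_genes <- if (substitution_genes == "collagens") {
      catalog$symbol[catalog$category == "collagens"]
    } else {
      catalog$symbol
    }
    m <- run_stage("variants", substitution_matrix(mat_var, genes = sub_genes))
    report$variants <- list(
      load = load_report(variants),
      n_matrisome_records = nrow(mat_var),
      per_disease = variants_per_disease(mat_var),
      substitution = m,
      ref_ranking = rank_substituted(m),
      gly_targets = rank_targets(m, "Gly")
    )
  }

  ## phewas branch
  if (!is.null(inputs$phewas)) {
    phewas <- run_stage("phewas", read_phewas_table(inputs$phewas))
    mat_hits <- run_stage("phewas", annotate_genes(phewas, catalog))
    sig <- filter_by_p(mat_hits, alpha)
    top <- top_hits(mat_hits, top_n, top_alpha)
    report$phewas <- list(
      load = load_report(phewas),
      n_matrisome_hits = nrow(mat_hits),
      n_matrisome_snps = length(unique(mat_hits$snp)),
      n_significant = nrow(sig),
      top_hits = top,
      n_top_genes = length(unique(top$gene)),
      gene_summaries = gene_phenotype_summary(mat_hits, label_threshold)
    )
  }

  ## association branches
  assoc_sets <- list()
  if (!is.null(inputs$associations)) {
    assoc_sets <- run_stage("associations", lapply(inputs$associations,
                                                   read_association_table))
  }
  if (length(assoc_sets) > 0) {
    dm <- run_stage("associations",
                    rlang::exec(disease_matrisome, !!!assoc_sets,
                                catalog = catalog))
    comp <- composition_summary(
      tibble(symbol = unique(dm$associations$gene),
             division = catalog$division[match(unique(dm$associations$gene),
                                               catalog$symbol)],
             category = catalog$category[match(unique(dm$associations$gene),
                                               catalog$symbol)]),
      nrow(catalog)
    )
    cats <- categorize_disease(unique(dm$associations$disease), terms)
    per_assoc <- categorize_disease(dm$associations$disease, terms)
    net <- run_stage("network", build_bipartite(dm$associations))
    sub <- run_stage("network", collagen_subnetwork(net, catalog))
    clusters <- if (length(sub$genes) > 0) {
      run_stage("network", shared_disease_clusters(sub, cluster_cut))
    } else {
      tibble(gene = character(), cluster = integer())
    }
    report$associations <- list(
      n_genes = dm$n_genes, n_diseases = dm$n_diseases, n_pairs = dm$n_pairs,
      composition = comp,
      category_by_disease = category_counts(cats, "by_disease"),
      category_by_association = category_counts(per_assoc, "by_association"),
      genes_per_disease = genes_per_disease(net),
      diseases_per_gene = diseases_per_gene(net),
      collagen = list(n_genes = length(sub$genes),
                      n_diseases = length(sub$diseases),
                      n_edges = nrow(sub$edges),
                      clusters = clusters),
      network = glance(net)
    )
    assoc_for_drugs <- dm$associations
  } else {
    assoc_for_drugs <- NULL
  }

  ## rare-disease branch
  if (!is.null(inputs$rare)) {
    rare <- run_stage("rare", read_rare_disease_table(inputs$rare))
    rare_mat <- run_stage("rare", annotate_genes(rare, catalog))
    report$rare <- list(
      load = load_report(rare),
      n_matrisome_genes = length(unique(rare_mat$gene)),
      n_rare_diseases = length(unique(rare_mat$disease))
    )
  }

  ## ppi branch
  if (!is.null(inputs$ppi)) {
    ppi <- run_stage("ppi", read_ppi_table(inputs$ppi))
    mm <- run_stage("ppi", matrisome_ppi_pairs(ppi, catalog))
    report$ppi <- list(load = load_report(ppi),
                       n_matrisome_pairs = mm$n_pairs,
                       n_matrisome_genes = mm$n_genes)
  }

  ## drug-repurposing branch
  if (!is.null(inputs$drugs) && !is.null(assoc_for_drugs)) {
    drugs <- run_stage("repurpose", read_drug_table(inputs$drugs))
    cand <- run_stage("repurpose", join_candidates(assoc_for_drugs, drugs))
    report$repurposing <- c(summarize_candidates(cand),
                            list(candidates = cand))
  }

  ## conservation identities re-asserted at report time
  run_stage("report", {
    for (br in c("catalog", "variants", "phewas", "rare", "ppi")) {
      lr <- report[[br]]$load
      if (!is.null(lr)) {
        stopifnot(lr$rows_in == lr$records_out + lr$dropped + lr$rejected)
      }
    }
    if (!is.null(report$associations)) {
      stopifnot(
        sum(report$associations$genes_per_disease$degree) ==
          report$associations$network$n_edges,
        sum(report$associations$diseases_per_gene$degree) ==
          report$associations$network$n_edges,
        sum(report$associations$category_by_disease$labels$n) ==
          report$associations$n_diseases
      )
    }
  })

  structure(report, class = "diseasome_report")
}

#' @export
print.diseasome_report <- function(x, ...) {
  cat("Diseasome pipeline report\n")
  cat("  catalog: ", x$catalog$n_genes, " matrisome genes\n", sep = "")
  if (!is.null(x$variants)) {
    cat("  variants: ", x$variants$load$records_out, " records, ",
        x$variants$n_matrisome_records, " in matrisome\n", sep = "")
  }
  if (!is.null(x$phewas)) {
    cat("  phewas: ", x$phewas$n_matrisome_hits, " matrisome hits (",
        x$phewas$n_significant, " significant)\n", sep = "")
  }
  if (!is.null(x$associations)) {
    cat("  associations: ", x$associations$n_genes, " genes x ",
        x$associations$n_diseases, " diseases, ",
        x$associations$n_pairs, " pairs (",
        sprintf("%.1f", x$associations$composition$fraction_of_catalog),
        "% of catalog)\n", sep = "")
  }
  if (!is.null(x$rare)) {
    cat("  rare: ", x$rare$n_matrisome_genes, " matrisome genes, ",
        x$rare$n_rare_diseases, " rare diseases\n", sep = "")
  }
  if (!is.null(x$ppi)) {
    cat("  ppi: ", x$ppi$n_matrisome_pairs, " matrisome-matrisome pairs (",
        x$ppi$n_matrisome_genes, " genes)\n", sep = "")
  }
  if (!is.null(x$repurposing)) {
    cat("  repurposing: ", x$repurposing$n_candidates, " candidates (",
        x$repurposing$n_drugs, " drugs, ", x$repurposing$n_genes,
        " genes)\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.diseasome_report <- function(x, ...) {
  tibble(
    n_catalog_genes = x$catalog$n_genes,
    n_variant_records = x$variants$load$records_out %||% NA_integer_,
    n_matrisome_hits = x$phewas$n_matrisome_hits %||% NA_integer_,
    n_association_pairs = x$associations$n_pairs %||% NA_integer_,
    fraction_of_catalog = x$associations$composition$fraction_of_catalog %||% NA_real_,
    n_rare_matrisome_genes = x$rare$n_matrisome_genes %||% NA_integer_,
    n_matrisome_ppi_pairs = x$ppi$n_matrisome_pairs %||% NA_integer_,
    n_repurposing_candidates = x$repurposing$n_candidates %||% NA_integer_
  )
}
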