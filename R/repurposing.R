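# Drug-repurposing triads: drug -> target gene -> associated diseases.

#' Join gene-disease associations with drug-gene links
#'
#' Builds one repurposing candidate per `(drug, gene)` pair whose target
#' gene carries at least one disease association; the candidate's disease
#' set is the union of that gene's diseases. Genes without drugs and drugs
#' without disease-linked targets are dropped and counted. When a
#' `snp_universe` is supplied (e.g. the SNP ids seen in variant or PheWAS
#' tables), drug links carrying a SNP id absent from it are additionally
#' dropped — the stricter SNP-mediated linkage.
#'
#' @param associations Gene-disease association tibble (`gene`, `disease`).
#' @param drugs Drug-gene link tibble from [read_drug_table()].
#' @param snp_universe Optional character vector of admissible SNP ids.
#' @return A tibble of class `repurposing_candidates` with columns `drug`,
#'   `gene`, `snp`, `n_diseases` and `diseases` (list column of sorted
#'   normalized names); drop counts in attribute `join_report`.
#' @export
join_candidates <- function(associations, drugs, snp_universe = NULL) {
  assoc <- as_tibble(associations)
  drugs <- as_tibble(drugs)
  n_drug_links <- nrow(drugs)
  if (!is.null(snp_universe)) {
    drugs <- drugs[!is.na(drugs$snp) & drugs$snp %in% snp_universe, , drop = FALSE]
  }
  disease_sets <- dplyr::summarise(
    dplyr::group_by(assoc, .data$gene),
    diseases = list(sort(unique(.data$disease))), .groups = "drop"
  )
  joined <- dplyr::inner_join(drugs, disease_sets, by = "gene")
  joined <- dplyr::arrange(joined, .data$drug, .data$gene)
  out <- tibble(
    drug = joined$drug, gene = joined$gene,
    snp = if ("snp" %in% names(joined)) joined$snp else NA_character_,
    n_diseases = purrr::map_int(joined$diseases, length),
    diseases = joined$diseases
  )
  report <- list(
    n_drug_links = n_drug_links,
    n_drugs_dropped = n_drug_links - nrow(out),
    n_genes_without_drug = length(setdiff(disease_sets$gene, out$gene))
  )
  structure(out, class = c("repurposing_candidates", class(out)),
            join_report = report)
}

#' Summarize repurposing candidates
#'
#' @param candidates A tibble from [join_candidates()].
#' @return A list with `n_drugs`, `n_genes`, `n_candidates`, and `per_gene`
#'   (tibble `gene`, `n_drugs`, `n_diseases` where `n_diseases` is the size
#'   of the union of that gene's disease sets).
#' @export
summarize_candidates <- function(candidates) {
  df <- as_tibble(candidates)
  if (nrow(df) == 0) {
    return(list(n_drugs = 0L, n_genes = 0L, n_candidates = 0L,
                per_gene = tibble(gene = character(), n_drugs = integer(),
                                  n_diseases = integer())))
  }
  per_gene <- dplyr::summarise(
    dplyr::group_by(df, .data$gene),
    n_drugs = dplyr::n_distinct(.data$drug),
    n_diseases = length(unique(unlist(.data$diseases))),
    .groups = "drop"
  )
  list(
    n_drugs = length(unique(df$drug)),
    n_genes = length(unique(df$gene)),
    n_candidates = nrow(df),
    per_gene = dplyr::arrange(per_gene, dplyr::desc(.data$n_drugs), .data$gene)
  )
}

#' Export repurposing candidates as a delimited table
#'
#' Tab-separated with the disease set semicolon-joined.
#'
#' @param candidates A tibble from [join_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  df <- as_tibble(candidates)
  flat <- tibble(drug = df$drug, gene = df$gene, snp = df$snp,
                 n_diseases = df$n_diseases,
                 diseases = purrr::map_chr(df$diseases, paste, collapse = ";"))
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
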