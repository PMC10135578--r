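# Intersection of gene-bearing record sets with the matrisome catalog, and
# disease-matrisome composition summaries.

#' Restrict a gene-bearing table to matrisome genes
#'
#' Filters any table with a gene-symbol column down to rows whose gene is in
#' the matrisome catalog, tagging each surviving row with the gene's
#' matrisome `division` and `category`. Input order is preserved; applying
#' the filter twice equals applying it once.
#'
#' @param records A tibble with a gene-symbol column (symbols already
#'   normalized, as the readers do).
#' @param catalog A matrisome catalog from [read_matrisome_list()].
#' @param gene_col Name of the gene-symbol column in `records`.
#' @return `records` restricted to matrisome genes, with `division` and
#'   `category` columns appended.
#' @export
annotate_genes <- function(records, catalog, gene_col = "gene") {
  if (is.null(catalog) || nrow(catalog) == 0) {
    abort("matrisome catalog is empty", class = "ecm_config_error")
  }
  records <- as_tibble(records)
  if (!gene_col %in% names(records)) {
    abort(paste0("records have no '", gene_col, "' column"),
          class = "ecm_format_error")
  }
  idx <- match(records[[gene_col]], catalog$symbol)
  keep <- !is.na(idx)
  out <- records[keep, setdiff(names(records), c("division", "category")),
                 drop = FALSE]
  out$division <- catalog$division[idx[keep]]
  out$category <- catalog$category[idx[keep]]
  out
}

#' Summarize the matrisome composition of a gene set
#'
#' Given a set of matrisome-tagged genes (for example the unique genes of a
#' disease-associated subset), counts genes per division and per category and
#' reports the share of the full catalog they cover. The fraction is
#' `100 * total_genes / catalog_size`, rounded half-up to one decimal, so
#' e.g. 333 disease genes against a 1027-gene catalog give 32.4.
#'
#' @param genes Tibble of tagged genes with columns `symbol` (or `gene`),
#'   `division`, `category`; duplicate symbols are counted once.
#' @param catalog_size Number of genes in the full catalog (> 0).
#' @return An object of class `composition_summary`: a list with
#'   `total_genes`, `fraction_of_catalog`, `by_division` and `by_category`
#'   count tibbles.
#' @export
composition_summary <- function(genes, catalog_size) {
  if (!is.numeric(catalog_size) || catalog_size <= 0) {
    abort("catalog_size must be a positive count", class = "ecm_config_error")
  }
  genes <- as_tibble(genes)
  sym_col <- if ("symbol" %in% names(genes)) "symbol" else "gene"
  if (!all(c(sym_col, "division", "category") %in% names(genes))) {
    abort("genes must carry symbol, division and category tags",
          class = "ecm_contract_error")
  }
  uniq <- dplyr::distinct(genes[, c(sym_col, "division", "category")])
  names(uniq)[1] <- "symbol"
  if (anyNA(uniq$division) || anyNA(uniq$category)) {
    abort("untagged gene in composition input", class = "ecm_contract_error")
  }
  by_division <- dplyr::count(uniq, .data$division, name = "n_genes")
  by_category <- dplyr::count(uniq, .data$division, .data$category,
                              name = "n_genes")
  structure(
    list(
      total_genes = nrow(uniq),
      catalog_size = as.integer(catalog_size),
      fraction_of_catalog = round_half_up(100 * nrow(uniq) / catalog_size, 1),
      by_division = by_division,
      by_category = by_category
    ),
    class = "composition_summary"
  )
}

#' @export
print.composition_summary <- function(x, ...) {
  cat("Matrisome composition: ", x$total_genes, "/", x$catalog_size,
      " catalog genes (", sprintf("%.1f", x$fraction_of_catalog), "%)\n",
      sep = "")
  print(x$by_category)
  invisible(x)
}

#' @export
tidy.composition_summary <- function(x, ...) {
  x$by_category
}

#' @export
glance.composition_summary <- function(x, ...) {
  tibble(total_genes = x$total_genes,
         catalog_size = x$catalog_size,
         fraction_of_catalog = x$fraction_of_catalog)
}

#' Merge association sources into the disease matrisome
#'
#' Takes one or more gene-disease association tables, merges them, restricts
#' to matrisome genes, and deduplicates on the `(gene, disease)` pair across
#' sources. Disease identity is the normalized disease string; no ontology
#' reconciliation is attempted. Merging is associative and commutative at
#' the unique-pair level.
#'
#' @param ... One or more association tibbles (as from
#'   [read_association_table()]).
#' @param catalog A matrisome catalog from [read_matrisome_list()].
#' @return A list with `associations` (unique tagged pairs), `n_genes`,
#'   `n_diseases`, `n_pairs`.
#' @export
disease_matrisome <- function(..., catalog) {
  sets <- rlang::list2(...)
  if (length(sets) == 0) abort("no association sets supplied",
                               class = "ecm_config_error")
  merged <- dplyr::bind_rows(lapply(sets, function(s) {
    as_tibble(s)[, intersect(c("gene", "disease", "source"), names(s))]
  }))
  tagged <- annotate_genes(merged, catalog, gene_col = "gene")
  pairs <- dplyr::distinct(tagged, .data$gene, .data$disease, .keep_all = TRUE)
  list(
    associations = pairs,
    n_genes = length(unique(pairs$gene)),
    n_diseases = length(unique(pairs$disease)),
    n_pairs = nrow(pairs)
  )
}
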