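# Readers for the canonical delimited dialects. Every reader normalizes into
# the shared column vocabulary, deduplicates exact records, and attaches a
# load report (see load_report()) satisfying
#   rows_in = records_out + dropped + rejected.

MATRISOME_CATEGORIES <- c(
  "collagens", "glycoproteins", "proteoglycans",
  "ecm_affiliated", "ecm_regulators", "secreted_factors"
)

# collagens/glycoproteins/proteoglycans form the core matrisome; the rest
# are matrisome-associated.
DIVISION_FOR_CATEGORY <- c(
  collagens = "core_matrisome",
  glycoproteins = "core_matrisome",
  proteoglycans = "core_matrisome",
  ecm_affiliated = "matrisome_associated",
  ecm_regulators = "matrisome_associated",
  secreted_factors = "matrisome_associated"
)

ASSOCIATION_SOURCES <- c(
  "clinvar_like", "monarch_like", "phewas_like", "rare_disease", "curated"
)

# Map free-text category/division labels ("ECM Glycoproteins",
# "Core matrisome", ...) onto the canonical enums.
canonical_category <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  lookup <- c(
    collagens = "collagens", collagen = "collagens",
    glycoproteins = "glycoproteins", ecmglycoproteins = "glycoproteins",
    proteoglycans = "proteoglycans",
    ecmaffiliated = "ecm_affiliated", ecmaffiliatedproteins = "ecm_affiliated",
    ecmregulators = "ecm_regulators",
    secretedfactors = "secreted_factors"
  )
  out <- unname(lookup[key])
  out
}

canonical_division <- function(x) {
  key <- gsub("[^a-z]", "", tolower(x))
  lookup <- c(
    corematrisome = "core_matrisome", core = "core_matrisome",
    matrisomeassociated = "matrisome_associated",
    associated = "matrisome_associated"
  )
  unname(lookup[key])
}

# Read a delimited file, apply a column-mapping config, and check mandatory
# columns. `col_map` is a named character vector canonical_name = file_column;
# unmapped canonical names are looked up verbatim. Delimiter defaults to tab,
# with ".csv" files read as comma-separated.
read_dialect <- function(path, delim = NULL, col_map = NULL,
                         mandatory = character(), optional = character()) {
  if (!file.exists(path)) {
    abort(paste0("cannot read '", path, "': no such file"), class = "ecm_io_error")
  }
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  wanted <- c(mandatory, optional)
  map <- setNames(wanted, wanted)
  if (!is.null(col_map)) map[names(col_map)] <- unname(col_map)
  missing_cols <- mandatory[!map[mandatory] %in% names(df)]
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste0(missing_cols, " (expected file column '",
                        map[missing_cols], "')", collapse = ", ")),
          class = "ecm_format_error")
  }
  out <- tibble(.rows = nrow(df))
  for (nm in wanted) {
    out[[nm]] <- if (map[[nm]] %in% names(df)) df[[map[[nm]]]] else NA_character_
  }
  out
}

is_blank <- function(x) is.na(x) | stringr::str_trim(x) == ""

warn_if_empty <- function(x, what) {
  if (nrow(x) == 0) warn(paste0("no usable rows in ", what), class = "ecm_empty_input")
  x
}

#' Read a matrisome gene catalog
#'
#' Reads a gene catalog in the canonical `matrisome(symbol, division,
#' category)` dialect (tab-separated by default, header required) and returns
#' a deduplicated tibble of matrisome genes. Category labels such as
#' `"ECM Glycoproteins"` or `"Collagens"` are mapped onto the canonical
#' enums; the division is inferred from the category when absent, and checked
#' for consistency when present (collagens, glycoproteins and proteoglycans
#' belong to the core matrisome, the other categories to the
#' matrisome-associated division).
#'
#' @param path Path to the delimited file.
#' @param delim Field delimiter; defaults to tab (`","` for `.csv` paths).
#' @param col_map Optional named character vector mapping canonical column
#'   names (`symbol`, `division`, `category`) to the file's column names,
#'   so real database exports can be adapted without editing them.
#' @return A tibble with columns `symbol`, `division`, `category`, one row
#'   per unique gene, with a [load_report()] attached.
#' @export
read_matrisome_list <- function(path, delim = NULL, col_map = NULL) {
  raw <- read_dialect(path, delim, col_map,
                      mandatory = c("symbol", "category"),
                      optional = "division")
  rows_in <- nrow(raw)
  ok <- !is_blank(raw$symbol) & !is_blank(raw$category)
  dropped_missing <- sum(!ok)
  df <- raw[ok, , drop = FALSE]
  df$symbol <- normalize_symbol(df$symbol)
  cat_canon <- canonical_category(df$category)
  bad_cat <- is.na(cat_canon)
  if (any(bad_cat)) {
    abort(paste0("unrecognized matrisome category value(s): ",
                 paste(unique(df$category[bad_cat]), collapse = ", ")),
          class = "ecm_format_error")
  }
  df$category <- cat_canon
  inferred <- unname(DIVISION_FOR_CATEGORY[df$category])
  given <- canonical_division(df$division)
  conflict_div <- !is.na(given) & given != inferred
  if (any(conflict_div)) {
    abort(paste0("division inconsistent with category for: ",
                 paste(unique(df$symbol[conflict_div]), collapse = ", ")),
          class = "ecm_conflict_error")
  }
  df$division <- inferred
  df <- df[, c("symbol", "division", "category")]
  deduped <- dplyr::distinct(df)
  dup_sym <- deduped$symbol[duplicated(deduped$symbol)]
  if (length(dup_sym) > 0) {
    abort(paste0("duplicate symbol(s) with conflicting annotation: ",
                 paste(unique(dup_sym), collapse = ", ")),
          class = "ecm_conflict_error")
  }
  out <- with_load_report(
    deduped,
    new_load_report(rows_in, nrow(deduped),
                    dropped_missing = dropped_missing,
                    dropped_duplicate = nrow(df) - nrow(deduped))
  )
  warn_if_empty(out, "matrisome catalog")
}

#' Read a clinical variant table
#'
#' Reads variant records in the canonical `variants(gene, variant_id,
#' protein_change, condition)` dialect. Rows with an empty gene or condition
#' are dropped and counted; exact duplicate records are collapsed. The
#' `protein_change` column may be absent, in which case all records carry
#' `NA`. Because a "polymorphism" count can mean either table rows or unique
#' variant ids, the load report exposes both (`records_out` and
#' `unique_variant_ids`).
#'
#' @inheritParams read_matrisome_list
#' @return A tibble with columns `gene`, `variant_id`, `protein_change`,
#'   `condition` (raw name) and `condition_norm` (normalized identity key),
#'   with a [load_report()] attached.
#' @export
read_variant_table <- function(path, delim = NULL, col_map = NULL) {
  raw <- read_dialect(path, delim, col_map,
                      mandatory = c("gene", "variant_id", "condition"),
                      optional = "protein_change")
  rows_in <- nrow(raw)
  ok <- !is_blank(raw$gene) & !is_blank(raw$condition)
  df <- raw[ok, , drop = FALSE]
  df$gene <- normalize_symbol(df$gene)
  df$condition_norm <- normalize_disease(df$condition)
  df <- df[, c("gene", "variant_id", "protein_change", "condition", "condition_norm")]
  deduped <- dplyr::distinct(df)
  out <- with_load_report(
    deduped,
    new_load_report(rows_in, nrow(deduped),
                    dropped_missing = sum(!ok),
                    dropped_duplicate = nrow(df) - nrow(deduped),
                    unique_variant_ids = length(unique(deduped$variant_id)))
  )
  warn_if_empty(out, "variant table")
}

#' Read a PheWAS hit table
#'
#' Reads SNP-phenotype association records in the canonical
#' `phewas(snp, gene, phenotype, category, p)` dialect. P-values are parsed
#' from decimal or scientific notation; rows whose p-value is missing,
#' non-numeric, or outside (0, 1] are rejected and counted in the load
#' report.
#'
#' @inheritParams read_matrisome_list
#' @return A tibble with columns `snp`, `gene`, `phenotype`, `category`,
#'   `p` (numeric), with a [load_report()] attached.
#' @export
read_phewas_table <- function(path, delim = NULL, col_map = NULL) {
  raw <- read_dialect(path, delim, col_map,
                      mandatory = c("snp", "gene", "phenotype", "p"),
                      optional = "category")
  rows_in <- nrow(raw)
  ok <- !is_blank(raw$gene) & !is_blank(raw$phenotype) & !is_blank(raw$snp)
  df <- raw[ok, , drop = FALSE]
  p <- suppressWarnings(as.numeric(df$p))
  valid_p <- is.finite(p) & p > 0 & p <= 1
  rejected <- sum(!valid_p)
  df <- df[valid_p, , drop = FALSE]
  df$p <- p[valid_p]
  df$gene <- normalize_symbol(df$gene)
  df <- df[, c("snp", "gene", "phenotype", "category", "p")]
  deduped <- dplyr::distinct(df)
  out <- with_load_report(
    deduped,
    new_load_report(rows_in, nrow(deduped),
                    dropped_missing = sum(!ok),
                    dropped_duplicate = nrow(df) - nrow(deduped),
                    rejected = rejected)
  )
  warn_if_empty(out, "PheWAS table")
}

#' Read a gene-disease association table
#'
#' Reads records in the canonical `associations(gene, disease, source)`
#' dialect. The `(gene, normalized disease)` pair is the identity key;
#' duplicate pairs from the same source are collapsed. When the file has no
#' `source` column the `source` argument fills it.
#'
#' @inheritParams read_matrisome_list
#' @param source Default provenance label for rows without one; one of
#'   `"clinvar_like"`, `"monarch_like"`, `"phewas_like"`, `"rare_disease"`,
#'   `"curated"`.
#' @return A tibble with columns `gene`, `disease` (normalized),
#'   `disease_raw`, `source`, with a [load_report()] attached.
#' @export
read_association_table <- function(path, delim = NULL, col_map = NULL,
                                   source = "curated") {
  source <- rlang::arg_match(source, ASSOCIATION_SOURCES)
  raw <- read_dialect(path, delim, col_map,
                      mandatory = c("gene", "disease"),
                      optional = "source")
  rows_in <- nrow(raw)
  ok <- !is_blank(raw$gene) & !is_blank(raw$disease)
  df <- raw[ok, , drop = FALSE]
  df$gene <- normalize_symbol(df$gene)
  df$disease_raw <- df$disease
  df$disease <- normalize_disease(df$disease)
  df$source <- dplyr::if_else(is_blank(df$source), source, df$source)
  bad_src <- !df$source %in% ASSOCIATION_SOURCES
  if (any(bad_src)) {
    abort(paste0("unknown association source value(s): ",
                 paste(unique(df$source[bad_src]), collapse = ", ")),
          class = "ecm_format_error")
  }
  df <- df[, c("gene", "disease", "disease_raw", "source")]
  deduped <- dplyr::distinct(df, .data$gene, .data$disease, .data$source,
                             .keep_all = TRUE)
  out <- with_load_report(
    deduped,
    new_load_report(rows_in, nrow(deduped),
                    dropped_missing = sum(!ok),
                    dropped_duplicate = nrow(df) - nrow(deduped))
  )
  warn_if_empty(out, "association table")
}

#' Read a rare-disease gene-disease table
#'
#' A minimal reader for rare/orphan disease extracts: the canonical
#' `associations(gene, disease)` dialect with the source fixed to
#' `"rare_disease"`.
#'
#' @inheritParams read_matrisome_list
#' @return As [read_association_table()].
#' @export
read_rare_disease_table <- function(path, delim = NULL, col_map = NULL) {
  read_association_table(path, delim, col_map, source = "rare_disease")
}

#' Read a drug-gene link table
#'
#' Reads records in the canonical `drugs(drug, gene, snp)` dialect. The
#' `(drug, gene)` pair is the identity key; duplicates are collapsed.
#'
#' @inheritParams read_matrisome_list
#' @return A tibble with columns `drug`, `gene`, `snp` (optional ids, `NA`
#'   when absent), with a [load_report()] attached.
#' @export
read_drug_table <- function(path, delim = NULL, col_map = NULL) {
  raw <- read_dialect(path, delim, col_map,
                      mandatory = c("drug", "gene"),
                      optional = "snp")
  rows_in <- nrow(raw)
  ok <- !is_blank(raw$drug) & !is_blank(raw$gene)
  df <- raw[ok, , drop = FALSE]
  df$drug <- stringr::str_trim(df$drug)
  df$gene <- normalize_symbol(df$gene)
  df <- df[, c("drug", "gene", "snp")]
  deduped <- dplyr::distinct(df, .data$drug, .data$gene, .keep_all = TRUE)
  out <- with_load_report(
    deduped,
    new_load_report(rows_in, nrow(deduped),
                    dropped_missing = sum(!ok),
                    dropped_duplicate = nrow(df) - nrow(deduped))
  )
  warn_if_empty(out, "drug table")
}

#' Read a protein-protein interaction pair list
#'
#' Reads records in the canonical `ppi(gene_a, gene_b)` dialect. Pairs are
#' unordered: each is canonicalized with `gene_a <= gene_b`
#' lexicographically, so `(A, B)` and `(B, A)` collapse to one pair.
#' Self-interactions are rejected and counted.
#'
#' @inheritParams read_matrisome_list
#' @return A tibble with columns `gene_a`, `gene_b`, with a [load_report()]
#'   attached.
#' @export
read_ppi_table <- function(path, delim = NULL, col_map = NULL) {
  raw <- read_dialect(path, delim, col_map, mandatory = c("gene_a", "gene_b"))
  rows_in <- nrow(raw)
  ok <- !is_blank(raw$gene_a) & !is_blank(raw$gene_b)
  df <- raw[ok, , drop = FALSE]
  a <- normalize_symbol(df$gene_a)
  b <- normalize_symbol(df$gene_b)
  self <- a == b
  rejected <- sum(self)
  df <- tibble(gene_a = pmin(a[!self], b[!self]),
               gene_b = pmax(a[!self], b[!self]))
  deduped <- dplyr::distinct(df)
  out <- with_load_report(
    deduped,
    new_load_report(rows_in, nrow(deduped),
                    dropped_missing = sum(!ok),
                    dropped_duplicate = nrow(df) - nrow(deduped),
                    rejected = rejected)
  )
  warn_if_empty(out, "PPI table")
}

#' Write a gene-disease association table
#'
#' Writes associations in the canonical tab-delimited dialect with a header
#' row, one association per line, stably sorted by `(gene, disease)`.
#' Re-reading the file with [read_association_table()] reproduces the
#' association multiset.
#'
#' @param associations Tibble with columns `gene`, `disease` and optionally
#'   `source` (filled with `"curated"` when absent).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(associations, path) {
  df <- as_tibble(associations)
  if (!"source" %in% names(df)) df$source <- "curated"
  df <- df[, c("gene", "disease", "source")]
  df <- dplyr::arrange(df, .data$gene, .data$disease)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
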