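# Filtering and per-gene summarization of PheWAS hits. The pipeline consumes
# p-values, never computes them; thresholds are applied with a strict "<"
# throughout.

#' Filter hits by significance threshold
#'
#' Keeps hits with `p < alpha` (strict inequality), preserving input order.
#' Monotone in alpha: a smaller threshold yields a subset.
#'
#' @param hits PheWAS tibble with a `p` column.
#' @param alpha Threshold in (0, 1].
#' @return The filtered tibble.
#' @export
filter_by_p <- function(hits, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("alpha must be in (0, 1]", class = "ecm_domain_error")
  }
  hits <- as_tibble(hits)
  hits[hits$p < alpha, , drop = FALSE]
}

#' Select the most significant hits
#'
#' The `n` smallest-p hits among those with `p < alpha`, sorted ascending by
#' p with ties broken by `(snp, phenotype)` lexicographically. Fewer than
#' `n` rows are returned when the filter leaves fewer.
#'
#' @param hits PheWAS tibble.
#' @param n Maximum number of hits to return (>= 1).
#' @param alpha Significance threshold (strict), default 1 (no filtering
#'   beyond `p < 1`).
#' @return A tibble of at most `n` hits.
#' @export
top_hits <- function(hits, n, alpha = 1) {
  if (!is.numeric(n) || n < 1) abort("n must be >= 1", class = "ecm_domain_error")
  out <- filter_by_p(hits, alpha)
  out <- dplyr::arrange(out, .data$p, .data$snp, .data$phenotype)
  head(out, n)
}

#' Per-gene phenotype association summaries
#'
#' For every gene present in the hits, summarizes its phenotype p-value
#' distribution: hit count, minimum and median p, quartiles of `-log10(p)`,
#' and the most significant phenotypes below a labelling threshold (capped).
#' Summaries are invariant to hit ordering.
#'
#' @param hits PheWAS tibble with `gene`, `phenotype`, `p` columns.
#' @param label_threshold Strict p threshold for labelling top phenotypes
#'   (default `1e-5`).
#' @param max_labels Cap on labelled phenotypes per gene (default 10).
#' @return A tibble with one row per gene: `gene`, `n_hits`, `min_p`,
#'   `median_p`, `q1_neglog10`, `median_neglog10`, `q3_neglog10`, and
#'   `top_phenotypes` (list column of `(phenotype, p)` tibbles sorted by p).
#' @export
gene_phenotype_summary <- function(hits, label_threshold = 1e-5,
                                   max_labels = 10) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) {
    return(tibble(gene = character(), n_hits = integer(),
                  min_p = double(), median_p = double(),
                  q1_neglog10 = double(), median_neglog10 = double(),
                  q3_neglog10 = double(), top_phenotypes = list()))
  }
  hits <- dplyr::arrange(hits, .data$gene, .data$p, .data$snp, .data$phenotype)
  out <- dplyr::summarise(
    dplyr::group_by(hits, .data$gene),
    n_hits = dplyr::n(),
    min_p = min(.data$p),
    median_p = median(.data$p),
    q1_neglog10 = quantile(-log10(.data$p), 0.25, names = FALSE),
    median_neglog10 = quantile(-log10(.data$p), 0.5, names = FALSE),
    q3_neglog10 = quantile(-log10(.data$p), 0.75, names = FALSE),
    top_phenotypes = list({
      lab <- dplyr::pick("phenotype", "p")
      head(lab[lab$p < label_threshold, , drop = FALSE], max_labels)
    }),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$min_p, .data$gene)
}

#' Long table for Manhattan-style plotting
#'
#' @param hits PheWAS tibble.
#' @return A tibble `(gene, phenotype, category, neglog10_p)`.
#' @export
manhattan_table <- function(hits) {
  hits <- as_tibble(hits)
  tibble(gene = hits$gene, phenotype = hits$phenotype,
         category = hits$category, neglog10_p = -log10(hits$p))
}
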