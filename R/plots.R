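# ggplot2 displays for the main result types. These mirror the field's usual
# figures: a substitution-frequency heatmap, division/category composition
# bars, degree bar charts, and per-gene -log10(p) boxplots.

#' @export
autoplot.substitution_matrix <- function(object, drop_empty = TRUE, ...) {
  df <- tidy(object)
  if (!drop_empty) {
    full <- tidyr::expand_grid(ref = rownames(object), alt = colnames(object))
    df <- dplyr::left_join(full, df, by = c("ref", "alt"))
    df$n[is.na(df$n)] <- 0L
  }
  ord <- aa_order()
  df$ref <- factor(df$ref, levels = rev(ord))
  df$alt <- factor(df$alt, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alt, y = .data$ref,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "substitutions") +
    ggplot2::labs(x = "alternate residue", y = "reference residue",
                  title = "Amino-acid substitution frequency") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.composition_summary <- function(object, ...) {
  df <- object$by_category
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$category,
                                                      .data$n_genes),
                                   y = .data$n_genes,
                                   fill = .data$division)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes",
                  title = sprintf("Disease matrisome: %d/%d catalog genes (%.1f%%)",
                                  object$total_genes, object$catalog_size,
                                  object$fraction_of_catalog)) +
    ggplot2::theme_minimal()
}

#' Bar chart of bipartite degrees
#'
#' @param degrees A degree tibble from [genes_per_disease()] or
#'   [diseases_per_gene()].
#' @param top How many top nodes to show.
#' @return A ggplot object.
#' @export
plot_degrees <- function(degrees, top = 25) {
  df <- head(degrees, top)
  side <- names(df)[1]
  df$node <- df[[side]]
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$node, .data$degree),
                                   y = .data$degree)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = side, y = "degree") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-gene -log10(p) distributions
#'
#' @param hits A PheWAS tibble with `gene` and `p` columns.
#' @param genes Optional subset of genes to show.
#' @return A ggplot object.
#' @export
plot_phewas_boxplots <- function(hits, genes = NULL) {
  df <- as_tibble(hits)
  if (!is.null(genes)) df <- df[df$gene %in% genes, , drop = FALSE]
  df$neglog10_p <- -log10(df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$gene,
                                                      .data$neglog10_p,
                                                      FUN = stats::median),
                                   y = .data$neglog10_p)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' Bar chart of disease category counts
#'
#' @param counts Result of [category_counts()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(counts) {
  ggplot2::ggplot(counts$labels, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange3") +
    ggplot2::labs(x = "category combination", y = "count") +
    ggplot2::theme_minimal()
}
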