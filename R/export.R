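# Artifact exports: graphs as GraphML / edge lists, substitution matrices as
# TSV grids, load reports as JSON.

#' Export a diseasome graph
#'
#' @param graph A `diseasome` from [build_bipartite()].
#' @param path Output path; format chosen by extension (`.graphml` for
#'   GraphML, anything else a tab-separated edge list).
#' @return `path`, invisibly.
#' @export
write_diseasome <- function(graph, path) {
  if (grepl("\\.graphml$", path, ignore.case = TRUE)) {
    igraph::write_graph(graph$graph, path, format = "graphml")
  } else {
    readr::write_tsv(graph$edges, path, progress = FALSE)
  }
  invisible(path)
}

#' Export a substitution matrix as a TSV grid
#'
#' Rows are reference residues (three-letter code), columns alternates.
#'
#' @param matrix A [substitution_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_substitution_matrix <- function(matrix, path) {
  df <- as.data.frame(unclass(matrix))
  df <- cbind(ref = rownames(matrix), df)
  readr::write_tsv(as_tibble(df), path, progress = FALSE)
  invisible(path)
}

#' Export a load report as JSON
#'
#' @param x A tibble with a [load_report()] attached, or the report itself.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_load_report <- function(x, path) {
  rep <- if (is.list(x) && !is.data.frame(x)) x else load_report(x)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
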