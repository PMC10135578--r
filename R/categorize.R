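# Substring-based assignment of diseases to the A/B/C category lattice:
# A = connective-tissue disease, B = common disease, C = age-related disease.
# A disease may match several lists and then carries the combined label
# ("A_C", "B_C", "A_B_C"); one matching no list is "uncategorized".

#' Default disease category term lists
#'
#' Built-in term lists for the three disease categories: A
#' (connective-tissue diseases such as the Ehlers-Danlos, Marfan and Alport
#' syndromes), B (common diseases such as asthma, autism or stroke), and C
#' (age-related diseases such as arthritis, cancer or fibrosis). The lists
#' cover well-known exemplars of each group and are deliberately
#' user-replaceable via [load_terms()] or a hand-built list: term choice is
#' a curation decision, not an algorithmic one.
#'
#' @return An object of class `category_terms`: a list of three character
#'   vectors `A`, `B`, `C`, lowercase and deduplicated.
#' @export
default_category_terms <- function() {
  new_category_terms(list(
    A = c("ehlers-danlos", "ehlers danlos", "osteogenesis imperfecta",
          "marfan", "alport", "fraser", "von willebrand", "stickler",
          "ullrich", "epidermolysis bullosa", "cutis laxa",
          "connective tissue"),
    B = c("diabetes type 1", "type 1 diabetes", "diabetes mellitus type 1",
          "asthma", "autism", "lissencephaly", "schizophrenia", "seizure",
          "muscular dystrophy", "obesity", "stroke", "epilepsy",
          "intellectual disability"),
    C = c("arthritis", "alzheimer", "cancer", "carcinoma",
          "diabetes type 2", "type 2 diabetes", "diabetes mellitus type 2",
          "chronic obstructive pulmonary", "fibrosis", "parkinson",
          "cirrhosis", "osteoporosis", "hypertension", "macular",
          "atherosclerosis", "glaucoma")
  ))
}

new_category_terms <- function(lists) {
  missing <- setdiff(c("A", "B", "C"), names(lists))
  if (length(missing) > 0) {
    abort(paste0("term config must name list(s): ", paste(missing, collapse = ", ")),
          class = "ecm_config_error")
  }
  out <- lapply(lists[c("A", "B", "C")], function(v) {
    v <- tolower(stringr::str_trim(as.character(v)))
    v <- unique(v[v != "" & !is.na(v)])
    v
  })
  structure(out, class = "category_terms")
}

#' Load disease category term lists from a config file
#'
#' Reads a JSON config with three arrays `A`, `B`, `C` of category terms.
#' Terms are lowercased, trimmed and deduplicated; a missing list is a
#' configuration error (an empty list is allowed and simply makes that
#' category unassignable).
#'
#' @param path Path to a JSON file.
#' @return A `category_terms` object.
#' @export
load_terms <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_category_terms(as.list(cfg))
}

#' Categorize disease names by substring matching
#'
#' Tests every term of every category list as a case-insensitive substring
#' of each normalized disease name. A disease receives every category with
#' at least one matching term; its label is the sorted matching categories
#' joined with `"_"` (`"A"`, `"B_C"`, `"A_B_C"`), or `"uncategorized"` when
#' nothing matches. Matching is plain substring containment with no
#' word-boundary requirement, so "cancerous" matches the term "cancer".
#'
#' @param diseases Character vector of disease names (any case/whitespace).
#' @param terms A `category_terms` object; defaults to
#'   [default_category_terms()].
#' @return A tibble with one row per input: `disease` (normalized), `in_A`,
#'   `in_B`, `in_C`, and `label`.
#' @export
#' @examples
#' categorize_disease(c("Marfan syndrome", "prostate cancer", "xyzzy"))
categorize_disease <- function(diseases, terms = default_category_terms()) {
  if (!inherits(terms, "category_terms")) terms <- new_category_terms(terms)
  name <- normalize_disease(diseases)
  match_any <- function(term_list) {
    if (length(term_list) == 0) return(rep(FALSE, length(name)))
    hits <- vapply(term_list, function(t) stringr::str_detect(name, stringr::fixed(t)),
                   logical(length(name)))
    if (length(name) == 1) any(hits) else rowSums(matrix(hits, nrow = length(name))) > 0
  }
  in_a <- match_any(terms$A)
  in_b <- match_any(terms$B)
  in_c <- match_any(terms$C)
  label <- purrr::pmap_chr(list(in_a, in_b, in_c), function(a, b, c) {
    got <- c("A", "B", "C")[c(a, b, c)]
    if (length(got) == 0) "uncategorized" else paste(got, collapse = "_")
  })
  tibble(disease = name, in_A = in_a, in_B = in_b, in_C = in_c, label = label)
}

#' Tabulate disease category assignments
#'
#' Counts assignments per combined label, plus the marginal count of each
#' single category including overlaps (so a `"B_C"` disease contributes to
#' both the B and the C marginal). Label counts partition the input:
#' their sum equals the number of counted units. With
#' `weight = "by_disease"` each unique disease counts once; with
#' `"by_association"` every row (one per gene-disease association) counts.
#'
#' @param assignments A tibble from [categorize_disease()] (one row per
#'   disease or per association, matching `weight`).
#' @param weight `"by_disease"` or `"by_association"`.
#' @return A list with `labels` (tibble `label`, `n`) and `marginals`
#'   (tibble `category`, `n`, categories A, B, C and uncategorized).
#' @export
category_counts <- function(assignments, weight = c("by_disease", "by_association")) {
  weight <- rlang::arg_match(weight)
  df <- as_tibble(assignments)
  if (weight == "by_disease") {
    df <- dplyr::distinct(df, .data$disease, .keep_all = TRUE)
  }
  if (nrow(df) == 0) {
    return(list(labels = tibble(label = character(), n = integer()),
                marginals = tibble(category = character(), n = integer())))
  }
  labels <- dplyr::arrange(dplyr::count(df, .data$label), .data$label)
  marginals <- tibble(
    category = c("A", "B", "C", "uncategorized"),
    n = c(sum(df$in_A), sum(df$in_B), sum(df$in_C),
          sum(!df$in_A & !df$in_B & !df$in_C))
  )
  list(labels = labels, marginals = marginals)
}
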